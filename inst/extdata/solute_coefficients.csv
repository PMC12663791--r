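name,mode,m0,m1,constant_d,citation
ammonium,linear_ionic,9.50,0.413,NA,"Boudreau (1997) Diagenetic Models and Their Implementation, Table 4.8 (NH4+)"
nitrite,linear_ionic,10.30,0.394,NA,"Boudreau (1997) Table 4.8 (NO2-)"
nitrate,linear_ionic,9.50,0.388,NA,"Boudreau (1997) Table 4.8 (NO3-)"
phosphate_h2po4,linear_ionic,4.02,0.223,NA,"Boudreau (1997) Table 4.8 (H2PO4-)"
phosphate_hpo4,linear_ionic,3.26,0.177,NA,"Boudreau (1997) Table 4.8 (HPO4 2-)"
phosphate_po4,linear_ionic,2.62,0.143,NA,"Boudreau (1997) Table 4.8 (PO4 3-)"
urea,constant,NA,NA,1.36e-05,"fixed molecular diffusion coefficient for urea in seawater"
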