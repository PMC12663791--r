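test_that("the synthetic cruise is deterministic and well-formed", {
  sc <- cruise_scenario(seed = 13)
  a <- simulate_cruise(sc); b <- simulate_cruise(sc)
  expect_identical(a$stations, b$stations)
  expect_identical(a$underway, b$underway)
  st <- a$stations
  expect_identical(nrow(st), 43L)
  expect_true(all(diff(st$along_track_km) > 0))
  # SST decreases southward on the large scale; salinity stays plausible
  expect_gt(st$temp_c[1], 20); expect_lt(st$temp_c[43], 5)
  expect_true(all(st$sal > 33 & st$sal < 36))
  # DIN partition fractions hold exactly
  din <- st$ammonium + st$nitrite + st$nitrate
  expect_equal(st$ammonium / din, rep(0.15, 43), tolerance = 1e-12)
  expect_equal(st$nitrite / din, rep(0.05, 43), tolerance = 1e-12)
  expect_error(cruise_scenario(sst_knots = data.frame(frac = c(0, 1),
                                                      sst_c = c(2, 25))),
               "SST must decrease")
})

test_that("regional nutrient structure matches the scenario anchors", {
  st <- fixture_cruise()$stations
  reg <- classify_region(st$temp_c)
  din <- (st$ammonium + st$nitrite + st$nitrate) / 1000    # umol/L
  # subantarctic stations are macronutrient replete
  expect_true(all(din[reg == "subantarctic"] > 14))
  # DIN rises southward between the regional extremes
  expect_lt(median(din[reg == "subtropical"]), 0.1)
  expect_gt(median(din[reg == "front"]), median(din[reg == "subtropical"]))
  expect_lt(median(din[reg == "front"]), min(din[reg == "subantarctic"]))
})

test_that("simulated cells recover their profile morphology", {
  cr <- fixture_cruise()
  prof <- default_taxon_profiles()
  cells <- simulate_cells(prof, n_cells = 12000, cruise = cr, seed = 8)
  expect_identical(cells, simulate_cells(prof, 12000, cr, seed = 8))
  g <- geometry_from_features(cells$major_um, cells$minor_um)
  for (tx in c("Dinophyceae", "Prymnesiophyceae", "Mediophyceae")) {
    i <- cells$taxon == tx
    med <- prof$esd_median_um[prof$taxon == tx]
    expect_gt(sum(i), 100)
    expect_lt(abs(median(g$esd[i]) - med) / med, 0.05)
  }
  expect_true(all(g$aspect_ratio >= 1 & g$aspect_ratio <= 50))
  expect_error(simulate_cells(prof[0, ], 10, cr), "empty taxon profiles")
})

test_that("competitive exclusion removes slow pure osmotrophs", {
  cr <- fixture_cruise()
  cells <- simulate_cells(n_cells = 800, cruise = cr, seed = 6,
                          exclusion = list(threshold = 0.2,
                                           strategy = "osmotroph", prob = 1))
  res <- suppressMessages(apply_model(cells, cr$stations, cr$underway))
  expect_identical(sum(res$strategy == "osmotroph" & res$gr_n < 0.2), 0L)
  # non-osmotrophs below the threshold survive
  expect_gt(sum(res$strategy != "osmotroph" & res$gr_n < 0.2), 0)
})

test_that("occurrence tables are deterministic with tunable structure", {
  st <- fixture_cruise()$stations
  a <- simulate_occurrences(300, st, seed = 9)
  expect_identical(a, simulate_occurrences(300, st, seed = 9))
  expect_identical(dim(a), c(300L, 43L))
  expect_true(all(a %in% c(0L, 1L)))
  # no filtering: station occupancy is homogeneous (chi-square on totals)
  b <- simulate_occurrences(400, st, filtering_strength = 0, seed = 10)
  p <- suppressWarnings(stats::chisq.test(colSums(b))$p.value)
  expect_gt(p, 0.01)
  # strong filtering concentrates taxa near their thermal niche
  f <- simulate_occurrences(400, st, filtering_strength = 1,
                            niche_width = 2, seed = 10)
  expect_lt(mean(f), mean(b))
  expect_error(simulate_occurrences(10, st, filtering_strength = 2),
               "filtering_strength")
})
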