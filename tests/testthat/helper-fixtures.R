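# Shared fixtures, built in code. The default synthetic cruise is cached per
# session because several files exercise it.

.fixture_env <- new.env(parent = emptyenv())

fixture_cruise <- function(seed = 42) {
  key <- paste0("cruise_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_cruise(cruise_scenario(seed = seed))
  .fixture_env[[key]]
}

# three-station mini transect (internal nmol/L units), constant nutrients by
# default so interpolation is exactly checkable
mini_stations <- function(ammonium = c(100, 200, 300),
                          nitrite = c(10, 20, 30),
                          nitrate = c(50, 100, 150),
                          phosphate = c(80, 160, 240),
                          urea = NA_real_) {
  st <- data.frame(station_id = c("A", "B", "C"),
                   lat = c(-30, -31, -32), lon = c(40, 40, 40),
                   temp_c = c(22, 21, 20), sal = c(35.4, 35.3, 35.2),
                   ammonium = ammonium, nitrite = nitrite,
                   nitrate = nitrate, phosphate = phosphate,
                   urea = rep_len(urea, 3), stringsAsFactors = FALSE)
  st$along_track_km <- along_track_distance(st$lat, st$lon)
  st
}

mini_underway <- function(n = 5, sst = 21) {
  data.frame(time = as.POSIXct("2021-01-20 00:00:00", tz = "UTC") +
               7200 * (seq_len(n) - 1),
             lat = seq(-30, -32, length.out = n),
             lon = rep(40, n),
             sst_c = rep_len(sst, n), sal = rep(35.3, n),
             stringsAsFactors = FALSE)
}

# per-cell results table with chosen growth rates and strategies, for the
# summary functions
toy_results <- function(gr_n, strategy, taxon = strategy,
                        region = "subtropical", functional_group = taxon) {
  n <- length(gr_n)
  data.frame(object_id = sprintf("c%04d", seq_len(n)),
             taxon = rep_len(taxon, n),
             functional_group = rep_len(functional_group, n),
             strategy = rep_len(strategy, n),
             esd = rep(10, n), aspect_ratio = rep(1, n),
             region = factor(rep_len(region, n),
                             levels = c("subtropical", "front",
                                        "subantarctic")),
             gr_n = gr_n, gr_p = gr_n * 16,
             growth_bin = bin_growth(gr_n),
             stringsAsFactors = FALSE)
}

# critical esd for every station of a station table
station_critical_esd <- function(st, target, urea = NULL) {
  vapply(seq_len(nrow(st)), function(i) {
    u <- if (is.null(urea)) st$urea[i] else urea
    fld <- nutrient_field(st$ammonium[i], st$nitrite[i], st$nitrate[i],
                          st$phosphate[i], u)
    critical_esd(target, fld, st$temp_c[i], st$sal[i])
  }, numeric(1))
}
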