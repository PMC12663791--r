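test_that("geometry follows the prolate-spheroid volume rule", {
  g <- geometry_from_features(10, 10)
  expect_equal(g$aspect_ratio, 1)
  expect_equal(g$biovolume, 523.60, tolerance = 1e-4)
  expect_equal(g$esd, 10, tolerance = 1e-9)
  g <- geometry_from_features(20, 10)
  expect_equal(g$aspect_ratio, 2)
  expect_equal(g$biovolume, 1047.20, tolerance = 1e-4)
  expect_equal(g$esd, 2000^(1 / 3), tolerance = 1e-9)
  # esd never exceeds the major axis
  set.seed(9)
  minor <- runif(50, 0.5, 40); major <- minor * runif(50, 1, 20)
  expect_true(all(geometry_from_features(major, minor)$esd <= major))
  expect_error(geometry_from_features(5, 10), "minor axis")
  expect_error(geometry_from_features(5, -1), "axis lengths")
})

test_that("strategy assignment follows the lookup table", {
  tx <- c("living>Dinophyceae>Gymnodinium", "Trichodesmium",
          "Bacillariophyceae>Haslea", "Mediophyceae", NA)
  expect_identical(assign_strategy(tx),
                   c("mixotroph", "diazotroph", "osmotroph", "osmotroph",
                     "unknown"))
  expect_identical(assign_strategy(tx, default_strategy_map(TRUE))[3], "dda")
})

test_that("per-cell model run preserves identity and reproduces the chain", {
  # single fixture cell on a constant two-station field = worked example
  st <- mini_stations(ammonium = c(100, 100, 100), nitrite = c(0, 0, 0),
                      nitrate = c(0, 0, 0), phosphate = c(0, 0, 0))
  uw <- mini_underway(3, sst = 20)
  cells <- data.frame(object_id = "c1", time = uw$time[2],
                      lat = -31, lon = 40, major_um = 10, minor_um = 10,
                      taxon = "Prymnesiophyceae", stringsAsFactors = FALSE)
  res <- apply_model(cells, st, uw, model_config(force_diffusivity = 1e-5))
  expect_equal(nrow(res) + attr(res, "dropped"), nrow(cells))
  expect_equal(res$gr_n, 0.4888, tolerance = 1e-3)
  expect_identical(res$gr_p, 0)
  expect_equal(as.character(res$region), "front")
  # all-zero nutrient field: every rate is zero
  st0 <- mini_stations(ammonium = rep(0, 3), nitrite = rep(0, 3),
                       nitrate = rep(0, 3), phosphate = rep(0, 3))
  cells5 <- data.frame(object_id = paste0("c", 1:5), time = uw$time[2],
                       lat = seq(-30, -32, length.out = 5), lon = 40,
                       major_um = c(5, 10, 20, 8, 12),
                       minor_um = c(5, 8, 10, 8, 6),
                       taxon = "Mediophyceae", stringsAsFactors = FALSE)
  res0 <- apply_model(cells5, st0, uw)
  expect_true(all(res0$gr_n == 0) && all(res0$gr_p == 0))
  expect_error(apply_model(cells5, st, uw[0, ]), "empty underway")
})

test_that("high-DIN subantarctic cells up to 50 um all grow above 2/d", {
  cr <- fixture_cruise()
  cells <- simulate_cells(n_cells = 800, cruise = cr, seed = 5)
  res <- suppressMessages(apply_model(cells, cr$stations, cr$underway))
  sa <- res$region == "subantarctic" & res$esd <= 50
  expect_gt(sum(sa), 50)
  expect_true(all(res$gr_n[sa] > 2))
})

test_that("growth-bin proportions are conservative and sum to one", {
  res <- toy_results(gr_n = c(0.05, 0.1, 0.3, 0.5, 0.7, 1.5, 2.5, 0.15,
                              0.25, 3),
                     strategy = "osmotroph",
                     functional_group = rep(c("diatom", "Dinophyceae"), 5))
  tab <- bin_and_summarize(res, thresholds = c(0.2, 0.6))
  # hand count: bins [0,0.2) = 3, [0.2,0.6) = 3, [0.6,Inf) = 4
  n_by_bin <- tapply(tab$n, tab$growth_bin, sum)
  expect_identical(as.vector(n_by_bin), c(3L, 3L, 4L))
  expect_identical(sum(tab$n), nrow(res))
  s <- tapply(tab$proportion, paste(tab$region, tab$growth_bin), sum)
  expect_true(all(abs(s - 1) < 1e-12))
  # single cell: proportion 1 in its bin
  tab1 <- bin_and_summarize(toy_results(0.1, "osmotroph"))
  expect_identical(tab1$proportion, 1)
  expect_warning(bin_and_summarize(toy_results(numeric(0), character(0))),
                 "no results")
})

test_that("limited-cell strategy shares count alternative strategies", {
  # toy: 4 limited cells, 1 diazotroph -> 25%
  res <- toy_results(gr_n = c(0.1, 0.1, 0.1, 0.1, 0.9),
                     strategy = c("osmotroph", "osmotroph", "osmotroph",
                                  "diazotroph", "mixotroph"))
  s <- limited_cell_strategy_summary(res, 0.2)
  expect_identical(s$n_limited, 4L)
  expect_equal(s$alternative_share_pct, 25)
  # empty limited set: share reported absent
  s0 <- limited_cell_strategy_summary(toy_results(0.9, "osmotroph"), 0.2)
  expect_identical(s0$n_limited, 0L)
  expect_true(is.na(s0$alternative_share_pct))
  expect_error(limited_cell_strategy_summary(res, -0.1), "threshold")
})

test_that("DDA reclassification can only raise the alternative share", {
  set.seed(21)
  taxa <- sample(c("Hemiaulus", "Chaetoceros", "Haslea", "Mastogloia",
                   "Mediophyceae", "Dinophyceae"), 200, replace = TRUE)
  res <- toy_results(gr_n = runif(200, 0, 0.4), strategy = "osmotroph",
                     taxon = taxa)
  res$strategy <- assign_strategy(res$taxon)
  base <- limited_cell_strategy_summary(res, 0.2)$alternative_share_pct
  pats <- c("Hemiaulus", "Chaetocero", "Haslea", "Mastogloia")
  for (i in 1:8) {
    pick <- sample(pats, sample(1:4, 1))
    m <- stats::setNames(rep("dda", length(pick)), pick)
    s <- limited_cell_strategy_summary(res, 0.2, dda_reclassification = m)
    expect_gte(s$alternative_share_pct, base)
  }
})
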