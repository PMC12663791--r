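cfg_d <- model_config(force_diffusivity = 1e-5)

test_that("diffusive uptake to a sphere matches the analytic solution", {
  expect_equal(sphere_max_uptake(1e-5, 5e-4, 100), 6.2832e-9,
               tolerance = 1e-4)
  expect_identical(sphere_max_uptake(1e-5, 5e-4, 0), 0)
  # linear in each argument
  base <- sphere_max_uptake(1e-5, 5e-4, 100)
  expect_equal(sphere_max_uptake(2e-5, 5e-4, 100), 2 * base)
  expect_equal(sphere_max_uptake(1e-5, 1e-3, 100), 2 * base)
  expect_equal(sphere_max_uptake(1e-5, 5e-4, 200), 2 * base)
  expect_error(sphere_max_uptake(-1e-5, 5e-4, 100), "D")
  expect_error(sphere_max_uptake(1e-5, 0, 100), "r0")
})

test_that("prolate shape factor: limit, fixed points, monotonicity", {
  expect_identical(prolate_correction(1), 1)
  expect_equal(prolate_correction(2), 1.3152, tolerance = 1e-4)
  expect_equal(prolate_correction(10), 3.3242, tolerance = 1e-4)
  E <- seq(1, 40, by = 0.5)
  expect_true(all(diff(prolate_correction(E)) > 0))
  # continuous at the spherical limit
  expect_equal(prolate_correction(1 + 1e-8), 1, tolerance = 1e-4)
  expect_error(prolate_correction(0.8), "aspect ratio")
})

test_that("cylinder shape factor exceeds the prolate one and is stable", {
  cyl10 <- cylinder_correction(10)
  # frozen regression value from the boundary-element solver at 256 panels
  expect_equal(cyl10, 3.8120, tolerance = 5e-4)
  expect_gt(cyl10, prolate_correction(10))
  # monotone in elongation
  cs <- vapply(c(2, 5, 10, 20), cylinder_correction, numeric(1))
  expect_true(all(diff(cs) > 0))
  # refining the discretization moves the answer by < 0.1%
  expect_equal(cylinder_correction(10, n_panels = 384), cyl10,
               tolerance = 1e-3)
  expect_error(cylinder_correction(1), "aspect ratio")
})

test_that("daily N uptake weights solutes by their uptake window", {
  # worked example: 10 um sphere, D forced to 1e-5, ammonium 100 nmol/L only
  fld <- nutrient_field(100, 0, 0, 0)
  expect_equal(daily_nitrogen_uptake(10, fld, 20, 35, 1, cfg_d),
               5.4288e-4, tolerance = 1e-4)
  # equal concentrations: nitrate (12 h) contributes half of ammonium (24 h)
  f_nh4 <- nutrient_field(100, 0, 0, 0)
  f_no3 <- nutrient_field(0, 0, 100, 0)
  expect_equal(daily_nitrogen_uptake(10, f_no3, 20, 35, 1, cfg_d),
               daily_nitrogen_uptake(10, f_nh4, 20, 35, 1, cfg_d) / 2)
  # additivity across solutes at machine precision
  f_all <- nutrient_field(100, 40, 100, 0)
  f_no2 <- nutrient_field(0, 40, 0, 0)
  expect_equal(daily_nitrogen_uptake(10, f_all, 20, 35, 1, cfg_d),
               daily_nitrogen_uptake(10, f_nh4, 20, 35, 1, cfg_d) +
               daily_nitrogen_uptake(10, f_no2, 20, 35, 1, cfg_d) +
               daily_nitrogen_uptake(10, f_no3, 20, 35, 1, cfg_d),
               tolerance = 1e-14)
  # missing concentration is an explicit error, not a zero
  f_na <- nutrient_field(100, NA, 0, 0)
  expect_error(daily_nitrogen_uptake(10, f_na, 20, 35, 1, cfg_d),
               "missing nitrite")
})

test_that("N-based growth reproduces the worked example chain", {
  fld <- nutrient_field(100, 0, 0, 0)
  expect_equal(n_based_max_growth(10, fld, 20, 35, 1, cfg_d), 0.4888,
               tolerance = 1e-3)
  # all-zero N field gives zero growth
  f0 <- nutrient_field(0, 0, 0, 50)
  expect_identical(n_based_max_growth(10, f0, 20, 35, 1, cfg_d), 0)
  # aspect ratio 1 equals the pure-sphere path exactly
  expect_identical(n_based_max_growth(10, fld, 20, 35, 1, cfg_d),
                   n_based_max_growth(10, fld, 20, 35, rep(1, 1), cfg_d))
})

test_that("P-based growth follows from the Redfield quota", {
  fld <- nutrient_field(100, 0, 0, 100)
  expect_equal(p_based_max_growth(10, fld, 20, 35, 1, cfg_d), 7.822,
               tolerance = 1e-3)
  # NH4-only DIN equal to DIP and one forced D: gr_p = 16 * gr_n
  expect_equal(p_based_max_growth(10, fld, 20, 35, 1, cfg_d),
               16 * n_based_max_growth(10, fld, 20, 35, 1, cfg_d),
               tolerance = 1e-12)
  f0 <- nutrient_field(100, 0, 0, 0)
  expect_identical(p_based_max_growth(10, f0, 20, 35, 1, cfg_d), 0)
})

test_that("growth obeys the -1.511 size power law for spheres", {
  fld <- nutrient_field(120, 15, 300, 40)
  alpha <- c(0.3, 2, 7.7)
  g1 <- n_based_max_growth(10, fld, 14, 35)
  for (a in alpha)
    expect_equal(n_based_max_growth(10 * a, fld, 14, 35),
                 a^(-1.511) * g1, tolerance = 1e-9)
})

test_that("critical size inverts the growth model", {
  fld <- nutrient_field(100, 0, 0, 0)
  # the 0.489/d worked-example cell reaches 0.2/d at 18.07 um
  expect_equal(critical_esd(0.2, fld, 20, 35, config = cfg_d), 18.07,
               tolerance = 1e-3)
  # decreasing in the target growth rate
  es <- vapply(c(0.1, 0.2, 0.6, 2),
               function(g) critical_esd(g, fld, 20, 35, config = cfg_d),
               numeric(1))
  expect_true(all(diff(es) < 0))
  # doubling every N concentration scales the limit by 2^(1/1.511)
  f2 <- nutrient_field(200, 0, 0, 0)
  expect_equal(critical_esd(0.2, f2, 20, 35, config = cfg_d),
               2^(1 / 1.511) * critical_esd(0.2, fld, 20, 35, config = cfg_d),
               tolerance = 1e-4)
  # error paths
  f0 <- nutrient_field(0, 0, 0, 100)
  expect_error(critical_esd(0.2, f0, 20, 35), "no solution")
  expect_error(critical_esd(1e9, fld, 20, 35, config = cfg_d,
                            method = "root"), "bracket")
})

test_that("root-finding and the closed form agree over a random sweep", {
  set.seed(11)
  for (i in 1:20) {
    fld <- nutrient_field(runif(1, 1, 500), runif(1, 0, 50),
                          runif(1, 0, 2000), runif(1, 1, 300))
    T <- runif(1, 0, 28); S <- runif(1, 33, 36); E <- runif(1, 1, 6)
    g <- 10^runif(1, -1.2, 0.5)
    a <- critical_esd(g, fld, T, S, aspect_ratio = E)
    b <- critical_esd(g, fld, T, S, aspect_ratio = E, method = "root")
    expect_lt(abs(a - b) / a, 1e-6)
  }
})

test_that("urea strictly increases the critical size when present", {
  f0 <- nutrient_field(30, 5, 100, 20)
  fu <- nutrient_field(30, 5, 100, 20, urea = 200)
  for (g in c(0.2, 0.6))
    expect_gt(critical_esd(g, fu, 22, 35.4), critical_esd(g, f0, 22, 35.4))
  # and is ignored when disabled
  cfg_nou <- model_config(include_urea = FALSE)
  expect_identical(critical_esd(0.2, fu, 22, 35.4, config = cfg_nou),
                   critical_esd(0.2, f0, 22, 35.4, config = cfg_nou))
})

test_that("model configuration is validated", {
  expect_error(model_config(photoperiod_h = 30), "photoperiod")
  expect_error(model_config(growth_thresholds = c(0.6, 0.2)), "increasing")
  expect_error(model_config(force_diffusivity = -1), "force_diffusivity")
  expect_error(nutrient_field(-1, 0, 0, 0), "nutrient")
})
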