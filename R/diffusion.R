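# Mass-transfer model for osmotrophic cells: maximal diffusive uptake to a
# sphere, shape corrections for prolate spheroids and finite cylinders
# (via the diffusion-electrostatics capacitance analogy), day/night-weighted
# daily N and P uptake, conversion to maximum growth rates through the
# allometric quotas, and inversion to critical cell sizes.

#' Ambient nutrient field
#'
#' Dissolved concentrations around a cell, in nmol/L. The concentration at
#' the cell surface is assumed to be zero (perfect absorber), so the
#' diffusive gradient is set by the ambient values alone. `urea` is optional
#' (`NA` = not measured); the N-budget functions only include it when it is
#' present and enabled in the configuration.
#'
#' @param ammonium,nitrite,nitrate,phosphate nmol/L, >= 0 (vectorized).
#' @param urea nmol/L, >= 0, or `NA` when absent.
#' @return A data.frame of class `nutrient_field`.
#' @export
nutrient_field <- function(ammonium, nitrite, nitrate, phosphate,
                           urea = NA_real_) {
  n <- max(length(ammonium), length(nitrite), length(nitrate),
           length(phosphate), length(urea))
  fld <- data.frame(ammonium = rep_len(as.numeric(ammonium), n),
                    nitrite = rep_len(as.numeric(nitrite), n),
                    nitrate = rep_len(as.numeric(nitrate), n),
                    phosphate = rep_len(as.numeric(phosphate), n),
                    urea = rep_len(as.numeric(urea), n))
  for (s in names(fld)) {
    v <- fld[[s]]
    bad <- !is.na(v) & (!is.finite(v) | v < 0)
    if (any(bad))
      stop("nutrient concentrations must be finite and >= 0 (", s, ")",
           call. = FALSE)
  }
  class(fld) <- c("nutrient_field", "data.frame")
  fld
}

#' Model configuration
#'
#' Tunable parameters of the growth model. Nitrate and nitrite are credited
#' only during the photoperiod (light-dependent uptake); ammonium, urea and
#' phosphate around the clock. Growth thresholds define the reporting bins.
#'
#' @param photoperiod_h day length in hours, in [0, 24] (default 12).
#' @param day_only_solutes solutes credited only during the photoperiod.
#' @param growth_thresholds strictly increasing growth rates (1/d) bounding
#'   the reporting bins; defaults 0.2, 0.6 and 2.
#' @param redfield_np molar N:P used for the P quota (default 16).
#' @param phosphate_species phosphate speciation for the diffusivity
#'   (`"hpo4"` default; see [diffusion_coefficient()]).
#' @param pressure_bar pressure for the diffusivities, bar (default 1).
#' @param include_urea include urea in the N budget when the field carries a
#'   non-`NA` urea concentration (default TRUE).
#' @param force_diffusivity optional single diffusivity (cm^2/s) applied to
#'   every solute, overriding the physical-chemistry module; used for
#'   controlled comparisons and worked examples.
#' @return A list of class `osmo_config`.
#' @export
model_config <- function(photoperiod_h = 12,
                         day_only_solutes = c("nitrate", "nitrite"),
                         growth_thresholds = c(0.2, 0.6, 2),
                         redfield_np = 16,
                         phosphate_species = "hpo4",
                         pressure_bar = 1,
                         include_urea = TRUE,
                         force_diffusivity = NULL) {
  if (!is.finite(photoperiod_h) || photoperiod_h < 0 || photoperiod_h > 24)
    stop("photoperiod_h must lie in [0, 24]", call. = FALSE)
  if (length(growth_thresholds) < 1 ||
      any(diff(growth_thresholds) <= 0) || any(growth_thresholds <= 0))
    stop("growth_thresholds must be positive and strictly increasing",
         call. = FALSE)
  if (!is.null(force_diffusivity) &&
      (!is.finite(force_diffusivity) || force_diffusivity <= 0))
    stop("force_diffusivity must be a positive scalar", call. = FALSE)
  cfg <- list(photoperiod_h = photoperiod_h,
              day_only_solutes = day_only_solutes,
              growth_thresholds = growth_thresholds,
              redfield_np = redfield_np,
              phosphate_species = phosphate_species,
              pressure_bar = pressure_bar,
              include_urea = isTRUE(include_urea),
              force_diffusivity = force_diffusivity)
  class(cfg) <- "osmo_config"
  cfg
}

#' Maximal diffusive uptake by a spherical absorber
#'
#' Steady-state diffusion to a perfectly absorbing sphere:
#' `rho = 4*pi*D*r0*(C_inf - C_0)` with `C_0 = 0`. Ambient concentration is
#' supplied in nmol/L and converted to nmol/cm^3 internally.
#'
#' @param D molecular diffusivity, cm^2/s.
#' @param r0 equivalent spherical radius, cm.
#' @param c_ambient ambient concentration, nmol/L.
#' @return Maximal uptake, nmol/s (vectorized).
#' @export
sphere_max_uptake <- function(D, r0, c_ambient) {
  if (any(!is.finite(D)) || any(D <= 0)) stop("D must be > 0", call. = FALSE)
  if (any(!is.finite(r0)) || any(r0 <= 0)) stop("r0 must be > 0", call. = FALSE)
  if (any(!is.finite(c_ambient)) || any(c_ambient < 0))
    stop("c_ambient must be >= 0", call. = FALSE)
  4 * pi * D * r0 * (c_ambient / 1000)
}

#' Prolate-spheroid shape factor
#'
#' Enhancement of the diffusive flux for a prolate spheroid of aspect ratio
#' E (major/minor), relative to the spherical solution:
#' `sqrt(E^2 - 1) / ln(E + sqrt(E^2 - 1))`. Equals 1 exactly at E = 1 (the
#' analytic limit) and increases with elongation.
#'
#' @param E aspect ratio >= 1 (vectorized).
#' @return Multiplicative factor >= 1.
#' @export
prolate_correction <- function(E) {
  if (any(!is.finite(E)) || any(E < 1))
    stop("aspect ratio E must be >= 1", call. = FALSE)
  out <- rep_len(1, length(E))
  gt <- E > 1
  if (any(gt)) {
    s <- sqrt(E[gt]^2 - 1)
    out[gt] <- s / log(E[gt] + s)
  }
  out
}

# Potential at (r, z) of a unit charge spread uniformly on a ring of radius
# R at height Z (Gaussian units: an isolated sphere of radius a has C = a).
.ring_potential <- function(r, z, R, Z) {
  d2 <- (R + r)^2 + (z - Z)^2
  m <- pmin(pmax(4 * R * r / d2, 0), 1 - 1e-15)
  (2 / pi) * pracma::ellipke(m)$k / sqrt(d2)
}

# Capacitance of a solid finite cylinder with unit radius and length 2E
# (length:diameter = E), by an axisymmetric method of moments: piecewise-
# constant ring charge on the side wall and both end caps, collocation at
# panel midpoints; the log-singular self term is integrated by splitting the
# panel at the collocation point. Returns C in units of the cylinder radius.
.cylinder_capacitance <- function(E, n_panels = 256, n_quad = 16) {
  a <- 1; L <- 2 * E * a
  ns <- max(8L, as.integer(round(n_panels * L / (L + 2 * a))))
  nc <- max(4L, (n_panels - ns) %/% 2L)
  zs <- seq(-L / 2, L / 2, length.out = ns + 1)
  rs <- seq(0, a, length.out = nc + 1)
  kind <- c(rep("s", ns), rep("t", nc), rep("b", nc))
  t0 <- c(zs[-(ns + 1)], rs[-(nc + 1)], rs[-(nc + 1)])
  t1 <- c(zs[-1], rs[-1], rs[-1])
  geom_r <- function(k, t) {
    k <- rep_len(k, length(t))
    ifelse(k == "s", a, pmax(t, 1e-12))
  }
  geom_z <- function(k, t) {
    k <- rep_len(k, length(t))
    ifelse(k == "s", t, ifelse(k == "t", L / 2, -L / 2))
  }
  N <- length(kind)
  cr <- geom_r(kind, (t0 + t1) / 2)
  cz <- geom_z(kind, (t0 + t1) / 2)
  g <- pracma::gaussLegendre(n_quad, -1, 1)
  A <- matrix(0, N, N)
  for (j in seq_len(N)) {
    tt <- (t0[j] + t1[j]) / 2 + (t1[j] - t0[j]) / 2 * g$x
    ww <- (t1[j] - t0[j]) / 2 * g$w
    Rj <- geom_r(kind[j], tt); Zj <- geom_z(kind[j], tt)
    acc <- numeric(N)
    for (q in seq_along(tt))
      acc <- acc + ww[q] * .ring_potential(cr, cz, Rj[q], Zj[q])
    A[, j] <- acc / (t1[j] - t0[j])
  }
  # replace the singular diagonal with split quadrature around the midpoint
  for (j in seq_len(N)) {
    mid <- (t0[j] + t1[j]) / 2
    acc <- 0
    for (seg in list(c(t0[j], mid), c(mid, t1[j]))) {
      tt <- mean(seg) + diff(seg) / 2 * g$x
      ww <- diff(seg) / 2 * g$w
      Rj <- geom_r(kind[j], tt); Zj <- geom_z(kind[j], tt)
      acc <- acc + sum(ww * .ring_potential(cr[j], cz[j], Rj, Zj))
    }
    A[j, j] <- acc / (t1[j] - t0[j])
  }
  sum(solve(A, rep(1, N)))
}

#' Finite-cylinder shape factor
#'
#' Diffusive mass-transfer shape factor for a solid finite cylinder of
#' length:diameter ratio E, normalized exactly as the prolate factor of
#' [prolate_correction()] (by the minor radius). Computed through the
#' electrostatic analogy -- the diffusion-limited flux to a perfect absorber
#' is proportional to its capacitance -- with an axisymmetric
#' boundary-element solver. Exceeds the prolate factor for elongated cells;
#' used in sensitivity analyses only, never in the default per-cell path.
#'
#' @param E length:diameter ratio, > 1.
#' @param n_panels boundary panels for the solver (default 256; the E = 10
#'   factor changes by < 0.1\% beyond this).
#' @return Multiplicative factor.
#' @export
cylinder_correction <- function(E, n_panels = 256) {
  if (length(E) != 1 || !is.finite(E) || E <= 1)
    stop("cylinder aspect ratio E must be a scalar > 1", call. = FALSE)
  key <- paste0("cyl_", format(E, digits = 12), "_", n_panels)
  if (is.null(.osmo_env[[key]]))
    .osmo_env[[key]] <- .cylinder_capacitance(E, n_panels)
  .osmo_env[[key]]
}

# Per-solute diffusivity honouring a forced override.
.solute_D <- function(solute, temperature, salinity, config) {
  if (!is.null(config$force_diffusivity))
    return(rep_len(config$force_diffusivity,
                   max(length(temperature), length(salinity))))
  diffusion_coefficient(solute, temperature, salinity,
                        pressure = config$pressure_bar,
                        phosphate_species = config$phosphate_species)
}

# Uptake window in seconds for one solute.
.uptake_window <- function(solute, config) {
  if (solute %in% config$day_only_solutes) config$photoperiod_h * 3600 else 86400
}

.require_conc <- function(field, solute) {
  v <- field[[solute]]
  if (any(is.na(v)))
    stop("missing ", solute, " concentration: no silent zero-fill",
         call. = FALSE)
  v
}

# Shared engine: day/night-weighted daily uptake (nmol/d) summed over
# `solutes`, with the prolate correction for aspect_ratio > 1.
.daily_uptake <- function(solutes, esd, aspect_ratio, field,
                          temperature, salinity, config) {
  r0 <- esd / 2 * 1e-4                      # um -> cm
  if (any(!is.finite(esd)) || any(esd <= 0))
    stop("esd must be > 0", call. = FALSE)
  corr <- prolate_correction(aspect_ratio)
  tot <- 0
  for (s in solutes) {
    conc <- .require_conc(field, s)
    D <- .solute_D(s, temperature, salinity, config)
    rho <- sphere_max_uptake(D, r0, conc) * corr
    tot <- tot + rho * .uptake_window(s, config)
  }
  tot
}

.n_solutes <- function(field, config) {
  s <- c("ammonium", "nitrite", "nitrate")
  if (config$include_urea && any(!is.na(field$urea))) s <- c(s, "urea")
  s
}

#' Daily nitrogen uptake of a cell
#'
#' Sum over the dissolved N species of the shape-corrected maximal uptake
#' times each species' uptake window: 86400 s for round-the-clock solutes
#' (ammonium, and urea when present and enabled), `photoperiod_h * 3600` s
#' for the light-dependent ones (nitrate, nitrite).
#'
#' @param esd equivalent spherical diameter, um.
#' @param field a [nutrient_field()] (nmol/L).
#' @param temperature,salinity seawater state at the cell.
#' @param aspect_ratio cell aspect ratio (>= 1); the prolate factor is
#'   applied to the sphere flux at the equivalent spherical radius.
#' @param config a [model_config()].
#' @return nmol N per day (vectorized over cells).
#' @export
daily_nitrogen_uptake <- function(esd, field, temperature, salinity,
                                  aspect_ratio = 1, config = model_config()) {
  .daily_uptake(.n_solutes(field, config), esd, aspect_ratio, field,
                temperature, salinity, config)
}

#' Daily phosphorus uptake of a cell
#'
#' Phosphate only, credited around the clock by default.
#'
#' @inheritParams daily_nitrogen_uptake
#' @return nmol P per day.
#' @export
daily_phosphorus_uptake <- function(esd, field, temperature, salinity,
                                    aspect_ratio = 1,
                                    config = model_config()) {
  .daily_uptake("phosphate", esd, aspect_ratio, field,
                temperature, salinity, config)
}

#' Maximum N-based osmotrophic growth rate
#'
#' Daily diffusive N supply divided by the allometric cell N quota:
#' `GR_N = daily_nitrogen_uptake / n_content(BV)` with `BV = pi/6 * esd^3`.
#' For spheres this is an exact power law, `GR_N(a*esd) =
#' a^-1.511 * GR_N(esd)` (exponent `-(3*0.837 - 1)`).
#'
#' @inheritParams daily_nitrogen_uptake
#' @return Growth rate, 1/d.
#' @export
n_based_max_growth <- function(esd, field, temperature, salinity,
                               aspect_ratio = 1, config = model_config()) {
  up <- daily_nitrogen_uptake(esd, field, temperature, salinity,
                              aspect_ratio, config)
  up / n_content(pi / 6 * esd^3)
}

#' Maximum P-based osmotrophic growth rate
#'
#' Daily diffusive phosphate supply divided by the Redfield-derived P quota.
#'
#' @inheritParams daily_nitrogen_uptake
#' @return Growth rate, 1/d.
#' @export
p_based_max_growth <- function(esd, field, temperature, salinity,
                               aspect_ratio = 1, config = model_config()) {
  up <- daily_phosphorus_uptake(esd, field, temperature, salinity,
                                aspect_ratio, config)
  up / (n_content(pi / 6 * esd^3) / config$redfield_np)
}

#' Critical cell size at a target growth rate
#'
#' The equivalent spherical diameter at which the N-based maximum
#' osmotrophic growth rate equals `target_gr`. Because the growth rate is an
#' exact power law in size (exponent -1.511) at fixed aspect ratio, the
#' default method uses the closed form anchored at a reference size;
#' `method = "root"` instead bisects `log(esd)` over [0.2, 1e4] um
#' (relative tolerance 1e-8) and is kept as an independent route.
#'
#' @param target_gr target growth rate, 1/d (> 0).
#' @param field a [nutrient_field()] with at least one positive N solute.
#' @param temperature,salinity seawater state.
#' @param aspect_ratio cell aspect ratio (>= 1).
#' @param config a [model_config()].
#' @param method `"closed_form"` (default) or `"root"`.
#' @return Critical esd, um.
#' @export
critical_esd <- function(target_gr, field, temperature, salinity,
                         aspect_ratio = 1, config = model_config(),
                         method = c("closed_form", "root")) {
  method <- match.arg(method)
  if (!is.finite(target_gr) || target_gr <= 0)
    stop("target_gr must be > 0", call. = FALSE)
  stopifnot(nrow(field) == 1)
  nsol <- .n_solutes(field, config)
  conc <- vapply(nsol, function(s) .require_conc(field, s), numeric(1))
  if (all(conc == 0))
    stop("no solution: all N concentrations are zero", call. = FALSE)
  gr_at <- function(esd) n_based_max_growth(esd, field, temperature,
                                            salinity, aspect_ratio, config)
  expo <- 3 * quota_constants()$slope - 1    # 1.511
  if (method == "closed_form") {
    ref <- 10
    return(ref * (gr_at(ref) / target_gr)^(1 / expo))
  }
  lo <- 0.2; hi <- 1e4
  g_lo <- gr_at(lo); g_hi <- gr_at(hi)
  if (target_gr > g_lo || target_gr < g_hi)
    stop("target growth rate ", target_gr,
         " outside the bracket [", signif(g_hi, 4), ", ", signif(g_lo, 4),
         "] 1/d reachable for esd in [0.2, 1e4] um", call. = FALSE)
  f <- function(le) log(gr_at(exp(le))) - log(target_gr)
  r <- stats::uniroot(f, lower = log(lo), upper = log(hi), tol = 1e-10)
  exp(r$root)
}
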