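# Molecular diffusion coefficients of dissolved N and P species in seawater.
#
# Freshwater diffusivities of the ionic species follow the linear
# ion-mobility tabulation D0 = (m0 + m1*T) * 1e-6 cm^2/s (Boudreau 1997);
# salinity and pressure enter through a dynamic-viscosity ratio
# (Stokes-Einstein scaling), using a Kukulka-type seawater viscosity
# correlation. Urea is carried as a fixed constant.

.osmo_env <- new.env(parent = emptyenv())

#' Solute coefficient table
#'
#' The shipped table of freshwater-diffusivity coefficients, one row per
#' dissolved species, plus any solutes registered in the session with
#' [register_solute()]. For `linear_ionic` solutes the freshwater diffusion
#' coefficient is `(m0 + m1*T) * 1e-6` cm^2/s; `constant` solutes carry a
#' temperature-independent `constant_d` (cm^2/s).
#'
#' @return A data.frame with columns `name`, `mode`, `m0`, `m1`,
#'   `constant_d`, `citation`.
#' @export
solute_coefficients <- function() {
  if (is.null(.osmo_env$solutes)) {
    path <- system.file("extdata", "solute_coefficients.csv",
                        package = "osmolimit", mustWork = TRUE)
    .osmo_env$solutes <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .osmo_env$solutes
}

#' Register a custom solute
#'
#' Adds (or overrides) a solute in the session coefficient registry so it can
#' be used by [freshwater_diffusivity()] and [diffusion_coefficient()].
#'
#' @param name solute name.
#' @param mode `"linear_ionic"` or `"constant"`.
#' @param m0,m1 linear coefficients (1e-6 cm^2/s and 1e-6 cm^2/s/degC), for
#'   `linear_ionic` solutes; `m0` must be positive and `m1` non-negative.
#' @param constant_d fixed diffusivity (cm^2/s), for `constant` solutes.
#' @return The updated coefficient table, invisibly.
#' @export
register_solute <- function(name, mode = c("linear_ionic", "constant"),
                            m0 = NA_real_, m1 = NA_real_,
                            constant_d = NA_real_) {
  mode <- match.arg(mode)
  if (mode == "linear_ionic") {
    if (!is.finite(m0) || m0 <= 0 || !is.finite(m1) || m1 < 0)
      stop("linear_ionic solutes need m0 > 0 and m1 >= 0", call. = FALSE)
  } else {
    if (!is.finite(constant_d) || constant_d <= 0)
      stop("constant solutes need constant_d > 0", call. = FALSE)
  }
  tab <- solute_coefficients()
  row <- data.frame(name = name, mode = mode, m0 = m0, m1 = m1,
                    constant_d = constant_d, citation = "user-registered",
                    stringsAsFactors = FALSE)
  tab <- rbind(tab[tab$name != name, , drop = FALSE], row)
  .osmo_env$solutes <- tab
  invisible(tab)
}

# Resolve a solute name to its coefficient row; "phosphate" is an alias for
# the configured species (HPO4 2- is dominant at seawater pH ~8.1).
.solute_row <- function(solute, phosphate_species = "hpo4") {
  stopifnot(is.character(solute), length(solute) == 1L)
  if (solute == "phosphate") {
    if (!phosphate_species %in% c("h2po4", "hpo4", "po4"))
      stop("phosphate_species must be one of 'h2po4', 'hpo4', 'po4'",
           call. = FALSE)
    solute <- paste0("phosphate_", phosphate_species)
  }
  tab <- solute_coefficients()
  i <- match(solute, tab$name)
  if (is.na(i)) stop("unknown solute: '", solute, "'", call. = FALSE)
  tab[i, , drop = FALSE]
}

#' Seawater state
#'
#' Validated container for the physical state entering the diffusion
#' coefficients: temperature (degC), practical salinity, and pressure (bar,
#' default 1 as at the sea surface).
#'
#' @param temperature degC, in [-2, 40].
#' @param salinity practical salinity, in [0, 42].
#' @param pressure bar, >= 1.
#' @return A data.frame of class `seawater_state` (vectorized, recycled to a
#'   common length).
#' @export
seawater_state <- function(temperature, salinity = 35, pressure = 1) {
  n <- max(length(temperature), length(salinity), length(pressure))
  st <- data.frame(temperature = rep_len(as.numeric(temperature), n),
                   salinity = rep_len(as.numeric(salinity), n),
                   pressure = rep_len(as.numeric(pressure), n))
  if (any(!is.finite(st$temperature)) ||
      any(st$temperature < -2) || any(st$temperature > 40))
    stop("temperature out of range [-2, 40] degC", call. = FALSE)
  if (any(!is.finite(st$salinity)) ||
      any(st$salinity < 0) || any(st$salinity > 42))
    stop("salinity out of range [0, 42]", call. = FALSE)
  if (any(!is.finite(st$pressure)) || any(st$pressure < 1))
    stop("pressure must be >= 1 bar", call. = FALSE)
  class(st) <- c("seawater_state", "data.frame")
  st
}

#' Dynamic viscosity of seawater
#'
#' Kukulka-type correlation for the dynamic viscosity of seawater as a
#' function of temperature, salinity and pressure, implemented from the
#' printed coefficients. Decreasing in temperature, increasing in salinity.
#'
#' @param temperature degC (vectorized).
#' @param salinity practical salinity.
#' @param pressure bar.
#' @return Dynamic viscosity in centipoise.
#' @export
seawater_viscosity <- function(temperature, salinity = 35, pressure = 1) {
  st <- seawater_state(temperature, salinity, pressure)
  TC <- st$temperature; S <- st$salinity; P <- st$pressure
  1.7910 -
    TC * (6.144e-02 - TC * (1.4510e-03 - TC * 1.6826e-05)) -
    1.5290e-04 * P + 8.3885e-08 * P^2 +
    2.4727e-03 * S +
    TC * (6.0574e-06 * P - 2.6760e-09 * P^2) +
    S * (4.8429e-05 * TC - 4.7172e-06 * TC^2 + 7.5986e-08 * TC^3)
}

#' Freshwater molecular diffusivity
#'
#' Diffusion coefficient of a dissolved species in pure water at temperature
#' `temperature`: `(m0 + m1*T) * 1e-6` cm^2/s for ionic solutes from the
#' linear ion-mobility tabulation, or the fixed `constant_d` for constant
#' solutes (urea).
#'
#' @param solute solute name (see [solute_coefficients()]); `"phosphate"`
#'   resolves through `phosphate_species`.
#' @param temperature degC (vectorized).
#' @param phosphate_species `"hpo4"` (default), `"h2po4"` or `"po4"`.
#' @return Diffusivity in cm^2/s.
#' @export
freshwater_diffusivity <- function(solute, temperature,
                                   phosphate_species = "hpo4") {
  row <- .solute_row(solute, phosphate_species)
  st <- seawater_state(temperature, salinity = 0)
  if (row$mode == "constant") {
    rep_len(row$constant_d, nrow(st))
  } else {
    (row$m0 + row$m1 * st$temperature) * 1e-6
  }
}

#' Molecular diffusivity in seawater
#'
#' Applies Stokes-Einstein scaling to the freshwater diffusivity:
#' `D(S,T,P) = D0(T) * mu(T, S=0, P) / mu(T, S, P)`, so the correction is
#' exactly 1 at S = 0, D increases with temperature and decreases with
#' salinity. Constant-mode solutes (urea) are returned unchanged.
#'
#' @inheritParams freshwater_diffusivity
#' @param salinity practical salinity.
#' @param pressure bar, default 1 (sea surface).
#' @return Diffusivity in cm^2/s.
#' @export
diffusion_coefficient <- function(solute, temperature, salinity = 35,
                                  pressure = 1, phosphate_species = "hpo4") {
  row <- .solute_row(solute, phosphate_species)
  d0 <- freshwater_diffusivity(solute, temperature, phosphate_species)
  if (row$mode == "constant") return(d0)
  mu0 <- seawater_viscosity(temperature, 0, pressure)
  mu <- seawater_viscosity(temperature, salinity, pressure)
  d0 * mu0 / mu
}
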