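# Synthetic cruise, cell and occurrence generators. They emulate the
# statistical structure of a summer subtropical-to-subantarctic transect:
# a monotone SST gradient crossed by the 20 and 10 degC isotherms, dissolved
# inorganic N near the detection limit in the subtropical gyre (with a
# couple of enriched coastal stations at the start of the track) rising to
# macronutrient-replete subantarctic values, DIP tied to regional DIN:DIP
# targets, lognormal cell morphology per taxon, and occurrence matrices
# with tunable thermal filtering and frontal endemics.

.sub_seed <- function(seed, stream) {
  ((as.numeric(seed) %% 2147483647) * 48271 + stream) %% 2147483647
}

# piecewise-linear interpolation helper (clamped at the ends)
.pl <- function(x, xk, yk) stats::approx(xk, yk, xout = x, rule = 2)$y

#' Cruise scenario
#'
#' Parameters of the synthetic transect. Defaults emulate an austral-summer
#' southern Indian Ocean section: SST falling 25 -> 2 degC southward; DIN
#' near the nitrate detection limit in the subtropical gyre (median
#' ~0.02 umol/L) with two enriched coastal stations at the northern end so
#' the subtropical regional mean is ~0.25 umol/L; subantarctic DIN above
#' 14 umol/L; regional DIN:DIP targets 3.7 (north) and 14.5 (south); DIN
#' split 15/5/80\% into ammonium/nitrite/nitrate.
#'
#' @param n_stations number of stations (default 43).
#' @param lat_span,lon_span track endpoints, decimal degrees.
#' @param sst_knots data.frame (`frac`, `sst_c`): SST profile versus track
#'   fraction.
#' @param din_sst_knots data.frame (`sst_c`, `din_umol_l`): median DIN
#'   versus SST (log-linear between knots).
#' @param din_log10_sd_knots data.frame (`sst_c`, `sd`): lognormal DIN noise
#'   (log10 sd) versus SST.
#' @param n_coastal,coastal_din_umol enriched coastal stations at the track
#'   start and their median DIN.
#' @param np_ratio_north,np_ratio_south regional DIN:DIP targets (applied
#'   above 20 and below 10 degC, linear in SST between).
#' @param np_log10_sd lognormal noise on the DIN:DIP ratio.
#' @param din_fractions DIN partition into ammonium/nitrite/nitrate.
#' @param urea_nmol_l optional urea concentration (nmol/L) for all stations
#'   (`NA` = not measured).
#' @param sal_span salinity endpoints north -> south.
#' @param sst_noise_sd,sal_noise_sd additive measurement-scale noise.
#' @param n_underway underway records (2-hourly; default 500).
#' @param start_time first underway timestamp (UTC).
#' @param seed integer master seed.
#' @return List of class `cruise_scenario`.
#' @export
cruise_scenario <- function(n_stations = 43,
                            lat_span = c(-28, -55),
                            lon_span = c(38, 72),
                            sst_knots = data.frame(
                              frac = c(0, 0.44, 0.56, 1),
                              sst_c = c(25, 21, 9, 2)),
                            din_sst_knots = data.frame(
                              sst_c = c(25, 20, 10, 2),
                              din_umol_l = c(0.02, 0.03, 16.5, 22)),
                            din_log10_sd_knots = data.frame(
                              sst_c = c(25, 20, 10, 2),
                              sd = c(0.20, 0.20, 0.02, 0.02)),
                            n_coastal = 2,
                            coastal_din_umol = 2.2,
                            np_ratio_north = 3.7,
                            np_ratio_south = 14.5,
                            np_log10_sd = 0.03,
                            din_fractions = c(ammonium = 0.15,
                                              nitrite = 0.05,
                                              nitrate = 0.80),
                            urea_nmol_l = NA_real_,
                            sal_span = c(35.5, 33.8),
                            sst_noise_sd = 0.15,
                            sal_noise_sd = 0.05,
                            n_underway = 500,
                            start_time = as.POSIXct("2021-01-13 00:00:00",
                                                    tz = "UTC"),
                            seed = 1) {
  if (diff(range(sst_knots$sst_c)) <= 0 || any(diff(sst_knots$sst_c) > 0))
    stop("SST must decrease southward", call. = FALSE)
  if (any(diff(din_sst_knots$din_umol_l[order(-din_sst_knots$sst_c)]) < 0))
    stop("DIN must increase southward (toward lower SST)", call. = FALSE)
  if (abs(sum(din_fractions) - 1) > 1e-9)
    stop("din_fractions must sum to 1", call. = FALSE)
  sc <- as.list(environment())
  class(sc) <- "cruise_scenario"
  sc
}

#' Simulate a cruise
#'
#' Generates the ordered station table (internal nmol/L units) and the
#' 2-hourly underway table of a [cruise_scenario()]. Byte-identical output
#' for a fixed scenario (the seed lives in the scenario).
#'
#' @param scenario a [cruise_scenario()].
#' @return List of class `osmo_cruise` with elements `stations`, `underway`
#'   and `scenario`.
#' @export
simulate_cruise <- function(scenario = cruise_scenario()) {
  sc <- scenario
  .with_seed(.sub_seed(sc$seed, 1L), {
    frac_st <- seq(0, 1, length.out = sc$n_stations)
    lat <- sc$lat_span[1] + frac_st * diff(sc$lat_span)
    lon <- sc$lon_span[1] + frac_st * diff(sc$lon_span)
    sst <- .pl(frac_st, sc$sst_knots$frac, sc$sst_knots$sst_c) +
      stats::rnorm(sc$n_stations, 0, sc$sst_noise_sd)
    sal <- sc$sal_span[1] + frac_st * diff(sc$sal_span) +
      stats::rnorm(sc$n_stations, 0, sc$sal_noise_sd)
    din_med <- .pl(sst, rev(sc$din_sst_knots$sst_c),
                   rev(log10(sc$din_sst_knots$din_umol_l)))
    din_sd <- .pl(sst, rev(sc$din_log10_sd_knots$sst_c),
                  rev(sc$din_log10_sd_knots$sd))
    if (sc$n_coastal > 0) {
      i <- seq_len(sc$n_coastal)
      din_med[i] <- log10(sc$coastal_din_umol)
      din_sd[i] <- 0.04
    }
    din <- 10^(din_med + stats::rnorm(sc$n_stations, 0, din_sd))  # umol/L
    ratio <- .pl(sst, c(10, 20), c(sc$np_ratio_south, sc$np_ratio_north)) *
      10^stats::rnorm(sc$n_stations, 0, sc$np_log10_sd)
    dip <- din / ratio
    stations <- data.frame(
      station_id = sprintf("S%02d", seq_len(sc$n_stations)),
      lat = lat, lon = lon, temp_c = sst, sal = sal,
      ammonium = din * sc$din_fractions[["ammonium"]] * 1000,  # nmol/L
      nitrite = din * sc$din_fractions[["nitrite"]] * 1000,
      nitrate = din * sc$din_fractions[["nitrate"]] * 1000,
      phosphate = dip * 1000,
      urea = rep_len(sc$urea_nmol_l, sc$n_stations),
      stringsAsFactors = FALSE)
    stations$along_track_km <- along_track_distance(lat, lon)

    frac_uw <- seq(0, 1, length.out = sc$n_underway)
    underway <- data.frame(
      time = sc$start_time + 7200 * (seq_len(sc$n_underway) - 1),
      lat = sc$lat_span[1] + frac_uw * diff(sc$lat_span),
      lon = sc$lon_span[1] + frac_uw * diff(sc$lon_span),
      sst_c = .pl(frac_uw, sc$sst_knots$frac, sc$sst_knots$sst_c) +
        stats::rnorm(sc$n_underway, 0, sc$sst_noise_sd),
      sal = sc$sal_span[1] + frac_uw * diff(sc$sal_span) +
        stats::rnorm(sc$n_underway, 0, sc$sal_noise_sd),
      stringsAsFactors = FALSE)
    structure(list(stations = stations, underway = underway, scenario = sc),
              class = "osmo_cruise")
  })
}

#' Default taxon profiles
#'
#' Morphology and trophic-strategy profiles emulating the major imaged
#' groups of a subtropical-to-subantarctic transect: mixotrophic
#' dinoflagellates and diazotroph filaments concentrated in the warm
#' oligotrophic north, diatoms dominating the cold macronutrient-replete
#' south, small prymnesiophytes and flagellates throughout. Cell sizes are
#' lognormal (median/geometric-sd), aspect ratios 1 + gamma-distributed
#' excess (capped at 50).
#'
#' @return data.frame, one row per taxon profile.
#' @export
default_taxon_profiles <- function() {
  data.frame(
    taxon = c("Dinophyceae", "Mediophyceae", "Bacillariophyceae",
              "Trichodesmium", "Hemiaulus", "Prymnesiophyceae",
              "Chlorophyta"),
    functional_group = c("Dinophyceae", "diatom", "diatom",
                         "Trichodesmium", "diatom", "Prymnesiophyceae",
                         "other"),
    strategy = c("mixotroph", "osmotroph", "osmotroph",
                 "diazotroph", "osmotroph", "osmotroph", "osmotroph"),
    esd_median_um = c(18, 30, 20, 15, 25, 7, 3),
    esd_gsd = c(1.5, 1.6, 1.5, 1.3, 1.4, 1.4, 1.3),
    ar_shape = c(2, 2, 4, 16, 3, 2, 2),
    ar_scale = c(0.15, 0.25, 0.75, 0.9, 0.30, 0.05, 0.05),
    w_subtropical = c(0.45, 0.05, 0.05, 0.12, 0.08, 0.15, 0.10),
    w_front = c(0.30, 0.25, 0.20, 0.01, 0.04, 0.10, 0.10),
    w_subantarctic = c(0.10, 0.45, 0.30, 0.00, 0.02, 0.08, 0.05),
    stringsAsFactors = FALSE)
}

#' Simulate imaged cells along a cruise
#'
#' Places cells uniformly along the underway track, draws a taxon with
#' region-dependent weights and a lognormal morphology from its profile,
#' and emits an imaged-cell feature table. With `exclusion` set, cells of
#' the given strategy whose modeled N-based growth rate falls below the
#' threshold are removed with the given probability (resource-based
#' competitive exclusion).
#'
#' @param profiles taxon profiles as [default_taxon_profiles()].
#' @param n_cells cells to draw before exclusion.
#' @param cruise an [simulate_cruise()] result.
#' @param seed integer seed.
#' @param exclusion `NULL`, or `list(threshold = 0.2, strategy =
#'   "osmotroph", prob = 1)`.
#' @param config [model_config()] used when exclusion is applied.
#' @return Cell feature table: `object_id`, `time`, `lat`, `lon`,
#'   `major_um`, `minor_um`, `area_um2`, `taxon`, `functional_group`,
#'   `strategy`.
#' @export
simulate_cells <- function(profiles = default_taxon_profiles(),
                           n_cells = 2000, cruise, seed = 1,
                           exclusion = NULL, config = model_config()) {
  if (is.null(profiles) || nrow(profiles) == 0)
    stop("empty taxon profiles", call. = FALSE)
  uw <- cruise$underway
  cells <- .with_seed(.sub_seed(seed, 2L), {
    iu <- sample.int(nrow(uw), n_cells, replace = TRUE)
    region <- as.character(classify_region(uw$sst_c[iu]))
    wcol <- c(subtropical = "w_subtropical", front = "w_front",
              subantarctic = "w_subantarctic")
    tx <- vapply(region, function(r) {
      w <- profiles[[wcol[[r]]]]
      sample.int(nrow(profiles), 1, prob = w)
    }, integer(1))
    p <- profiles[tx, ]
    esd <- p$esd_median_um * exp(stats::rnorm(n_cells, 0, log(p$esd_gsd)))
    E <- pmin(1 + stats::rgamma(n_cells, shape = p$ar_shape,
                                scale = p$ar_scale), 50)
    data.frame(object_id = sprintf("obj_%06d", seq_len(n_cells)),
               time = uw$time[iu],
               lat = uw$lat[iu], lon = uw$lon[iu],
               major_um = esd * E^(2 / 3),
               minor_um = esd * E^(-1 / 3),
               area_um2 = pi / 4 * esd^2 * E^(1 / 3),
               taxon = p$taxon,
               functional_group = p$functional_group,
               strategy = p$strategy,
               stringsAsFactors = FALSE)
  })
  if (!is.null(exclusion)) {
    res <- apply_model(cells, cruise$stations, uw, config)
    gr <- res$gr_n[match(cells$object_id, res$object_id)]
    cand <- cells$strategy == exclusion$strategy &
      !is.na(gr) & gr < exclusion$threshold
    drop <- .with_seed(.sub_seed(seed, 4L),
                       cand & stats::runif(n_cells) < exclusion$prob)
    cells <- cells[!drop, , drop = FALSE]
    rownames(cells) <- NULL
  }
  cells
}

#' Simulate a taxa-by-station occurrence table
#'
#' Taxa receive Gaussian thermal niches; the presence probability at a
#' station blends a flat baseline with the niche response according to
#' `filtering_strength` (0 = exchangeable stations, 1 = pure thermal
#' filtering). A configured fraction of taxa are frontal endemics occurring
#' only at front-region stations.
#'
#' @param n_taxa number of taxa.
#' @param stations station table with `temp_c` (regions via
#'   [classify_region()]).
#' @param niche_width Gaussian thermal niche sd, degC.
#' @param filtering_strength in [0, 1].
#' @param frontal_endemic_fraction fraction of taxa exclusive to the front.
#' @param frontal_stations station labels hosting the endemics; default all
#'   front-region stations.
#' @param baseline_occupancy flat presence probability (default 0.5).
#' @param seed integer seed.
#' @return Integer presence matrix (taxa x stations) with dimnames.
#' @export
simulate_occurrences <- function(n_taxa, stations, niche_width = 4,
                                 filtering_strength = 0.5,
                                 frontal_endemic_fraction = 0,
                                 frontal_stations = NULL,
                                 baseline_occupancy = 0.5, seed = 1) {
  if (filtering_strength < 0 || filtering_strength > 1)
    stop("filtering_strength must lie in [0, 1]", call. = FALSE)
  if (frontal_endemic_fraction < 0 || frontal_endemic_fraction > 1)
    stop("frontal_endemic_fraction must lie in [0, 1]", call. = FALSE)
  tc <- stations$temp_c
  region <- classify_region(tc)
  .with_seed(.sub_seed(seed, 3L), {
    n_st <- nrow(stations)
    opt <- stats::runif(n_taxa, min(tc) - 2, max(tc) + 2)
    niche <- exp(-outer(opt, tc, `-`)^2 / (2 * niche_width^2))
    p <- baseline_occupancy *
      ((1 - filtering_strength) + filtering_strength * niche)
    n_end <- round(frontal_endemic_fraction * n_taxa)
    if (n_end > 0) {
      host <- if (is.null(frontal_stations)) region == "front"
              else stations$station_id %in% frontal_stations
      if (!any(host))
        stop("no front-region stations for the endemics", call. = FALSE)
      p[seq_len(n_end), ] <- 0
      p[seq_len(n_end), host] <- 0.8
    }
    m <- matrix(as.integer(stats::runif(n_taxa * n_st) < p), n_taxa, n_st,
                dimnames = list(sprintf("taxon_%05d", seq_len(n_taxa)),
                                stations$station_id))
    m
  })
}
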