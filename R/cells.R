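# Imaged-cell pipeline: morphology from 2-D features, per-cell application
# of the diffusion model with locally interpolated nutrients, growth-bin /
# functional-group summaries and the trophic-strategy accounting of
# diffusion-limited cells.

#' Cell geometry from imaged 2-D features
#'
#' Prolate-spheroid volume rule: aspect ratio `E = major/minor`, biovolume
#' `BV = pi/6 * major * minor^2` (um^3), equivalent spherical diameter
#' `esd = (6*BV/pi)^(1/3)`; esd never exceeds the major axis.
#'
#' @param major,minor axis lengths, um (vectorized; `major >= minor > 0`).
#' @return data.frame with `aspect_ratio`, `biovolume`, `esd`.
#' @export
geometry_from_features <- function(major, minor) {
  if (any(!is.finite(major)) || any(!is.finite(minor)) ||
      any(major <= 0) || any(minor <= 0))
    stop("axis lengths must be finite and > 0", call. = FALSE)
  if (any(minor > major))
    stop("minor axis exceeds major axis", call. = FALSE)
  bv <- pi / 6 * major * minor^2
  data.frame(aspect_ratio = major / minor,
             biovolume = bv,
             esd = (6 * bv / pi)^(1 / 3))
}

#' Default trophic-strategy lookup table
#'
#' Maps taxon annotations to trophic strategies by keyword: Dinophyceae are
#' treated as mixotrophs; Trichodesmium and Richelia associations as
#' diazotrophs; Hemiaulus, Chaetocerotaceae, Haslea-like pennates and
#' Mastogloia become diatom-diazotroph associations (DDA) only under
#' `reclassify_dda = TRUE` (they are pure osmotrophs in the base map).
#' Everything else defaults to osmotroph.
#'
#' @param reclassify_dda reclassify the putative DDA hosts (default FALSE).
#' @return data.frame with columns `pattern` (regex, case-insensitive) and
#'   `strategy`, applied first-match-wins.
#' @export
default_strategy_map <- function(reclassify_dda = FALSE) {
  map <- data.frame(
    pattern = c("Trichodesmium", "Richelia",
                "Dinophyceae|Dinoflagell",
                "Hemiaulus", "Chaetocero", "Haslea", "Mastogloia"),
    strategy = c("diazotroph", "diazotroph",
                 "mixotroph",
                 if (reclassify_dda) rep("dda", 4) else rep("osmotroph", 4)),
    stringsAsFactors = FALSE)
  map
}

#' Assign trophic strategies to taxa
#'
#' @param taxon character vector of taxon annotations.
#' @param map a strategy map as from [default_strategy_map()].
#' @return Character vector drawn from `osmotroph`, `mixotroph`,
#'   `diazotroph`, `dda`, `unknown`.
#' @export
assign_strategy <- function(taxon, map = default_strategy_map()) {
  out <- rep("osmotroph", length(taxon))
  out[is.na(taxon) | !nzchar(taxon)] <- "unknown"
  for (i in rev(seq_len(nrow(map)))) {
    hit <- grepl(map$pattern[i], taxon, ignore.case = TRUE)
    out[hit & !is.na(taxon)] <- map$strategy[i]
  }
  out
}

#' Bin growth rates
#'
#' Left-closed bins `[0, t1), [t1, t2), ..., [tk, Inf)` from the configured
#' thresholds.
#'
#' @param gr growth rates, 1/d.
#' @param thresholds strictly increasing positive thresholds.
#' @return Factor of bin labels.
#' @export
bin_growth <- function(gr, thresholds = c(0.2, 0.6, 2)) {
  br <- c(0, thresholds, Inf)
  labs <- paste0("[", br[-length(br)], ",", br[-1], ")")
  cut(gr, breaks = br, labels = labs, right = FALSE, include.lowest = TRUE)
}

#' Apply the diffusion model to a table of imaged cells
#'
#' For each cell: geometry from the imaged axes, seawater state from the
#' nearest-in-time underway record, ambient nutrients interpolated along the
#' track at the cell position, then the N- and P-based maximum osmotrophic
#' growth rates with the prolate correction at the cell's aspect ratio.
#' Cells whose nutrients or state cannot be resolved are dropped and
#' counted (attribute `dropped`).
#'
#' @param cells a cell feature table as from [read_cell_table()] or
#'   [simulate_cells()]: columns `object_id`, `time`, `lat`, `lon`,
#'   `major_um`, `minor_um`, `taxon` (and optionally `functional_group`,
#'   `strategy`).
#' @param stations station table (nmol/L internal units).
#' @param underway underway table (`time`, `lat`, `lon`, `sst_c`, `sal`).
#' @param config a [model_config()].
#' @param strategy_map used when `cells` lacks a `strategy` column.
#' @return data.frame of per-cell results (`object_id`, `esd`,
#'   `aspect_ratio`, `region`, `gr_n`, `gr_p`, `growth_bin`,
#'   `functional_group`, `strategy`, nutrient columns), with attribute
#'   `dropped` (count of unresolvable cells).
#' @export
apply_model <- function(cells, stations, underway, config = model_config(),
                        strategy_map = default_strategy_map()) {
  if (is.null(underway) || nrow(underway) == 0)
    stop("empty underway track", call. = FALSE)
  if (is.null(stations) || nrow(stations) == 0)
    stop("empty station table", call. = FALSE)
  geom <- geometry_from_features(cells$major_um, cells$minor_um)
  iu <- nearest_in_time(cells$time, underway)
  sst <- underway$sst_c[iu]
  sal <- underway$sal[iu]
  fld <- interpolate_nutrients(cells$lat, cells$lon, stations)
  need <- c("ammonium", "nitrite", "nitrate", "phosphate")
  ok <- is.finite(sst) & is.finite(sal) &
    Reduce(`&`, lapply(need, function(s) is.finite(fld[[s]])))
  dropped <- sum(!ok)
  if (dropped > 0)
    message("apply_model: dropped ", dropped,
            " cell(s) with unresolvable nutrients or seawater state")
  keep <- which(ok)
  fldk <- fld[keep, , drop = FALSE]
  class(fldk) <- class(fld)
  gr_n <- n_based_max_growth(geom$esd[keep], fldk, sst[keep], sal[keep],
                             geom$aspect_ratio[keep], config)
  gr_p <- p_based_max_growth(geom$esd[keep], fldk, sst[keep], sal[keep],
                             geom$aspect_ratio[keep], config)
  strategy <- if (!is.null(cells$strategy)) cells$strategy[keep]
              else assign_strategy(cells$taxon[keep], strategy_map)
  fg <- if (!is.null(cells$functional_group)) cells$functional_group[keep]
        else cells$taxon[keep]
  out <- data.frame(object_id = cells$object_id[keep],
                    taxon = cells$taxon[keep],
                    functional_group = fg,
                    strategy = strategy,
                    esd = geom$esd[keep],
                    aspect_ratio = geom$aspect_ratio[keep],
                    biovolume = geom$biovolume[keep],
                    sst_c = sst[keep],
                    region = classify_region(sst[keep]),
                    gr_n = gr_n,
                    gr_p = gr_p,
                    growth_bin = bin_growth(gr_n, config$growth_thresholds),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(fldk))
  attr(out, "dropped") <- dropped
  out
}

#' Growth-bin by functional-group proportions
#'
#' Proportion of each functional group within every region x growth-bin
#' stratum (proportions sum to 1 per stratum); counts are preserved.
#'
#' @param results per-cell results from [apply_model()].
#' @param thresholds growth-bin thresholds (1/d); defaults to the bins
#'   already present in `results`.
#' @return data.frame with `region`, `growth_bin`, `functional_group`,
#'   `n`, `proportion`.
#' @export
bin_and_summarize <- function(results, thresholds = NULL) {
  if (is.null(results) || nrow(results) == 0) {
    warning("no results to summarize")
    return(data.frame(region = character(), growth_bin = character(),
                      functional_group = character(), n = integer(),
                      proportion = numeric()))
  }
  bin <- if (is.null(thresholds)) results$growth_bin
         else bin_growth(results$gr_n, thresholds)
  tab <- as.data.frame(table(region = results$region, growth_bin = bin,
                             functional_group = results$functional_group),
                       responseName = "n")
  tab <- tab[order(tab$region, tab$growth_bin, tab$functional_group), ]
  tot <- stats::ave(tab$n, tab$region, tab$growth_bin, FUN = sum)
  tab$proportion <- ifelse(tot > 0, tab$n / tot, NA_real_)
  tab <- tab[tot > 0, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Trophic strategies of diffusion-limited cells
#'
#' Among cells whose N-based maximum osmotrophic growth rate falls below
#' `threshold`, counts each trophic strategy and reports the share holding
#' an alternative N acquisition strategy (diazotrophy, mixotrophy, or DDA).
#' An optional reclassification map (taxon regex -> strategy) is applied
#' first; moving taxa from osmotroph to dda can only increase the share.
#'
#' @param results per-cell results from [apply_model()] (needs `gr_n`,
#'   `strategy`, `taxon`).
#' @param threshold limiting growth rate, 1/d (default 0.2).
#' @param dda_reclassification optional named character vector
#'   `c(regex = strategy)` applied to `taxon` before counting.
#' @return List with `n_limited`, `counts` (named by strategy),
#'   `alternative_share_pct` (percent with strategy in diazotroph /
#'   mixotroph / dda; `NA` when no cell is limited).
#' @export
limited_cell_strategy_summary <- function(results, threshold = 0.2,
                                          dda_reclassification = NULL) {
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be > 0", call. = FALSE)
  strategy <- results$strategy
  if (!is.null(dda_reclassification)) {
    for (pat in names(dda_reclassification)) {
      hit <- grepl(pat, results$taxon, ignore.case = TRUE)
      strategy[hit] <- dda_reclassification[[pat]]
    }
  }
  lim <- results$gr_n < threshold
  n_limited <- sum(lim)
  counts <- table(factor(strategy[lim],
                         levels = c("osmotroph", "mixotroph", "diazotroph",
                                    "dda", "unknown")))
  alt <- sum(counts[c("mixotroph", "diazotroph", "dda")])
  list(n_limited = n_limited,
       counts = counts,
       alternative_share_pct = if (n_limited > 0) 100 * alt / n_limited
                               else NA_real_)
}
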