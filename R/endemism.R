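# Frontal-endemism statistic: proportion of taxa exclusive to a station set,
# with a Monte-Carlo null over uniformly drawn station sets of equal size.

# Run code under a fixed seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.check_occurrence <- function(table) {
  if (!is.matrix(table) || !is.numeric(table))
    stop("occurrence table must be a numeric matrix (taxa x stations)",
         call. = FALSE)
  if (any(table < 0)) stop("occurrence counts must be >= 0", call. = FALSE)
  if (anyDuplicated(rownames(table)) || anyDuplicated(colnames(table)))
    stop("duplicate taxon or station labels", call. = FALSE)
  invisible(table)
}

#' Proportion of taxa exclusive to a station set
#'
#' Fraction of all taxa present anywhere that occur in at least one station
#' of `station_set` and in none outside it (presence = count >= 1).
#'
#' @param table taxa x stations numeric matrix of counts, with dimnames.
#' @param station_set station labels (or column indices), non-empty subset
#'   of the table's stations.
#' @return Fraction in [0, 1].
#' @export
exclusive_proportion <- function(table, station_set) {
  .check_occurrence(table)
  if (length(station_set) == 0) stop("empty station set", call. = FALSE)
  if (is.character(station_set)) {
    idx <- match(station_set, colnames(table))
    if (any(is.na(idx)))
      stop("unknown station label(s): ",
           paste(station_set[is.na(idx)], collapse = ", "), call. = FALSE)
  } else idx <- as.integer(station_set)
  pres <- table >= 1
  anywhere <- rowSums(pres) > 0
  inside <- rowSums(pres[, idx, drop = FALSE]) > 0
  outside <- rowSums(pres[, -idx, drop = FALSE]) > 0
  sum(inside & !outside) / sum(anywhere)
}

#' Resampling null for the exclusive-taxon proportion
#'
#' Draws `n_draws` uniform k-subsets of all stations (without replacement
#' within a draw; subsets may repeat across draws) and computes the
#' exclusive-taxon proportion of each, giving the null mean, sd and the
#' empirical p-value of an observed station set (fraction of draws >= the
#' observed proportion). Fully reproducible from `seed`.
#'
#' @inheritParams exclusive_proportion
#' @param station_set the focal (observed) station set.
#' @param n_draws Monte-Carlo draws (default 1000).
#' @param seed integer seed.
#' @param exclude_focal drop the focal stations from the pool before drawing
#'   (default FALSE: draws come from all stations, focal included).
#' @return List of class `endemism_result`: `observed_proportion`,
#'   `null_mean`, `null_sd`, `empirical_p`, `null_draws`, `n_draws`, `k`,
#'   `seed`.
#' @export
endemism_null <- function(table, station_set, n_draws = 1000, seed = 1,
                          exclude_focal = FALSE) {
  .check_occurrence(table)
  k <- length(station_set)
  obs <- exclusive_proportion(table, station_set)
  pool <- colnames(table)
  if (is.null(pool)) pool <- seq_len(ncol(table))
  if (exclude_focal) pool <- setdiff(pool, station_set)
  pool <- sort(pool)              # invariant to station column order
  if (k >= length(pool))
    stop("subset size k must be smaller than the station pool", call. = FALSE)
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  draws <- .with_seed(seed, {
    vapply(seq_len(n_draws), function(i)
      exclusive_proportion(table, sample(pool, k)), numeric(1))
  })
  structure(list(observed_proportion = obs,
                 null_mean = mean(draws),
                 null_sd = stats::sd(draws),
                 empirical_p = mean(draws >= obs),
                 null_draws = draws,
                 n_draws = n_draws, k = k, seed = seed),
            class = "endemism_result")
}

#' @export
print.endemism_result <- function(x, ...) {
  cat(sprintf(
    "Exclusive-taxon proportion: observed %.3f; null %.3f +/- %.3f (%d draws of %d stations, seed %d); empirical p = %.4g\n",
    x$observed_proportion, x$null_mean, x$null_sd, x$n_draws, x$k, x$seed,
    x$empirical_p))
  invisible(x)
}
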