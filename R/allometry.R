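# Allometric cell element quotas: nitrogen from biovolume (base-10
# power law), phosphorus by the Redfield N:P of 16.

#' Quota model constants
#'
#' Read-only constants of the allometric quota model: the base-10 regression
#' intercept and slope relating log10(N content, pg) to log10(biovolume,
#' um^3), the molar mass of nitrogen, and the Redfield N:P ratio.
#'
#' @return Named list with `intercept`, `slope`, `m_n` (g/mol), `redfield_np`.
#' @export
quota_constants <- function() {
  list(intercept = -1.084, slope = 0.837, m_n = 14.007, redfield_np = 16)
}

#' Cellular nitrogen content from biovolume
#'
#' `N_cell = 10^(intercept + slope*log10(BV)) / (M_N * 1000)` nmol N per
#' cell, i.e. the allometric pg-N regression converted to nmol with
#' M_N = 14.007 g/mol. Strictly increasing in biovolume.
#'
#' @param biovolume cell biovolume, um^3 (vectorized, > 0).
#' @return nmol N per cell.
#' @export
n_content <- function(biovolume) {
  if (any(!is.finite(biovolume)) || any(biovolume <= 0))
    stop("biovolume must be finite and > 0", call. = FALSE)
  k <- quota_constants()
  10^(k$intercept + k$slope * log10(biovolume)) / (k$m_n * 1000)
}

#' Cellular phosphorus content from biovolume
#'
#' Redfield-derived quota: exactly `n_content(biovolume) / 16`.
#'
#' @inheritParams n_content
#' @return nmol P per cell.
#' @export
p_content <- function(biovolume) {
  n_content(biovolume) / quota_constants()$redfield_np
}
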