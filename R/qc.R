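new_qc_result <- function(ds, report, stage) {
  ds <- append_log(ds, sprintf("%s:removed=%d/%d", stage,
                               sum(!report$kept), nrow(report)))
  attr(ds, "qc_report") <- report
  ds
}

#' Retrieve the QC report of the most recent quality gate
#'
#' @param ds a `spectra_set` returned by [pca_quality_filter()] or
#'   [amide1_filter()]
#' @return tibble with columns `spectrum_id`, `kept`, `reason`
#'   (`NA` for retained spectra, otherwise one of `pca_outlier`,
#'   `amide_low`, `amide_high`).
#' @export
qc_report <- function(ds) {
  rep <- attr(ds, "qc_report")
  if (is.null(rep)) stop("no QC report attached to this spectra_set",
                         call. = FALSE)
  rep
}

#' PCA score-space quality gate
#'
#' Principal component analysis of the mean-centred absorbance matrix;
#' spectra whose (PC1, PC2) scores fall outside the chi-square(2 df)
#' Mahalanobis ellipse at the given quantile are removed. This is the
#' automated analogue of drawing a centroid ellipse on the score plot and
#' discarding everything outside it (scatter-dominated spectra, rough core
#' edges, residual substrate).
#'
#' @param ds a `spectra_set` with at least 3 spectra
#' @param quantile coverage of the retention ellipse (default 0.99)
#' @return the filtered `spectra_set`; the per-spectrum report is available
#'   via [qc_report()].
#' @export
pca_quality_filter <- function(ds, quantile = 0.99) {
  stopifnot(inherits(ds, "spectra_set"))
  if (n_spectra(ds) < 3) stop("PCA quality gate needs >= 3 spectra",
                              call. = FALSE)
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)",
                                           call. = FALSE)
  m <- ds$absorbance
  total_var <- sum(apply(m, 2, var))
  if (total_var == 0) {
    stop("zero-variance dataset: PCA quality gate undefined", call. = FALSE)
  }
  pc <- prcomp(m, center = TRUE, scale. = FALSE, rank. = 2)
  scores <- pc$x
  # PCs are uncorrelated by construction; collapse near-zero dimensions so a
  # rank-1 cloud (e.g. all-identical spectra plus one outlier) still gates
  v <- apply(scores, 2, var)
  use <- v > 1e-12 * sum(v)
  scores <- scores[, use, drop = FALSE]
  d2 <- mahalanobis(scores, center = colMeans(scores),
                    cov = diag(v[use], nrow = sum(use)))
  cutoff <- qchisq(quantile, df = sum(use))
  kept <- d2 <= cutoff
  report <- tibble::tibble(
    spectrum_id = ds$meta$spectrum_id,
    kept = unname(kept),
    reason = ifelse(kept, NA_character_, "pca_outlier")
  )
  new_qc_result(filter_spectra(ds, kept), report, "pca_quality_filter")
}

#' Amide I intensity gate
#'
#' Retains spectra whose absorbance at the grid point nearest `at`
#' (1650 cm^-1, the Amide I maximum) lies in the closed window
#' \[`low`, `high`\]. Below 0.01 AU the spectral sensitivity collapses
#' (blank substrate); above 2 AU detector linearity is compromised
#' (saturation).
#'
#' @param ds a `spectra_set`
#' @param low,high window bounds in AU (defaults 0.01 and 2, inclusive)
#' @param at lookup wavenumber in cm^-1 (default 1650)
#' @return the filtered `spectra_set`; per-spectrum report via
#'   [qc_report()] with reasons `amide_low` / `amide_high`.
#' @export
amide1_filter <- function(ds, low = 0.01, high = 2, at = 1650) {
  stopifnot(inherits(ds, "spectra_set"))
  if (at > max(ds$grid) || at < min(ds$grid)) {
    stop(sprintf("lookup wavenumber %g cm-1 outside grid range [%g, %g]",
                 at, min(ds$grid), max(ds$grid)), call. = FALSE)
  }
  a <- ds$absorbance[, nearest_index(ds$grid, at)]
  reason <- dplyr::case_when(a < low ~ "amide_low",
                             a > high ~ "amide_high",
                             TRUE ~ NA_character_)
  kept <- is.na(reason)
  report <- tibble::tibble(spectrum_id = ds$meta$spectrum_id,
                           kept = unname(kept), reason = unname(reason))
  new_qc_result(filter_spectra(ds, kept), report, "amide1_filter")
}
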