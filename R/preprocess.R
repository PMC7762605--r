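#' Subtract a substrate reference spectrum
#'
#' Removes the mean absorbance of the clean substrate (e.g. CaF2) from every
#' spectrum, rowwise on the shared grid.
#'
#' @param ds a `spectra_set`
#' @param substrate numeric vector on `ds$grid` (descending storage order),
#'   or a two-column data frame with `wavenumber` and `absorbance`
#' @return the corrected `spectra_set`, provenance appended.
#' @export
subtract_substrate <- function(ds, substrate) {
  if (is.data.frame(substrate)) {
    ord <- order(substrate$wavenumber, decreasing = TRUE)
    if (!isTRUE(all.equal(substrate$wavenumber[ord], ds$grid))) {
      stop("substrate grid does not match dataset grid", call. = FALSE)
    }
    substrate <- substrate$absorbance[ord]
  }
  if (length(substrate) != length(ds$grid)) {
    stop("substrate grid does not match dataset grid", call. = FALSE)
  }
  ds$absorbance <- sweep(ds$absorbance, 2, as.numeric(substrate), `-`)
  append_log(ds, "subtract_substrate")
}

#' Normalise spectra
#'
#' * `minmax`: rescale each spectrum to span exactly \[0, 1\].
#' * `vector`: scale each spectrum to unit Euclidean norm.
#' * `amide1`: scale so the absorbance at the grid point nearest 1650 cm^-1
#'   (the Amide I maximum) equals 1.
#' * `none`: identity.
#'
#' @param ds a `spectra_set`
#' @param method normalisation method
#' @param amide_at wavenumber used by the `amide1` method (cm^-1)
#' @return the normalised `spectra_set`.
#' @export
normalise <- function(ds, method = c("none", "minmax", "vector", "amide1"),
                      amide_at = 1650) {
  method <- match.arg(method)
  m <- ds$absorbance
  if (method == "minmax") {
    lo <- apply(m, 1, min)
    hi <- apply(m, 1, max)
    if (any(hi - lo < .Machine$double.eps * 100)) {
      bad <- ds$meta$spectrum_id[hi - lo < .Machine$double.eps * 100]
      stop("minmax normalisation undefined for constant spectra: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    m <- (m - lo) / (hi - lo)
  } else if (method == "vector") {
    nrm <- sqrt(rowSums(m^2))
    if (any(nrm == 0)) stop("vector normalisation undefined for zero spectra",
                            call. = FALSE)
    m <- m / nrm
  } else if (method == "amide1") {
    i <- nearest_index(ds$grid, amide_at)
    a <- m[, i]
    if (any(a == 0)) stop("amide1 normalisation undefined where A(1650) = 0",
                          call. = FALSE)
    m <- m / a
  }
  ds$absorbance <- m
  append_log(ds, paste0("normalise:", method))
}

#' Bin spectra
#'
#' Replaces consecutive non-overlapping groups of `b` points by their mean on
#' both axes; a trailing remainder of fewer than `b` points is dropped.
#'
#' @param ds a `spectra_set`
#' @param b binning factor (1, 2, 4 or 8 in the search grid; any positive
#'   integer accepted)
#' @return the binned `spectra_set`.
#' @export
bin_spectrum <- function(ds, b) {
  b <- as.integer(b)
  if (b < 1) stop("binning factor must be >= 1", call. = FALSE)
  n <- length(ds$grid)
  if (b > n) stop("binning factor exceeds spectrum length", call. = FALSE)
  if (b == 1) return(append_log(ds, "bin:1"))
  n_out <- n %/% b
  idx <- rep(seq_len(n_out), each = b)
  keep <- seq_len(n_out * b)
  grid_new <- as.vector(tapply(ds$grid[keep], idx, mean))
  # rowsum on the transposed matrix averages column blocks in one pass
  m_new <- t(rowsum(t(ds$absorbance[, keep, drop = FALSE]), idx) / b)
  ds2 <- spectra_set(grid_new, m_new, ds$meta, log = ds$log)
  append_log(ds2, paste0("bin:", b))
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Applies a Savitzky-Golay filter of window length `2s + 1` and polynomial
#' order `min(4, 2s - 1)`, so the half-window code `s = 3` reproduces the
#' 7-point, order-4 filter. Derivatives are scaled by the grid spacing
#' (units AU per cm^-1 per derivative order); edges are handled by the
#' polynomial fits within the end windows. A derivative requested with
#' smoothing code 0 falls back to a 5-point, order-2 stencil.
#'
#' @param ds a `spectra_set`
#' @param s half-window code (0 = none, 2, 3 or 4)
#' @param deriv derivative order (0, 1 or 2)
#' @return the filtered `spectra_set`.
#' @export
savgol <- function(ds, s, deriv = 0) {
  s <- as.integer(s)
  deriv <- as.integer(deriv)
  if (s == 0 && deriv == 0) return(append_log(ds, "savgol:none"))
  if (s == 0) {
    window <- 5L
    order <- 2L
  } else {
    window <- 2L * s + 1L
    order <- min(4L, 2L * s - 1L)
  }
  if (window > length(ds$grid)) {
    stop("Savitzky-Golay window exceeds spectrum length", call. = FALSE)
  }
  if (deriv > order) stop("derivative order exceeds polynomial order",
                          call. = FALSE)
  spacing <- abs(mean(diff(ds$grid)))
  asc <- rev(seq_along(ds$grid))  # storage is high->low; filter on ascending axis
  m <- ds$absorbance[, asc, drop = FALSE]
  out <- t(apply(m, 1, function(row) {
    signal::sgolayfilt(row, p = order, n = window, m = deriv, ts = spacing)
  }))
  ds$absorbance <- out[, rev(seq_along(ds$grid)), drop = FALSE]
  rownames(ds$absorbance) <- ds$meta$spectrum_id
  append_log(ds, sprintf("savgol:s=%d,deriv=%d", s, deriv))
}

#' Cut spectra to a wavenumber window
#'
#' Retains grid points with `lo <= wavenumber <= hi` (inclusive).
#'
#' @param ds a `spectra_set`
#' @param window `"none"`, a window string `"1800-1200"`, or a numeric
#'   `c(lo, hi)`
#' @return the cut `spectra_set`.
#' @export
spectral_cut <- function(ds, window) {
  if (is.character(window)) {
    if (identical(window, "none")) return(append_log(ds, "cut:none"))
    window <- parse_window(window)
  }
  window <- sort(as.numeric(window))
  keep <- ds$grid >= window[1] & ds$grid <= window[2]
  if (!any(keep)) stop("spectral cut leaves no grid points", call. = FALSE)
  ds2 <- spectra_set(ds$grid[keep], ds$absorbance[, keep, drop = FALSE],
                     ds$meta, log = ds$log)
  append_log(ds2, sprintf("cut:%g-%g", window[2], window[1]))
}

#' Apply a full pre-processing pipeline
#'
#' Runs the steps of a [preproc_spec()] in the fixed order normalise, bin,
#' Savitzky-Golay (smoothing plus derivative), spectral cut; the order can be
#' permuted for sensitivity analyses. The canonical spec string is appended
#' to the provenance log.
#'
#' @param ds a `spectra_set`
#' @param spec a `preproc_spec` or its canonical string
#' @param order character vector permuting
#'   `c("normalise", "bin", "savgol", "cut")`
#' @return the processed `spectra_set`.
#' @export
#' @examples
#' grid <- seq(1800, 1000, by = -4)
#' ds <- spectra_set(grid, matrix(runif(5 * 201), 5),
#'                   tibble::tibble(spectrum_id = paste0("s", 1:5)))
#' apply_preproc(ds, preproc_spec("minmax", 0, 4, 3, "1800-1200"))
apply_preproc <- function(ds, spec,
                          order = c("normalise", "bin", "savgol", "cut")) {
  if (is.character(spec)) spec <- parse_preproc_spec(spec)
  stopifnot(inherits(spec, "preproc_spec"))
  if (!setequal(order, c("normalise", "bin", "savgol", "cut"))) {
    stop("order must permute normalise, bin, savgol, cut", call. = FALSE)
  }
  for (step in order) {
    ds <- tryCatch(switch(step,
      normalise = normalise(ds, spec$normalisation),
      bin = bin_spectrum(ds, spec$binning),
      savgol = savgol(ds, spec$smoothing, spec$derivative),
      cut = spectral_cut(ds, spec$cut)
    ), error = function(e) {
      stop(sprintf("preproc step '%s' failed: %s", step, conditionMessage(e)),
           call. = FALSE)
    })
  }
  append_log(ds, paste0("preproc:", format(spec)))
}
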