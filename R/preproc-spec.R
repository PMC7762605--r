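norm_levels <- c("none", "minmax", "vector", "amide1")
deriv_levels <- c(0L, 1L, 2L)
bin_levels <- c(1L, 2L, 4L, 8L)
smooth_levels <- c(0L, 2L, 3L, 4L)

#' Define one pre-processing pipeline
#'
#' One cell of the pre-processing search grid: normalisation method,
#' Savitzky-Golay derivative order, binning factor, smoothing half-window
#' code (window length 2s+1; 0 = no smoothing) and spectral cut window.
#' Serialises to the canonical string `n=<norm>|l=<deriv>|b=<bin>|s=<smooth>|
#' p=<lo>-<hi>` used in provenance logs and result tables.
#'
#' @param normalisation one of `"none"`, `"minmax"`, `"vector"`, `"amide1"`
#' @param derivative derivative order, 0, 1 or 2
#' @param binning binning factor, 1, 2, 4 or 8
#' @param smoothing half-window code, 0 (none), 2, 3 or 4; `s = 3` gives the
#'   7-point, order-4 filter of the best tissue model
#' @param cut `"none"` or a window string `"1800-1200"` (cm^-1, inclusive)
#' @return a `preproc_spec` object.
#' @export
#' @examples
#' preproc_spec("minmax", 0, 4, 3, "1800-1200")
preproc_spec <- function(normalisation = "none", derivative = 0,
                         binning = 1, smoothing = 0, cut = "none") {
  normalisation <- match.arg(normalisation, norm_levels)
  derivative <- as.integer(derivative)
  binning <- as.integer(binning)
  smoothing <- as.integer(smoothing)
  if (!derivative %in% deriv_levels) stop("derivative must be 0, 1 or 2",
                                          call. = FALSE)
  if (!binning %in% bin_levels) stop("binning must be 1, 2, 4 or 8",
                                     call. = FALSE)
  if (!smoothing %in% smooth_levels) stop("smoothing must be 0, 2, 3 or 4",
                                          call. = FALSE)
  cut <- as.character(cut)
  if (!identical(cut, "none")) parse_window(cut)  # validates
  structure(list(normalisation = normalisation, derivative = derivative,
                 binning = binning, smoothing = smoothing, cut = cut),
            class = "preproc_spec")
}

parse_window <- function(w) {
  m <- regmatches(w, regexec("^([0-9.]+)-([0-9.]+)$", w))[[1]]
  if (length(m) != 3) stop("cut window must look like '1800-1200' or 'none'",
                           call. = FALSE)
  sort(c(as.numeric(m[2]), as.numeric(m[3])))  # lo, hi
}

#' @export
format.preproc_spec <- function(x, ...) {
  sprintf("n=%s|l=%d|b=%d|s=%d|p=%s", x$normalisation, x$derivative,
          x$binning, x$smoothing, x$cut)
}

#' @export
print.preproc_spec <- function(x, ...) {
  cat("<preproc_spec>", format(x), "\n")
  invisible(x)
}

#' @export
as.character.preproc_spec <- function(x, ...) format(x)

#' Parse the canonical pre-processing string
#'
#' Inverse of `format()` on a [preproc_spec()]; round-trips bit-exactly.
#'
#' @param s string such as `"n=minmax|l=0|b=4|s=3|p=1800-1200"`
#' @return a `preproc_spec`.
#' @export
parse_preproc_spec <- function(s) {
  parts <- strsplit(s, "|", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  need <- c("n", "l", "b", "s", "p")
  if (!setequal(keys, need)) {
    stop("malformed preproc string: ", s, call. = FALSE)
  }
  v <- setNames(vals, keys)
  preproc_spec(v[["n"]], as.integer(v[["l"]]), as.integer(v[["b"]]),
               as.integer(v[["s"]]), v[["p"]])
}

#' Enumerate a pre-processing grid
#'
#' Full Cartesian product of the supplied parameter levels, defaulting to the
#' search grid used for the tissue analysis: 4 normalisations x 3 derivative
#' orders x 4 binning factors x 4 smoothing codes x 3 cuts = 576 pipelines.
#'
#' @param normalisation,derivative,binning,smoothing,cut vectors of levels
#' @return tibble with one row per combination and a `spec` column holding
#'   the canonical string.
#' @export
#' @examples
#' nrow(preproc_grid())  # 576
preproc_grid <- function(normalisation = norm_levels,
                         derivative = deriv_levels,
                         binning = bin_levels,
                         smoothing = smooth_levels,
                         cut = c("none", "1800-1000", "1800-1200")) {
  g <- tidyr::expand_grid(normalisation = normalisation,
                          derivative = as.integer(derivative),
                          binning = as.integer(binning),
                          smoothing = as.integer(smoothing),
                          cut = cut)
  g$spec <- purrr::pmap_chr(g, function(normalisation, derivative, binning,
                                        smoothing, cut) {
    format(preproc_spec(normalisation, derivative, binning, smoothing, cut))
  })
  g
}
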