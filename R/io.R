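#' Convert raw transmittance to absorbance
#'
#' Ratioing a single-beam sample intensity to its background and taking
#' \eqn{A = -\log_{10}(I_{sample}/I_{background})}, the standard absorbance
#' conversion. A ratio of 0.01 corresponds to A = 2, the linearity limit used
#' by the Amide I saturation gate.
#'
#' @param wavenumbers numeric grid (cm^-1)
#' @param sample_intensity,background_intensity positive numeric vectors on
#'   that grid
#' @return tibble with columns `wavenumber` and `absorbance`.
#' @export
#' @examples
#' transmittance_to_absorbance(c(1650, 1646), c(0.1, 1), c(1, 1))
transmittance_to_absorbance <- function(wavenumbers, sample_intensity,
                                        background_intensity) {
  if (length(sample_intensity) != length(background_intensity) ||
      length(sample_intensity) != length(wavenumbers)) {
    stop("wavenumbers, sample and background must have equal length",
         call. = FALSE)
  }
  if (any(background_intensity <= 0)) {
    stop("background intensity must be strictly positive", call. = FALSE)
  }
  ratio <- sample_intensity / background_intensity
  if (any(ratio <= 0)) {
    bad <- wavenumbers[ratio <= 0][1]
    stop(sprintf("non-positive transmittance ratio at %.6g cm-1", bad),
         call. = FALSE)
  }
  tibble::tibble(wavenumber = wavenumbers, absorbance = -log10(ratio))
}

meta_cols <- c(meta_patient = "patient_id", meta_group = "group_id",
               meta_fraction = "fraction", meta_class = "class_label")

#' Write a spectra_set as a wide CSV
#'
#' Layout: header `spectrum_id, meta_patient, meta_group, meta_fraction,
#' meta_class, <wavenumbers...>`, one spectrum per row, absorbance written to
#' 8 significant digits (below instrument noise). The provenance log is
#' serialised to a JSON sidecar `<path>.provenance.json`.
#'
#' @param ds a `spectra_set`
#' @param path output CSV path
#' @return `path`, invisibly.
#' @export
write_spectraset <- function(ds, path) {
  stopifnot(inherits(ds, "spectra_set"))
  meta_out <- tibble::tibble(
    spectrum_id = ds$meta$spectrum_id,
    meta_patient = ds$meta$patient_id,
    meta_group = ds$meta$group_id,
    meta_fraction = ds$meta$fraction,
    meta_class = ds$meta$class_label
  )
  abs_chr <- matrix(sprintf("%.8g", ds$absorbance),
                    nrow = nrow(ds$absorbance), ncol = length(ds$grid))
  colnames(abs_chr) <- sprintf("%.8g", ds$grid)
  out <- dplyr::bind_cols(meta_out, tibble::as_tibble(abs_chr))
  ok <- tryCatch({
    readr::write_csv(out, path, progress = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok),
                        call. = FALSE)
  jsonlite::write_json(list(provenance = ds$log),
                       paste0(path, ".provenance.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Read a spectra_set from CSV
#'
#' Accepts the wide layout written by [write_spectraset()] (metadata columns
#' prefixed `meta_`, remaining column names parsed as wavenumbers) or a long
#' layout with `wavenumber` and `absorbance` columns. Rows containing
#' non-finite absorbance are dropped with a warning listing their ids. A
#' `<path>.provenance.json` sidecar, when present, restores the provenance
#' log.
#'
#' @param path CSV path
#' @param layout `"wide"` or `"long"`
#' @return a validated `spectra_set`.
#' @export
read_spectraset <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs)) {
    stop(sprintf("parse error at line %d of %s: expected %s, saw %s",
                 probs$row[1] + 1L, path, probs$expected[1], probs$actual[1]),
         call. = FALSE)
  }
  if (layout == "long") {
    need <- c("spectrum_id", "wavenumber", "absorbance")
    miss <- setdiff(need, names(raw))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                           call. = FALSE)
    wide <- tidyr::pivot_wider(raw, names_from = "wavenumber",
                               values_from = "absorbance")
    return(read_wide_frame(wide, source = path))
  }
  read_wide_frame(raw, source = path)
}

read_wide_frame <- function(raw, source) {
  miss <- setdiff(c("spectrum_id", names(meta_cols)), names(raw))
  if (length(miss)) {
    stop("schema error: missing required metadata column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  wn_names <- setdiff(names(raw), c("spectrum_id", names(meta_cols)))
  grid <- suppressWarnings(as.numeric(wn_names))
  if (anyNA(grid)) {
    stop("schema error: non-numeric wavenumber column(s): ",
         paste(wn_names[is.na(grid)], collapse = ", "), call. = FALSE)
  }
  mat <- as.matrix(raw[, wn_names])
  storage.mode(mat) <- "double"
  meta <- tibble::tibble(
    spectrum_id = as.character(raw$spectrum_id),
    patient_id = as.character(raw$meta_patient),
    group_id = as.character(raw$meta_group),
    fraction = as.character(raw$meta_fraction),
    class_label = as.character(raw$meta_class)
  )
  bad <- rowSums(!is.finite(mat)) > 0
  if (any(bad)) {
    warning("dropping spectra with non-finite absorbance: ",
            paste(meta$spectrum_id[bad], collapse = ", "), call. = FALSE)
    mat <- mat[!bad, , drop = FALSE]
    meta <- meta[!bad, , drop = FALSE]
  }
  log <- character()
  sidecar <- paste0(source, ".provenance.json")
  if (file.exists(sidecar)) {
    log <- unlist(jsonlite::read_json(sidecar)$provenance, use.names = FALSE)
    if (is.null(log)) log <- character()
  }
  spectra_set(grid, mat, meta, log = log)
}
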