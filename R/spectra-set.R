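#' Spectral dataset container
#'
#' A `spectra_set` bundles a shared wavenumber grid, an absorbance matrix
#' (one spectrum per row) and a per-spectrum metadata tibble, together with a
#' provenance log of the operations applied so far. The grid is stored in
#' descending wavenumber order (4000 down to 450 cm^-1), the plotting
#' convention of infrared spectroscopy; operations that require an ascending
#' axis reverse internally and restore the order on output.
#'
#' @param grid numeric vector of wavenumbers (cm^-1), strictly monotonic.
#'   Ascending input is reversed to the descending storage order.
#' @param absorbance numeric matrix, `length(grid)` columns, one spectrum per
#'   row (absorbance units).
#' @param meta data frame with one row per spectrum. Must contain
#'   `spectrum_id`; `patient_id`, `group_id`, `fraction` and `class_label`
#'   are filled with defaults when absent. `fraction` must be one of
#'   `"tissue"`, `"whole_serum"`, `"filtrate"`, `"concentrate"`;
#'   `class_label` one of `"mutated"`, `"wildtype"`, `"unknown"`.
#' @param log character vector of provenance entries.
#'
#' @return A `spectra_set` object.
#' @export
#'
#' @examples
#' grid <- seq(1800, 1000, by = -4)
#' mat <- matrix(runif(3 * length(grid)), nrow = 3)
#' ds <- spectra_set(grid, mat, tibble::tibble(spectrum_id = c("a", "b", "c")))
#' ds
spectra_set <- function(grid, absorbance, meta, log = character()) {
  grid <- as.numeric(grid)
  if (length(grid) < 2) stop("grid must have at least 2 points", call. = FALSE)
  d <- diff(grid)
  if (all(d > 0)) {
    grid <- rev(grid)
    absorbance <- absorbance[, rev(seq_along(grid)), drop = FALSE]
  } else if (!all(d < 0)) {
    stop("grid must be strictly monotonic", call. = FALSE)
  }
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (ncol(absorbance) != length(grid)) {
    stop("absorbance must have one column per grid point", call. = FALSE)
  }
  meta <- tibble::as_tibble(meta)
  if (nrow(meta) != nrow(absorbance)) {
    stop("meta must have one row per spectrum", call. = FALSE)
  }
  if (!"spectrum_id" %in% names(meta)) {
    stop("meta must contain a spectrum_id column", call. = FALSE)
  }
  meta$spectrum_id <- as.character(meta$spectrum_id)
  if (anyDuplicated(meta$spectrum_id)) {
    stop("spectrum_id values must be unique", call. = FALSE)
  }
  defaults <- list(patient_id = "p1", group_id = "g1",
                   fraction = "tissue", class_label = "unknown")
  for (nm in names(defaults)) {
    if (!nm %in% names(meta)) meta[[nm]] <- defaults[[nm]]
    meta[[nm]] <- as.character(meta[[nm]])
  }
  bad_frac <- setdiff(unique(meta$fraction),
                      c("tissue", "whole_serum", "filtrate", "concentrate"))
  if (length(bad_frac)) {
    stop("unknown fraction value(s): ", paste(bad_frac, collapse = ", "),
         call. = FALSE)
  }
  bad_cls <- setdiff(unique(meta$class_label),
                     c("mutated", "wildtype", "unknown"))
  if (length(bad_cls)) {
    stop("unknown class_label value(s): ", paste(bad_cls, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(absorbance))) {
    bad <- meta$spectrum_id[rowSums(!is.finite(absorbance)) > 0]
    stop("non-finite absorbance in spectra: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rownames(absorbance) <- meta$spectrum_id
  structure(
    list(grid = grid, absorbance = absorbance, meta = meta,
         log = as.character(log)),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra x %d points, %.0f-%.0f cm-1\n",
              nrow(x$absorbance), length(x$grid),
              max(x$grid), min(x$grid)))
  cls <- table(x$meta$class_label)
  cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "),
      "\n")
  cat(sprintf("  patients: %d, groups: %d\n",
              dplyr::n_distinct(x$meta$patient_id),
              dplyr::n_distinct(x$meta$group_id)))
  if (length(x$log)) cat("  log:", paste(x$log, collapse = " -> "), "\n")
  invisible(x)
}

#' Number of spectra in a spectra_set
#' @param ds a `spectra_set`
#' @return integer count of spectra (rows).
#' @export
n_spectra <- function(ds) nrow(ds$absorbance)

append_log <- function(ds, entry) {
  ds$log <- c(ds$log, entry)
  ds
}

#' Subset a spectra_set by row
#'
#' @param ds a `spectra_set`
#' @param idx logical or integer row index
#' @return the subsetted `spectra_set` (provenance preserved).
#' @export
filter_spectra <- function(ds, idx) {
  spectra_set(ds$grid, ds$absorbance[idx, , drop = FALSE],
              ds$meta[idx, , drop = FALSE], log = ds$log)
}

#' Tidy a spectra_set into a long tibble
#'
#' One row per (spectrum, wavenumber) pair, joined to the spectrum metadata;
#' convenient for dplyr summaries and ggplot2.
#'
#' @param x a `spectra_set`
#' @param ... unused
#' @return tibble with columns `spectrum_id`, `patient_id`, `group_id`,
#'   `fraction`, `class_label`, `wavenumber`, `absorbance`.
#' @exportS3Method generics::tidy
tidy.spectra_set <- function(x, ...) {
  tibble::tibble(
    spectrum_id = rep(x$meta$spectrum_id, each = length(x$grid)),
    wavenumber = rep(x$grid, times = nrow(x$absorbance)),
    absorbance = as.vector(t(x$absorbance))
  ) |>
    dplyr::left_join(x$meta, by = "spectrum_id") |>
    dplyr::relocate("wavenumber", "absorbance", .after = dplyr::last_col())
}

#' One-row summary of a spectra_set
#' @param x a `spectra_set`
#' @param ... unused
#' @return tibble with spectrum/patient/group counts and grid descriptors.
#' @exportS3Method generics::glance
glance.spectra_set <- function(x, ...) {
  tibble::tibble(
    n_spectra = nrow(x$absorbance),
    n_points = length(x$grid),
    wn_max = max(x$grid),
    wn_min = min(x$grid),
    n_patients = dplyr::n_distinct(x$meta$patient_id),
    n_groups = dplyr::n_distinct(x$meta$group_id),
    n_mutated = sum(x$meta$class_label == "mutated"),
    n_wildtype = sum(x$meta$class_label == "wildtype")
  )
}

#' Plot class-mean spectra
#'
#' @param object a `spectra_set`
#' @param max_spectra draw at most this many individual spectra behind the
#'   class means (thinned at random but deterministically by order).
#' @param ... unused
#' @return a ggplot object (wavenumber axis reversed, the field convention).
#' @exportS3Method ggplot2::autoplot
autoplot.spectra_set <- function(object, max_spectra = 50, ...) {
  keep <- unique(round(seq(1, n_spectra(object),
                           length.out = min(max_spectra, n_spectra(object)))))
  long <- tidy(filter_spectra(object, keep))
  means <- long |>
    dplyr::summarise(absorbance = mean(.data$absorbance),
                     .by = c("class_label", "wavenumber"))
  ggplot2::ggplot(long, ggplot2::aes(.data$wavenumber, .data$absorbance)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$spectrum_id),
                       alpha = 0.15, linewidth = 0.2) +
    ggplot2::geom_line(data = means,
                       ggplot2::aes(colour = .data$class_label),
                       linewidth = 0.7) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)), y = "Absorbance (AU)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
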