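#' Van de Hulst extinction curves for Mie-type scatter modelling
#'
#' Smooth extinction efficiency curves
#' \eqn{Q(\nu) = 2 - (4/\rho)\sin\rho + (4/\rho^2)(1 - \cos\rho)} with phase
#' \eqn{\rho = 2\pi \nu d (m - 1)} (wavenumber \eqn{\nu} in cm^-1, sphere
#' diameter `d` in cm, refractive index `m`), the classical approximation for
#' the baseline distortions that wavelength-scale particles impose on tissue
#' microspectra. `Q` is bounded in \[0, 4\]. Curves are sampled over the
#' supplied diameter and refractive-index ranges and, by default, scaled to
#' unit Euclidean norm for use as EMSC interferents.
#'
#' @param grid wavenumber grid (cm^-1)
#' @param n_curves number of curves
#' @param d_um sphere diameter range in micrometres, `c(lo, hi)`
#' @param m refractive index range, `c(lo, hi)`
#' @param normalise scale each curve to unit Euclidean norm
#' @return matrix with `length(grid)` rows and `n_curves` columns.
#' @export
make_mie_interferents <- function(grid, n_curves = 3, d_um = c(5, 15),
                                  m = c(1.1, 1.5), normalise = TRUE) {
  n_curves <- as.integer(n_curves)
  if (n_curves < 1) stop("n_curves must be >= 1", call. = FALSE)
  if (length(d_um) != 2 || length(m) != 2 || any(d_um <= 0) || any(m <= 1)) {
    stop("empty or invalid (d, m) parameter range", call. = FALSE)
  }
  d_seq <- seq(d_um[1], d_um[2], length.out = n_curves) * 1e-4  # um -> cm
  m_seq <- seq(m[1], m[2], length.out = n_curves)
  out <- vapply(seq_len(n_curves), function(i) {
    rho <- 2 * pi * grid * d_seq[i] * (m_seq[i] - 1)
    q <- 2 - (4 / rho) * sin(rho) + (4 / rho^2) * (1 - cos(rho))
    q[rho == 0] <- 0
    if (normalise) q <- q / sqrt(sum(q^2))
    q
  }, numeric(length(grid)))
  colnames(out) <- sprintf("mie%d", seq_len(n_curves))
  out
}

emsc_design <- function(grid, reference, poly_order, interferents) {
  nu <- 2 * (grid - min(grid)) / (max(grid) - min(grid)) - 1  # scale to [-1, 1]
  polys <- vapply(0:poly_order, function(k) nu^k, numeric(length(grid)))
  colnames(polys) <- sprintf("b%d", 0:poly_order)
  X <- cbind(ref = as.numeric(reference), polys)
  if (!is.null(interferents)) {
    interferents <- as.matrix(interferents)
    if (nrow(interferents) != length(grid)) {
      stop("interferents must be on the working grid", call. = FALSE)
    }
    if (is.null(colnames(interferents))) {
      colnames(interferents) <- sprintf("c%d", seq_len(ncol(interferents)))
    }
    X <- cbind(X, interferents)
  }
  X
}

#' Fit extended multiplicative signal correction
#'
#' Ordinary least squares of each spectrum on a reference spectrum, scaled
#' wavenumber polynomials up to `poly_order`, and optional interferent
#' spectra (Mie extinction curves, contaminant profiles). The corrected
#' spectrum is `(raw - baseline - interferents) / a`, where `a` is the
#' multiplicative coefficient on the reference, so a spectrum that is an
#' affine contamination of the reference is restored exactly. Spectra whose
#' `|a|` falls below `tol` cannot be meaningfully rescaled; they are left
#' uncorrected and flagged (an error is raised if every spectrum is
#' degenerate).
#'
#' @param ds a `spectra_set`
#' @param reference numeric reference spectrum on `ds$grid`; defaults to the
#'   dataset mean
#' @param poly_order baseline polynomial degree (0-4)
#' @param interferents optional matrix of interferent spectra
#'   (`length(grid)` rows)
#' @param tol degeneracy threshold on `|a|`
#' @param min_scale spectra with `a < min_scale` are additionally flagged and
#'   left uncorrected: dividing by a near-zero scale would amplify noise
#'   without restoring signal (blank-substrate spectra are the typical case;
#'   the Amide I gate removes them downstream). 0 disables the guard.
#' @return an `emsc_fit` object: corrected `spectra_set` (`$corrected`),
#'   coefficient tibble (`$coefficients`: spectrum_id, a, b0..bk, c..,
#'   degenerate flag), and the model definition.
#' @export
fit_emsc <- function(ds, reference = NULL, poly_order = 2,
                     interferents = NULL, tol = 1e-8, min_scale = 0) {
  stopifnot(inherits(ds, "spectra_set"))
  poly_order <- as.integer(poly_order)
  if (poly_order < 0 || poly_order > 4) stop("poly_order must be 0-4",
                                             call. = FALSE)
  if (is.null(reference)) reference <- colMeans(ds$absorbance)
  if (length(reference) != length(ds$grid)) {
    stop("reference must be on the dataset grid", call. = FALSE)
  }
  if (sd(reference) == 0) stop("reference spectrum is constant", call. = FALSE)
  X <- emsc_design(ds$grid, reference, poly_order, interferents)
  # one shared projection for all spectra: coefs = A X (X'X)^-1
  XtX_inv <- solve(crossprod(X))
  coefs <- ds$absorbance %*% X %*% XtX_inv
  colnames(coefs) <- c("a", colnames(X)[-1])
  a <- coefs[, "a"]
  degenerate <- abs(a) < max(tol, min_scale)
  if (all(degenerate)) {
    stop("degenerate EMSC fit: no spectrum carries the reference component",
         call. = FALSE)
  }
  nuisance <- coefs[, -1, drop = FALSE] %*% t(X[, -1, drop = FALSE])
  corrected <- (ds$absorbance - nuisance) / ifelse(degenerate, 1, a)
  corrected[degenerate, ] <- ds$absorbance[degenerate, , drop = FALSE]
  out <- ds
  out$absorbance <- corrected
  rownames(out$absorbance) <- out$meta$spectrum_id
  out <- append_log(out, sprintf("emsc:poly=%d,interferents=%d", poly_order,
                                 if (is.null(interferents)) 0L
                                 else ncol(as.matrix(interferents))))
  structure(
    list(corrected = out,
         coefficients = dplyr::bind_cols(
           tibble::tibble(spectrum_id = ds$meta$spectrum_id),
           tibble::as_tibble(coefs),
           tibble::tibble(degenerate = unname(degenerate))
         ),
         reference = as.numeric(reference), poly_order = poly_order,
         interferents = interferents),
    class = "emsc_fit"
  )
}

#' @export
print.emsc_fit <- function(x, ...) {
  cat(sprintf("<emsc_fit> %d spectra, poly order %d, %d interferent(s), %d degenerate\n",
              nrow(x$coefficients), x$poly_order,
              if (is.null(x$interferents)) 0L else ncol(as.matrix(x$interferents)),
              sum(x$coefficients$degenerate)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.emsc_fit <- function(x, ...) x$coefficients

#' @exportS3Method generics::glance
glance.emsc_fit <- function(x, ...) {
  tibble::tibble(n_spectra = nrow(x$coefficients),
                 poly_order = x$poly_order,
                 n_interferents = if (is.null(x$interferents)) 0L
                                  else ncol(as.matrix(x$interferents)),
                 n_degenerate = sum(x$coefficients$degenerate),
                 mean_scale = mean(x$coefficients$a))
}

#' Iterative EMSC with reference refresh
#'
#' Applies [fit_emsc()] `n_iter` times: the first pass corrects against the
#' dataset mean spectrum, and each subsequent pass recomputes the reference
#' as the mean of the previous pass's corrected spectra, so the reference
#' converges towards a scatter-free consensus spectrum.
#'
#' @inheritParams fit_emsc
#' @param n_iter number of reference-refresh passes (default 5)
#' @param min_scale flag threshold on the multiplicative scale `a`
#'   (default 0.05); flagged spectra are left uncorrected and excluded from
#'   the reference refresh, so near-blank rows cannot distort the consensus
#' @return the corrected `spectra_set`; the per-iteration root-mean-square
#'   change of the reference is stored in `attr(, "ref_change")` and the
#'   number of degenerate rows in the provenance log.
#' @export
iterative_emsc <- function(ds, n_iter = 5, poly_order = 2,
                           interferents = NULL, tol = 1e-8,
                           min_scale = 0.05) {
  if (n_spectra(ds) < 2) stop("iterative EMSC needs at least 2 spectra",
                              call. = FALSE)
  n_iter <- as.integer(n_iter)
  stopifnot(n_iter >= 1)
  current <- ds
  reference <- colMeans(ds$absorbance)
  ref_change <- numeric(n_iter)
  n_degenerate <- 0L
  for (i in seq_len(n_iter)) {
    fit <- fit_emsc(current, reference = reference, poly_order = poly_order,
                    interferents = interferents, tol = tol,
                    min_scale = min_scale)
    current <- fit$corrected
    flagged <- fit$coefficients$degenerate
    n_degenerate <- max(n_degenerate, sum(flagged))
    new_ref <- colMeans(current$absorbance[!flagged, , drop = FALSE])
    ref_change[i] <- sqrt(mean((new_ref - reference)^2))
    reference <- new_ref
  }
  current$log <- c(ds$log,
                   sprintf("iterative_emsc:n_iter=%d,poly=%d,degenerate=%d",
                           n_iter, poly_order, n_degenerate))
  attr(current, "ref_change") <- ref_change
  current
}
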