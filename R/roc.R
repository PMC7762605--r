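#' ROC curve from group scores
#'
#' Threshold sweep over all distinct scores (plus the two degenerate
#' endpoints), calling `score >= p` positive. The area under the curve is
#' computed by the trapezoid rule on the (1 - specificity, sensitivity)
#' path. Three operating points are annotated with their thresholds:
#' `A`, the maximum sensitivity with both metrics at or above the 70% target
#' region; `B`, the maximum specificity under the same constraint; and `C`,
#' the most balanced point (maximum of `min(sensitivity, specificity)`).
#'
#' @param scores group-level positive-class scores
#' @param labels true labels (`"mutated"` / `"wildtype"`)
#' @param target minimum sensitivity and specificity (percent) for the
#'   A and B annotations (default 70)
#' @return a `roc_curve`: `$points` (threshold, sensitivity, specificity in
#'   percent), `$auc`, `$annotations`.
#' @export
roc_curve <- function(scores, labels, target = 70) {
  labels <- as.character(labels)
  n_pos <- sum(labels == "mutated")
  n_neg <- sum(labels == "wildtype")
  if (n_pos == 0 || n_neg == 0) stop("ROC needs both classes present",
                                     call. = FALSE)
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pts <- purrr::map_dfr(thresholds, function(p) {
    pos <- scores >= p
    tibble::tibble(
      threshold = p,
      sensitivity = 100 * sum(pos & labels == "mutated") / n_pos,
      specificity = 100 * sum(!pos & labels == "wildtype") / n_neg
    )
  })
  x <- (100 - pts$specificity) / 100
  y <- pts$sensitivity / 100
  auc <- sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  ok <- pts$sensitivity >= target & pts$specificity >= target
  pick <- function(idx) {
    if (!length(idx)) return(tibble::tibble(threshold = NA_real_,
                                            sensitivity = NA_real_,
                                            specificity = NA_real_))
    pts[idx, c("threshold", "sensitivity", "specificity")]
  }
  a <- pick(which(ok)[order(-pts$sensitivity[ok], -pts$specificity[ok])][1])
  b <- pick(which(ok)[order(-pts$specificity[ok], -pts$sensitivity[ok])][1])
  bal <- pmin(pts$sensitivity, pts$specificity)
  c_pt <- pick(which.max(bal))
  ann <- dplyr::bind_rows(A = a, B = b, C = c_pt, .id = "point")
  structure(list(points = pts, auc = auc, annotations = ann),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d operating points, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.roc_curve <- function(x, ...) x$points

#' @exportS3Method generics::glance
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_points = nrow(x$points))
}

#' @exportS3Method ggplot2::autoplot
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(100 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(data = dplyr::filter(object$annotations,
                                             !is.na(.data$threshold)),
                        colour = "red") +
    ggplot2::geom_text(data = dplyr::filter(object$annotations,
                                            !is.na(.data$threshold)),
                       ggplot2::aes(label = .data$point),
                       nudge_x = 4, colour = "red") +
    ggplot2::labs(x = "100 - Specificity (%)", y = "Sensitivity (%)",
                  subtitle = sprintf("AUC = %.4f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Vertically averaged mean ROC curve
#'
#' Averages a list of ROC curves on a fixed 101-point specificity grid:
#' each curve's sensitivity is linearly interpolated as a function of
#' specificity, the interpolated sensitivities are averaged pointwise, and
#' the AUC of the mean curve is computed by the trapezoid rule.
#'
#' @param curves list of `roc_curve` objects
#' @return a `roc_curve` on the common specificity grid (thresholds are
#'   averaging artefacts and reported as `NA`).
#' @export
mean_roc <- function(curves) {
  if (!length(curves)) stop("mean_roc needs at least one curve",
                            call. = FALSE)
  spec_grid <- seq(0, 100, length.out = 101)
  sens_mat <- vapply(curves, function(cv) {
    p <- cv$points[order(cv$points$specificity), ]
    # the empirical ROC is a staircase in (specificity, sensitivity): at a
    # knot the attainable sensitivity is the maximum over its vertical
    # segment, and between knots it is the value carried from the
    # higher-specificity knot, so interpolate as a right-continuous step
    approx(p$specificity, p$sensitivity, xout = spec_grid,
           method = "constant", f = 1, ties = max, rule = 2)$y
  }, numeric(101))
  sens_mean <- rowMeans(sens_mat)
  pts <- tibble::tibble(threshold = NA_real_, sensitivity = sens_mean,
                        specificity = spec_grid)
  x <- (100 - spec_grid) / 100
  ord <- order(x)
  y <- sens_mean[ord] / 100
  auc <- sum(diff(x[ord]) * (head(y, -1) + y[-1]) / 2)
  bal <- pmin(pts$sensitivity, pts$specificity)
  ann <- tibble::tibble(point = "C", threshold = NA_real_,
                        sensitivity = pts$sensitivity[which.max(bal)],
                        specificity = pts$specificity[which.max(bal)])
  structure(list(points = pts, auc = auc, annotations = ann),
            class = "roc_curve")
}
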