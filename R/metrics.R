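#' Build a 2x2 confusion matrix
#'
#' Positive class is `mutated` throughout: sensitivity is the recall of
#' mutated samples, specificity the recall of wildtype samples.
#'
#' @param truth,call character vectors of `"mutated"` / `"wildtype"`
#' @return tibble with integer columns `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_matrix <- function(truth, call) {
  tibble::tibble(
    tp = sum(truth == "mutated" & call == "mutated"),
    fn = sum(truth == "mutated" & call == "wildtype"),
    fp = sum(truth == "wildtype" & call == "mutated"),
    tn = sum(truth == "wildtype" & call == "wildtype")
  )
}

#' Cohen's kappa from a 2x2 confusion matrix
#'
#' Chance-corrected agreement
#' \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with observed agreement
#' \eqn{p_o = (TP + TN)/N} and chance agreement
#' \eqn{p_e = [(TP+FN)(TP+FP) + (TN+FP)(TN+FN)]/N^2}. When every count sits
#' in one cell, \eqn{p_e = 1} and kappa is defined as 0 (degenerate
#' agreement carries no information beyond chance).
#'
#' @param cm one-row tibble or list with `tp`, `fn`, `fp`, `tn`
#' @return kappa (dimensionless, `<= 1`).
#' @export
#' @examples
#' cohen_kappa(list(tp = 6, fn = 1, fp = 2, tn = 24))  # ~0.7416
cohen_kappa <- function(cm) {
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  po <- (cm$tp + cm$tn) / n
  pe <- ((cm$tp + cm$fn) * (cm$tp + cm$fp) +
           (cm$tn + cm$fp) * (cm$tn + cm$fn)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) return(0)
  (po - pe) / (1 - pe)
}

#' Classification metrics from a confusion matrix
#'
#' @param cm one-row tibble or list with `tp`, `fn`, `fp`, `tn`; both row
#'   totals must be positive
#' @return one-row tibble: `sensitivity`, `specificity`,
#'   `balanced_accuracy` (percent, unrounded) and `kappa`. Rounding to one
#'   decimal (half up) is applied only at report time.
#' @export
metrics_from_confusion <- function(cm) {
  if (cm$tp + cm$fn == 0 || cm$tn + cm$fp == 0) {
    stop("metrics undefined: a class is absent from the evaluated set",
         call. = FALSE)
  }
  sens <- 100 * cm$tp / (cm$tp + cm$fn)
  spec <- 100 * cm$tn / (cm$tn + cm$fp)
  tibble::tibble(sensitivity = sens, specificity = spec,
                 balanced_accuracy = (sens + spec) / 2,
                 kappa = cohen_kappa(cm))
}

#' Kappa-optimal probability threshold
#'
#' Sweeps candidate thresholds at the midpoints between consecutive sorted
#' unique scores, plus 0 and 1, calling `score >= p` positive, and returns
#' the threshold maximising Cohen's kappa. Ties are broken toward the
#' candidate closest to 0.5.
#'
#' @param scores group-level positive-class scores
#' @param labels true labels (`"mutated"` / `"wildtype"`)
#' @return list with `threshold` and `kappa`.
#' @export
select_threshold_kappa <- function(scores, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present",
                                       call. = FALSE)
  u <- sort(unique(scores))
  if (length(u) < 2) stop("degenerate threshold selection: constant scores",
                          call. = FALSE)
  candidates <- unique(c(0, (u[-1] + u[-length(u)]) / 2, 1))
  kappas <- vapply(candidates, function(p) {
    cohen_kappa(confusion_matrix(labels,
                                 ifelse(scores >= p, "mutated", "wildtype")))
  }, numeric(1))
  best <- kappas >= max(kappas) - 1e-12
  pick <- which(best)[which.min(abs(candidates[best] - 0.5))]
  list(threshold = candidates[pick], kappa = kappas[pick])
}
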