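#' Resampled, group-aware evaluation of one pipeline
#'
#' For each resample `r`: split the groups 70:30 (stratified by class, seed
#' `base_seed + r`), apply class-imbalance sampling to the training spectra
#' only, train the classifier, aggregate per-spectrum probabilities to group
#' scores, choose the kappa-optimal probability threshold on the
#' training-side group scores (choosing it on the test side would leak),
#' and score the test groups. Pre-processing is applied once up front: every
#' step is per-spectrum and unsupervised, so this is identical to applying
#' it inside each resample. Resamples whose test side degenerates to one
#' class are redrawn with a derived seed (at most 10 times, logged).
#'
#' @param ds a `spectra_set` (post-QC)
#' @param preproc a [preproc_spec()] or canonical string
#' @param clf a [classifier_spec()]
#' @param n_resamples number of train/test partitions
#' @param group_col metadata column defining the voting group: `"group_id"`
#'   (tissue cores) or `"patient_id"` (serum)
#' @param base_seed seed base; resample `r` uses `base_seed + r`
#' @param agg_mode aggregation rule for group calls (see
#'   [aggregate_group()])
#' @param threshold fixed probability threshold; `NULL` (default) selects
#'   the kappa-optimal threshold per resample on the training groups
#' @param keep_rocs retain per-resample test ROC curves (memory)
#' @return a `resample_report`: `$metrics` (one row per resample),
#'   `$summary` (mean and SD per metric), `$rocs`, `$mean_roc`, and the
#'   pipeline descriptors.
#' @export
resample_evaluate <- function(ds, preproc = preproc_spec(),
                              clf = classifier_spec("lda"),
                              n_resamples = 11, group_col = "group_id",
                              base_seed = 1,
                              agg_mode = c("mean_prob", "majority_vote"),
                              threshold = NULL, keep_rocs = TRUE) {
  agg_mode <- match.arg(agg_mode)
  if (is.character(preproc)) preproc <- parse_preproc_spec(preproc)
  dsp <- apply_preproc(ds, preproc)
  x <- dsp$absorbance
  meta <- dsp$meta
  meta$group_id <- meta[[group_col]]
  labels <- meta$class_label

  one_resample <- function(r) {
    seed_r <- base_seed + r
    for (try in 0:10) {
      if (try == 10) stop("resample ", r, ": no valid split in 10 redraws",
                          call. = FALSE)
      seed_use <- if (try == 0) seed_r else derive_seed(seed_r,
                                                        paste0("redraw", try))
      plan <- grouped_split(meta, 0.7, seed = seed_use)
      in_train <- meta$group_id %in% plan$train_groups
      test_classes <- unique(labels[!in_train])
      if (length(test_classes) == 2) break
    }
    samp <- apply_sampling(x[in_train, , drop = FALSE], labels[in_train],
                           method = clf$sampling, seed = seed_use)
    model <- train_classifier(samp$x, samp$labels, clf, seed = seed_use)
    train_scores <- aggregate_group(predict(model, x[in_train, , drop = FALSE]),
                                    meta[in_train, ], mode = agg_mode,
                                    threshold = 0.5)
    p_star <- if (!is.null(threshold)) threshold else {
      tryCatch(select_threshold_kappa(train_scores$score,
                                      train_scores$class_label)$threshold,
               error = function(e) 0.5)
    }
    test_groups <- aggregate_group(predict(model, x[!in_train, , drop = FALSE]),
                                   meta[!in_train, ], mode = agg_mode,
                                   threshold = p_star)
    cm <- confusion_matrix(test_groups$class_label, test_groups$call)
    roc <- roc_curve(test_groups$score, test_groups$class_label)
    list(metrics = dplyr::bind_cols(
           tibble::tibble(resample = r, seed = seed_use,
                          threshold = p_star),
           metrics_from_confusion(cm),
           tibble::tibble(auc = roc$auc, tp = cm$tp, fn = cm$fn,
                          fp = cm$fp, tn = cm$tn)),
         roc = roc)
  }

  res <- lapply(seq_len(n_resamples), one_resample)
  metrics <- dplyr::bind_rows(lapply(res, `[[`, "metrics"))
  rocs <- lapply(res, `[[`, "roc")
  summary <- metrics |>
    dplyr::summarise(dplyr::across(
      c("sensitivity", "specificity", "balanced_accuracy", "kappa", "auc"),
      list(mean = mean, sd = sd)))
  structure(list(metrics = metrics, summary = summary,
                 rocs = if (keep_rocs) rocs else NULL,
                 mean_roc = mean_roc(rocs),
                 preproc = format(preproc), classifier = format(clf),
                 sampling = clf$sampling, n_resamples = n_resamples,
                 group_col = group_col, agg_mode = agg_mode,
                 base_seed = base_seed),
            class = "resample_report")
}

#' @export
print.resample_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<resample_report> %s / %s, %d resamples (groups: %s)\n",
              x$preproc, x$classifier, x$n_resamples, x$group_col))
  cat(sprintf("  sensitivity %.1f +/- %.1f  specificity %.1f +/- %.1f\n",
              round_half_up(s$sensitivity_mean), s$sensitivity_sd,
              round_half_up(s$specificity_mean), s$specificity_sd))
  cat(sprintf("  balanced accuracy %.1f +/- %.1f  kappa %.2f  AUC %.4f\n",
              round_half_up(s$balanced_accuracy_mean),
              s$balanced_accuracy_sd, s$kappa_mean, s$auc_mean))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.resample_report <- function(x, ...) x$metrics

#' @exportS3Method generics::glance
glance.resample_report <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(preproc = x$preproc,
                                  classifier = x$classifier,
                                  sampling = x$sampling,
                                  n_resamples = x$n_resamples),
                   x$summary,
                   tibble::tibble(mean_roc_auc = x$mean_roc$auc))
}

#' @exportS3Method ggplot2::autoplot
autoplot.resample_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$metrics[, c("resample", "sensitivity", "specificity",
                       "balanced_accuracy")],
    -"resample", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "Percent",
                  subtitle = sprintf("%s / %s, %d resamples", object$preproc,
                                     object$classifier,
                                     object$n_resamples)) +
    ggplot2::theme_minimal()
}

#' Pre-processing grid search
#'
#' Evaluates every pipeline of a pre-processing grid with
#' [resample_evaluate()] and ranks by mean kappa (ties broken by mean
#' balanced accuracy, then by the canonical spec string). Individual
#' pipeline failures are recorded, not fatal.
#'
#' @param ds a `spectra_set` (post-QC)
#' @param grid tibble from [preproc_grid()] (a `spec` column of canonical
#'   strings)
#' @param clf a [classifier_spec()]
#' @param n_resamples resamples per pipeline (default 11)
#' @param group_col voting-group column
#' @param base_seed shared seed base, so pipelines see identical splits
#' @param verbose print progress every 25 pipelines
#' @return a `grid_result` tibble: one row per spec with mean metrics and
#'   `rank` (failed specs carry `NA` metrics and an `error` message).
#' @export
run_grid <- function(ds, grid = preproc_grid(),
                     clf = classifier_spec("lda"), n_resamples = 11,
                     group_col = "group_id", base_seed = 1,
                     verbose = FALSE) {
  if (!nrow(grid)) stop("empty grid definition", call. = FALSE)
  rows <- purrr::imap(grid$spec, function(s, i) {
    if (verbose && i %% 25 == 0) message("grid ", i, "/", nrow(grid))
    rep <- tryCatch(
      resample_evaluate(ds, s, clf, n_resamples = n_resamples,
                        group_col = group_col, base_seed = base_seed,
                        keep_rocs = FALSE),
      error = function(e) e)
    if (inherits(rep, "error")) {
      tibble::tibble(spec = s, kappa = NA_real_, sensitivity = NA_real_,
                     specificity = NA_real_, balanced_accuracy = NA_real_,
                     auc = NA_real_, error = conditionMessage(rep))
    } else {
      s_ <- rep$summary
      tibble::tibble(spec = s, kappa = s_$kappa_mean,
                     sensitivity = s_$sensitivity_mean,
                     specificity = s_$specificity_mean,
                     balanced_accuracy = s_$balanced_accuracy_mean,
                     auc = s_$auc_mean, error = NA_character_)
    }
  })
  out <- dplyr::bind_rows(rows)
  if (all(!is.na(out$error))) stop("every grid pipeline failed",
                                   call. = FALSE)
  out <- out |>
    dplyr::arrange(dplyr::desc(.data$kappa),
                   dplyr::desc(.data$balanced_accuracy), .data$spec) |>
    dplyr::mutate(rank = dplyr::row_number())
  class(out) <- c("grid_result", class(out))
  out
}

#' Refine the top grid pipelines with more resamples and sampling methods
#'
#' Re-evaluates the `k` best-ranked pre-processing pipelines of a grid
#' search at a higher resample count, crossed with the class-imbalance
#' sampling methods; the increased resample count shrinks the variance of
#' the mean metric estimates.
#'
#' @param grid a `grid_result` from [run_grid()]
#' @param ds the same `spectra_set` the grid was run on
#' @param k number of top pipelines to refine (default 10)
#' @param n_resamples resamples per refinement cell (default 51)
#' @param sampling_methods sampling methods to cross with each pipeline
#' @param family classifier family
#' @param group_col voting-group column
#' @param base_seed seed base shared across cells
#' @return tibble with one row per (spec, sampling) cell: mean and SD
#'   metrics, ranked by mean kappa; the full `resample_report` objects are
#'   in `attr(, "reports")`.
#' @export
top_k_refinement <- function(grid, ds, k = 10, n_resamples = 51,
                             sampling_methods = c("none", "up", "down",
                                                  "smote"),
                             family = "lda", group_col = "group_id",
                             base_seed = 1) {
  ok <- grid[is.na(grid$error), ]
  if (nrow(ok) < k) stop("grid has fewer than k successful rows",
                         call. = FALSE)
  top <- ok$spec[order(ok$rank)][seq_len(k)]
  cells <- tidyr::expand_grid(spec = top, sampling = sampling_methods)
  reports <- purrr::pmap(cells, function(spec, sampling) {
    resample_evaluate(ds, spec, classifier_spec(family, sampling = sampling),
                      n_resamples = n_resamples, group_col = group_col,
                      base_seed = base_seed, keep_rocs = FALSE)
  })
  out <- dplyr::bind_cols(cells,
                          dplyr::bind_rows(lapply(reports, `[[`, "summary")))
  out <- out |>
    dplyr::arrange(dplyr::desc(.data$kappa_mean)) |>
    dplyr::mutate(rank = dplyr::row_number())
  attr(out, "reports") <- reports
  out
}

#' Class difference spectrum with annotated extrema
#'
#' Mean spectrum of `class_a` minus mean spectrum of `class_b`, with local
#' extrema located (interior sign changes of the first difference, filtered
#' to at least `min_prominence` of the largest excursion) and matched to the
#' nearest entry of the built-in [band_assignments()] table within
#' 12 cm^-1.
#'
#' @param ds a `spectra_set`
#' @param class_a,class_b class labels (defaults mutated - wildtype)
#' @param min_prominence minimum |difference| of a reported extremum,
#'   relative to the maximum |difference| (default 0.15)
#' @return a `difference_spectrum`: `$spectrum` tibble (wavenumber,
#'   difference) and `$extrema` tibble (wavenumber, difference, type,
#'   assignment).
#' @export
difference_spectrum <- function(ds, class_a = "mutated",
                                class_b = "wildtype",
                                min_prominence = 0.15) {
  ma <- ds$meta$class_label == class_a
  mb <- ds$meta$class_label == class_b
  if (!any(ma) || !any(mb)) stop("both classes must be present",
                                 call. = FALSE)
  d <- colMeans(ds$absorbance[ma, , drop = FALSE]) -
    colMeans(ds$absorbance[mb, , drop = FALSE])
  spectrum <- tibble::tibble(wavenumber = ds$grid, difference = unname(d))
  slope <- diff(d)
  s <- sign(slope)
  turn <- which(s[-1] != s[-length(s)] & s[-1] != 0) + 1L
  cut <- min_prominence * max(abs(d))
  turn <- turn[abs(d[turn]) >= cut]
  assign_tbl <- band_assignments()
  extrema <- tibble::tibble(
    wavenumber = ds$grid[turn],
    difference = unname(d[turn]),
    type = ifelse(d[turn] >= 0, "maximum", "minimum"),
    assignment = vapply(ds$grid[turn], function(w) {
      i <- which.min(abs(assign_tbl$wavenumber - w))
      if (abs(assign_tbl$wavenumber[i] - w) <= 12) assign_tbl$assignment[i]
      else NA_character_
    }, character(1))
  ) |> dplyr::arrange(dplyr::desc(abs(.data$difference)))
  structure(list(spectrum = spectrum, extrema = extrema,
                 classes = c(class_a, class_b)),
            class = "difference_spectrum")
}

#' @export
print.difference_spectrum <- function(x, ...) {
  cat(sprintf("<difference_spectrum> %s - %s, %d annotated extrema\n",
              x$classes[1], x$classes[2], nrow(x$extrema)))
  print(head(x$extrema, 8))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.difference_spectrum <- function(x, ...) x$spectrum

#' @exportS3Method ggplot2::autoplot
autoplot.difference_spectrum <- function(object, ...) {
  ggplot2::ggplot(object$spectrum,
                  ggplot2::aes(.data$wavenumber, .data$difference)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$extrema, colour = "red", size = 1) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)),
                  y = sprintf("Mean %s - mean %s (AU)", object$classes[1],
                              object$classes[2])) +
    ggplot2::theme_minimal()
}
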