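#' Default end-to-end run configurations
#'
#' Assembles a `run_config` reproducing the shape of the two study
#' workflows:
#'
#' * `"tissue"`: synthetic synchrotron cohort (79 patients, 99 cores),
#'   iterative EMSC (5 passes), PCA and Amide I quality gates, the full
#'   576-cell pre-processing grid at 11 resamples with LDA, then top-10
#'   refinement at 51 resamples crossed with the four sampling methods,
#'   voting by core.
#' * `"serum"`: synthetic ATR serum cohort (72 patients, both fractions),
#'   single-pass EMSC against the pooled fraction mean, spectral cuts
#'   1800-1000 (whole serum) and 4000-800 / 1800-800 / 1800-1000
#'   (filtrate), RF, PLS-DA and SVM at 100 resamples, voting by patient.
#'
#' The full defaults are long-running research modes; `run_pipeline()`
#' accepts reduced grids and resample counts for routine use.
#'
#' @param mode `"tissue"` or `"serum"`
#' @param seed master seed
#' @return a `run_config` list.
#' @export
make_paper_defaults <- function(mode = c("tissue", "serum"), seed = 1) {
  mode <- match.arg(mode)
  if (mode == "tissue") {
    structure(list(
      mode = "tissue",
      synth = synthetic_config("tissue", seed = seed),
      emsc = list(n_iter = 5, poly_order = 2),
      qc = list(pca_quantile = 0.99, amide_low = 0.01, amide_high = 2),
      grid = preproc_grid(),
      best_spec = "n=minmax|l=0|b=4|s=3|p=1800-1200",
      classifier = "lda",
      n_resamples_grid = 11, n_resamples_refine = 51, refine_k = 10,
      sampling_methods = c("none", "up", "down", "smote"),
      group_col = "group_id", seed = seed
    ), class = "run_config")
  } else {
    structure(list(
      mode = "serum",
      synth = synthetic_config("serum", seed = seed),
      emsc = list(poly_order = 2),
      analyses = tidyr::expand_grid(
        fraction = c("whole_serum", "filtrate"),
        cut = c("1800-1000", "4000-800", "1800-800"),
        family = c("rf", "plsda", "svm")
      ) |> dplyr::filter(.data$fraction == "filtrate" |
                           .data$cut == "1800-1000"),
      n_resamples = 100,
      group_col = "patient_id", seed = seed
    ), class = "run_config")
  }
}

write_stage_csv <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  readr::write_csv(df, path, progress = FALSE)
  path
}

#' Run the full pipeline and write report artefacts
#'
#' Executes simulate, QC, grid search, refinement and final evaluation in
#' order, logging counts per stage, and writes CSV artefacts plus a
#' human-readable summary under `out_dir`. Deterministic for a fixed
#' (config, seed).
#'
#' @param config a `run_config` from [make_paper_defaults()]
#' @param out_dir output directory (created if needed)
#' @param grid optional pre-processing grid tibble overriding
#'   `config$grid` (e.g. a reduced grid)
#' @param n_resamples_grid,n_resamples_refine,refine_k,n_resamples optional
#'   overrides of the corresponding config entries
#' @param verbose print one line per stage
#' @return (invisibly) a list of stage results: `data`, `qc`, `grid`,
#'   `refinement`, `final`, `files`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("gliospec_run_"),
                         grid = NULL, n_resamples_grid = NULL,
                         n_resamples_refine = NULL, refine_k = NULL,
                         n_resamples = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  files <- character()
  t0 <- Sys.time()

  say("[simulate] scenario=%s seed=%d", config$synth$scenario, config$seed)
  ds <- generate_cohort(config$synth)
  say("[simulate] %d spectra, %d groups", n_spectra(ds),
      dplyr::n_distinct(ds$meta$group_id))

  if (config$mode == "tissue") {
    ds_corr <- iterative_emsc(ds, n_iter = config$emsc$n_iter,
                              poly_order = config$emsc$poly_order)
    n0 <- n_spectra(ds_corr)
    ds_pca <- pca_quality_filter(ds_corr, config$qc$pca_quantile)
    pca_rep <- qc_report(ds_pca)
    ds_qc <- amide1_filter(ds_pca, config$qc$amide_low, config$qc$amide_high)
    amide_rep <- qc_report(ds_qc)
    qc_counts <- tibble::tibble(
      stage = c("input", "pca_quality_filter", "amide1_filter"),
      n_removed = c(0L, sum(!pca_rep$kept), sum(!amide_rep$kept)),
      n_retained = c(n0, n_spectra(ds_pca), n_spectra(ds_qc))
    )
    say("[qc] retained %d of %d spectra", n_spectra(ds_qc), n0)
    files["qc"] <- write_stage_csv(qc_counts, out_dir, "qc_counts.csv")

    grid_def <- grid %||% config$grid
    g <- run_grid(ds_qc, grid_def, classifier_spec(config$classifier),
                  n_resamples = n_resamples_grid %||%
                    config$n_resamples_grid,
                  group_col = config$group_col, base_seed = config$seed)
    say("[grid] %d pipelines, best kappa %.3f (%s)", nrow(g), g$kappa[1],
        g$spec[1])
    files["grid"] <- write_stage_csv(tibble::as_tibble(g), out_dir,
                                     "grid.csv")

    k <- min(refine_k %||% config$refine_k, sum(is.na(g$error)))
    refined <- top_k_refinement(g, ds_qc, k = k,
                                n_resamples = n_resamples_refine %||%
                                  config$n_resamples_refine,
                                sampling_methods = config$sampling_methods,
                                family = config$classifier,
                                group_col = config$group_col,
                                base_seed = config$seed)
    say("[refine] best cell: %s + %s, kappa %.3f", refined$spec[1],
        refined$sampling[1], refined$kappa_mean[1])
    files["refinement"] <- write_stage_csv(tibble::as_tibble(refined),
                                           out_dir, "refinement.csv")

    best <- resample_evaluate(
      ds_qc, refined$spec[1],
      classifier_spec(config$classifier, sampling = refined$sampling[1]),
      n_resamples = n_resamples_refine %||% config$n_resamples_refine,
      group_col = config$group_col, base_seed = config$seed)
    files["metrics"] <- write_stage_csv(tidy(best), out_dir, "metrics.csv")
    files["roc"] <- write_stage_csv(best$mean_roc$points, out_dir,
                                    "roc_points.csv")
    dspec <- difference_spectrum(apply_preproc(ds_qc, refined$spec[1]))
    files["diff"] <- write_stage_csv(
      dplyr::left_join(dspec$spectrum,
                       dspec$extrema[, c("wavenumber", "type", "assignment")],
                       by = "wavenumber"),
      out_dir, "difference_spectrum.csv")
    final <- best
    refinement <- refined
    qc_out <- qc_counts
  } else {
    results <- purrr::pmap(config$analyses, function(fraction, cut, family) {
      sub <- filter_spectra(ds, ds$meta$fraction == fraction)
      sub <- fit_emsc(sub, reference = colMeans(sub$absorbance),
                      poly_order = config$emsc$poly_order)$corrected
      rep <- resample_evaluate(
        sub, preproc_spec("none", 0, 1, 0, cut),
        classifier_spec(family),
        n_resamples = n_resamples %||% config$n_resamples,
        group_col = config$group_col, base_seed = config$seed,
        keep_rocs = FALSE)
      dplyr::bind_cols(tibble::tibble(fraction = fraction, cut = cut,
                                      classifier = family),
                       rep$summary,
                       tibble::tibble(mean_roc_auc = rep$mean_roc$auc))
    })
    final <- dplyr::bind_rows(results)
    say("[serum] %d analysis cells evaluated", nrow(final))
    files["serum"] <- write_stage_csv(final, out_dir, "serum_metrics.csv")
    qc_out <- NULL
    g <- NULL
    refinement <- NULL
  }

  summary_path <- file.path(out_dir, "summary.txt")
  lines <- c(sprintf("gliospec run (%s mode), seed %d", config$mode,
                     config$seed),
             sprintf("spectra generated: %d", n_spectra(ds)),
             if (config$mode == "tissue") c(
               sprintf("spectra after QC: %d",
                       qc_out$n_retained[nrow(qc_out)]),
               sprintf("grid pipelines: %d", nrow(g)),
               sprintf("best pipeline: %s + %s", refinement$spec[1],
                       refinement$sampling[1]),
               sprintf("balanced accuracy: %.1f +/- %.1f",
                       round_half_up(final$summary$balanced_accuracy_mean),
                       final$summary$balanced_accuracy_sd),
               sprintf("mean ROC AUC: %.4f", final$mean_roc$auc)),
             sprintf("elapsed: %.1f s",
                     as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  writeLines(lines, summary_path)
  files["summary"] <- summary_path
  invisible(list(data = ds, qc = qc_out, grid = g, refinement = refinement,
                 final = final, files = files))
}
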