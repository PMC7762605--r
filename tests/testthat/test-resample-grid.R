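test_that("preproc spec strings round-trip bit-exactly and enumerate fully", {
  s <- preproc_spec("minmax", 0, 4, 3, "1800-1200")
  expect_identical(format(s), "n=minmax|l=0|b=4|s=3|p=1800-1200")
  expect_identical(format(parse_preproc_spec(format(s))), format(s))
  for (str in c("n=none|l=2|b=8|s=0|p=none", "n=vector|l=1|b=1|s=2|p=1800-1000",
                "n=amide1|l=0|b=2|s=4|p=1800-1200")) {
    expect_identical(format(parse_preproc_spec(str)), str)
  }
  expect_error(parse_preproc_spec("n=minmax|b=4"), "malformed")

  expect_equal(nrow(preproc_grid()), 576L)
  sub <- preproc_grid(normalisation = c("none", "minmax"), derivative = 0,
                      binning = 4, smoothing = 3, cut = "none")
  expect_equal(nrow(sub), 2L)
  # grid rows = product of level counts for any definition
  g2 <- preproc_grid(normalisation = c("none", "vector"),
                     derivative = c(0, 1), binning = c(1, 2),
                     smoothing = 0, cut = c("none", "1800-1200"))
  expect_equal(nrow(g2), 2 * 2 * 2 * 1 * 2)
  expect_false(anyDuplicated(g2$spec) > 0)
})

test_that("a single resample reduces to one split evaluation", {
  ds <- tissue_qc_small()
  rep1 <- resample_evaluate(ds, "n=minmax|l=0|b=4|s=3|p=1800-1200",
                            classifier_spec("lda"), n_resamples = 1,
                            base_seed = 5)
  expect_equal(nrow(rep1$metrics), 1L)
  expect_equal(rep1$summary$balanced_accuracy_mean,
               rep1$metrics$balanced_accuracy)
  expect_true(is.na(rep1$summary$balanced_accuracy_sd))
  expect_equal(rep1$metrics$balanced_accuracy,
               (rep1$metrics$sensitivity + rep1$metrics$specificity) / 2)
  # group-level confusion totals match the test-side group count
  n_test_groups <- with(rep1$metrics, tp + fn + fp + tn)
  expect_equal(n_test_groups,
               length(grouped_split(ds$meta, 0.7,
                                    seed = 5 + 1)$test_groups))
})

test_that("balanced accuracy identity holds across every resample row", {
  ds <- tissue_qc_small()
  rep <- resample_evaluate(ds, "n=minmax|l=0|b=4|s=3|p=1800-1200",
                           classifier_spec("lda", sampling = "up"),
                           n_resamples = 8, base_seed = 2)
  expect_equal(rep$metrics$balanced_accuracy,
               (rep$metrics$sensitivity + rep$metrics$specificity) / 2)
  expect_true(all(rep$metrics$threshold >= 0 & rep$metrics$threshold <= 1))
  expect_equal(nrow(rep$metrics), 8L)
  expect_s3_class(rep$mean_roc, "roc_curve")
  g <- glance(rep)
  expect_tibble_cols(g, c("preproc", "classifier", "balanced_accuracy_mean",
                          "mean_roc_auc"))
})

test_that("grid search ranks by kappa with a sort-oracle check", {
  ds <- tissue_qc_small()
  sub <- preproc_grid(normalisation = c("none", "minmax"),
                      derivative = c(0, 1), binning = 4, smoothing = 3,
                      cut = "1800-1200")
  g <- run_grid(ds, sub, n_resamples = 3, base_seed = 4)
  expect_equal(nrow(g), 4L)
  expect_equal(g$rank, 1:4)
  resorted <- dplyr::arrange(tibble::as_tibble(g), dplyr::desc(kappa),
                             dplyr::desc(balanced_accuracy), spec)
  expect_identical(g$spec, resorted$spec)
})

test_that("top-k refinement crosses pipelines with sampling methods", {
  ds <- tissue_qc_small()
  sub <- preproc_grid(normalisation = c("none", "minmax"), derivative = 0,
                      binning = 4, smoothing = 3, cut = "1800-1200")
  g <- run_grid(ds, sub, n_resamples = 3, base_seed = 4)

  ref1 <- top_k_refinement(g, ds, k = 1, n_resamples = 3,
                           sampling_methods = "up", base_seed = 4)
  expect_equal(nrow(ref1), 1L)

  ref <- top_k_refinement(g, ds, k = 2, n_resamples = 4,
                          sampling_methods = c("none", "up"), base_seed = 4)
  expect_equal(nrow(ref), 2 * 2)
  expect_true(all(diff(ref$kappa_mean) <= 1e-12))

  # more resamples shrink the spread of the mean estimate on fixed data
  reports <- attr(ref, "reports")
  expect_equal(reports[[1]]$n_resamples, 4L)
  se4 <- ref$balanced_accuracy_sd[1] / sqrt(4)
  ref16 <- top_k_refinement(g, ds, k = 1, n_resamples = 12,
                            sampling_methods = ref$sampling[1],
                            base_seed = 4)
  se16 <- ref16$balanced_accuracy_sd[1] / sqrt(12)
  expect_lt(se16, 2 * se4)
})

test_that("difference spectra vanish under identical classes and annotate
          known bands", {
  ds <- tissue_qc_small()
  same <- ds
  same$meta$class_label <- "mutated"
  same$meta$class_label[1:5] <- "wildtype"
  sub <- filter_spectra(same, 1:10)
  sub$absorbance[6:10, ] <- sub$absorbance[1:5, ]
  sub$meta$class_label <- rep(c("wildtype", "mutated"), each = 5)
  d0 <- difference_spectrum(sub)
  expect_equal(max(abs(d0$spectrum$difference)), 0)

  # Amide I sub-band structure: clean generated cohort with the class effect
  clean <- generate_cohort(synthetic_config(
    "tissue", n_patients = 40, n_groups = 60, spectra_per_group = c(15, 15),
    grid_range = c(1800, 1000), effect_scale = 0.05, class_balance = 0.5,
    blank_rate = 0, saturated_rate = 0, mie_amp = 0, baseline_amp = 0,
    scale_sdlog = 0, seed = 6))
  d <- difference_spectrum(clean)
  expect_s3_class(tidy(d), "tbl_df")
  neg <- d$extrema[d$extrema$type == "minimum", ]
  pos <- d$extrema[d$extrema$type == "maximum", ]
  expect_true(any(abs(neg$wavenumber - 1660) <= 10))
  expect_true(any(abs(pos$wavenumber - 1615) <= 10))
  # the QC'd noisy cohort still shows the alpha-helix deficit
  dq <- difference_spectrum(ds)
  expect_true(any(abs(dq$extrema$wavenumber[dq$extrema$type == "minimum"] -
                        1660) <= 14))

  ds_no_b <- filter_spectra(ds, ds$meta$class_label != "wildtype")
  expect_error(difference_spectrum(ds_no_b), "both classes")
})

test_that("the 1740 lipid band annotation resolves from the built-in table", {
  tbl <- band_assignments()
  i <- which.min(abs(tbl$wavenumber - 1740))
  expect_identical(tbl$assignment[i], "Lipids; C = O stretch")
})
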