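# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# small deterministic spectra_set on a 1800-1000 grid (201 points)
toy_set <- function(n = 5, seed = 42, grid = seq(1800, 1000, by = -4)) {
  set.seed(seed)
  mat <- matrix(runif(n * length(grid), 0.1, 1), nrow = n)
  spectra_set(grid, mat,
              tibble::tibble(spectrum_id = sprintf("s%02d", seq_len(n)),
                             patient_id = sprintf("p%d", rep_len(1:3, n)),
                             group_id = sprintf("g%d", rep_len(1:3, n)),
                             class_label = rep_len(c("mutated", "wildtype"),
                                                   n)))
}

# Gaussian-band spectrum for structural tests
band_profile <- function(grid, centres, fwhm, amps) {
  sig2 <- (fwhm / (2 * sqrt(2 * log(2))))^2
  rowSums(vapply(seq_along(centres), function(j) {
    amps[j] * exp(-(grid - centres[j])^2 / (2 * sig2[j]))
  }, numeric(length(grid))))
}

# full-size calibrated tissue cohort (79 patients, 99 cores) with contaminants
tissue_cohort_full <- function() {
  cached("tissue_full",
         function() generate_cohort(synthetic_config("tissue", seed = 1)))
}

# the same cohort after scatter correction and both QC gates
tissue_qc_full <- function() {
  cached("tissue_qc", function() {
    amide1_filter(pca_quality_filter(iterative_emsc(tissue_cohort_full())))
  })
}

# mid-sized tissue cohort for classification tests (fast but has signal)
tissue_qc_small <- function() {
  cached("tissue_qc_small", function() {
    cfg <- synthetic_config("tissue", n_patients = 24, n_groups = 30,
                            spectra_per_group = c(15, 20),
                            grid_range = c(1800, 1000), mie_amp = 0.3,
                            blank_rate = 0.05, saturated_rate = 0.02,
                            seed = 7)
    amide1_filter(pca_quality_filter(iterative_emsc(generate_cohort(cfg))))
  })
}

expect_tibble_cols <- function(x, cols) {
  testthat::expect_s3_class(x, "tbl_df")
  testthat::expect_true(all(cols %in% names(x)))
}
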