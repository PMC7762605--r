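make_ds <- function(rows, grid = seq(1800, 1000, by = -4)) {
  spectra_set(grid, do.call(rbind, rows),
              tibble::tibble(spectrum_id = sprintf("s%d", seq_along(rows))))
}

test_that("normalisation methods hit their exact targets", {
  grid <- c(1700, 1650, 1600)
  ds <- make_ds(list(c(2, 4, 6), c(3, 4, 0)), grid = grid)

  mm <- normalise(ds, "minmax")
  expect_equal(mm$absorbance[1, ], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_true(all(apply(mm$absorbance, 1, min) == 0))
  expect_true(all(apply(mm$absorbance, 1, max) == 1))

  vec <- normalise(make_ds(list(c(3, 4, 0)), grid = grid), "vector")
  expect_equal(vec$absorbance[1, ], c(0.6, 0.8, 0), ignore_attr = TRUE)
  expect_equal(sqrt(sum(vec$absorbance^2)), 1)

  am <- normalise(ds, "amide1")
  expect_equal(am$absorbance[, 2], c(1, 1), ignore_attr = TRUE)

  none <- normalise(ds, "none")
  expect_identical(none$absorbance, ds$absorbance)

  expect_error(normalise(make_ds(list(c(1, 1, 1)), grid = grid), "minmax"),
               "constant")
})

test_that("binning averages blocks on both axes and drops the remainder", {
  grid4 <- c(1712, 1708, 1704, 1700)
  ds <- make_ds(list(c(1, 2, 3, 4)), grid = grid4)
  b2 <- bin_spectrum(ds, 2)
  expect_equal(b2$absorbance[1, ], c(1.5, 3.5), ignore_attr = TRUE)
  expect_equal(b2$grid, c(1710, 1702))

  expect_identical(bin_spectrum(ds, 1)$absorbance, ds$absorbance)

  grid10 <- seq(1736, 1700, by = -4)
  ds10 <- make_ds(list(1:10), grid = grid10)
  b4 <- bin_spectrum(ds10, 4)
  expect_length(b4$grid, 2L)  # 10 %/% 4; trailing 2 points dropped
  expect_equal(b4$absorbance[1, ], c(2.5, 6.5), ignore_attr = TRUE)
  expect_error(bin_spectrum(ds10, 16), "exceeds")
})

test_that("Savitzky-Golay s=3 is the 7-point order-4 filter and reproduces
          polynomials and derivatives", {
  grid <- seq(1800, 1000, by = -4)
  x <- seq_along(grid)
  # degree-4 polynomial is invariant under window 7 / order 4 smoothing
  poly4 <- 1e-6 * x^4 - 3e-4 * x^3 + 0.01 * x^2 - x + 2
  ds <- make_ds(list(poly4), grid = grid)
  sm <- savgol(ds, s = 3, deriv = 0)
  interior <- 8:(length(grid) - 8)
  expect_lt(max(abs(sm$absorbance[1, interior] - poly4[interior])), 1e-9)

  # linear ramp in wavenumber: first derivative is the slope everywhere
  slope <- 0.002
  ramp <- make_ds(list(slope * ds$grid), grid = grid)
  d1 <- savgol(ramp, s = 3, deriv = 1)
  expect_equal(d1$absorbance[1, interior], rep(slope, length(interior)),
               tolerance = 1e-8, ignore_attr = TRUE)

  # s = 2 caps the order at 2s - 1 = 3: degree-3 invariance
  poly3 <- 2e-4 * x^3 - 0.05 * x^2 + x
  s2 <- savgol(make_ds(list(poly3), grid = grid), s = 2, deriv = 0)
  expect_lt(max(abs(s2$absorbance[1, interior] - poly3[interior])), 1e-9)

  # derivative with smoothing "none" uses the fallback stencil, not an error
  fallback <- savgol(ramp, s = 0, deriv = 1)
  expect_equal(fallback$absorbance[1, interior],
               rep(slope, length(interior)), tolerance = 1e-8,
               ignore_attr = TRUE)

  short <- make_ds(list(1:3), grid = c(1708, 1704, 1700))
  expect_error(savgol(short, s = 3, deriv = 0), "window")
})

test_that("spectral cuts keep inclusive windows with the expected counts", {
  ds <- toy_set(n = 2)  # 1800..1000 step 4
  cut1 <- spectral_cut(ds, "1800-1200")
  expect_length(cut1$grid, 151L)  # (1800-1200)/4 + 1
  expect_identical(spectral_cut(ds, "1800-1000")$absorbance, ds$absorbance)

  serum_grid <- seq(4000, 450, by = -1)
  big <- spectra_set(serum_grid, matrix(1, 1, length(serum_grid)),
                     tibble::tibble(spectrum_id = "a"))
  expect_length(spectral_cut(big, "1800-1000")$grid, 801L)
  expect_error(spectral_cut(ds, c(100, 200)), "no grid points")
})

test_that("apply_preproc composes the steps in the documented order", {
  ds <- toy_set(n = 4)
  ident <- apply_preproc(ds, preproc_spec())
  expect_equal(ident$absorbance, ds$absorbance, ignore_attr = TRUE)

  best <- "n=minmax|l=0|b=4|s=3|p=1800-1200"
  out <- apply_preproc(ds, best)
  expect_true(all(out$grid >= 1200 & out$grid <= 1800))
  expect_true(any(grepl(best, out$log, fixed = TRUE)))

  # order matters on an asymmetric pipeline: cut-then-normalise differs from
  # normalise-then-cut
  spec <- preproc_spec("minmax", 0, 1, 0, "1800-1400")
  a <- apply_preproc(ds, spec)
  b <- apply_preproc(ds, spec, order = c("cut", "normalise", "bin", "savgol"))
  expect_false(isTRUE(all.equal(a$absorbance, b$absorbance)))

  expect_error(apply_preproc(ds, preproc_spec("minmax", 0, 512, 0, "none")),
               "binning")
})

test_that("binning commutes with cutting when boundaries align", {
  ds <- toy_set(n = 3)
  # 1800-1400 spans 101 points; with b = 2 the blocks align pairwise
  a <- spectral_cut(bin_spectrum(ds, 2), c(1402, 1800))
  b <- bin_spectrum(spectral_cut(ds, c(1403, 1800)), 2)
  expect_equal(a$grid, b$grid)
  expect_equal(a$absorbance, b$absorbance, ignore_attr = TRUE)
})

test_that("substrate subtraction is exact rowwise subtraction", {
  ds <- toy_set(n = 3)
  zero <- rep(0, length(ds$grid))
  expect_identical(subtract_substrate(ds, zero)$absorbance, ds$absorbance)

  sub <- ds$absorbance[2, ]
  out <- subtract_substrate(ds, sub)
  expect_equal(unname(out$absorbance[2, ]), rep(0, length(ds$grid)))
  expect_equal(out$absorbance, sweep(ds$absorbance, 2, sub),
               ignore_attr = TRUE)
  expect_error(subtract_substrate(ds, rep(0, 10)), "grid")
})
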