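make_spectra <- function(foldedness, titrant_uM = c(0, 5, 25),
                         band_amp = 10) {
  wl <- 225:325
  shape <- band_amp * exp(-(wl - 262)^2 / 72)
  purrr::map2(titrant_uM, foldedness, function(cc, ff) {
    tibble::tibble(titrant_uM = cc, wavelength_nm = wl,
      ellipticity = ff * shape)
  }) |>
    purrr::list_rbind()
}

test_that("molar ellipticity normalization follows the CD convention", {
  expect_equal(molar_ellipticity(10, 1, 5e-6, 24), 10 / (10 * 1 * 5e-6 * 24))
  expect_equal(molar_ellipticity(0, 1, 5e-6, 24), 0)
  # doubling the concentration halves the normalized signal
  expect_equal(molar_ellipticity(10, 1, 1e-5, 24),
    molar_ellipticity(10, 1, 5e-6, 24) / 2)
  expect_error(molar_ellipticity(10, 0, 5e-6, 24), class = "quadbind_input_error")
})

test_that("foldedness is the 262 nm ratio to the protein-free spectrum", {
  fc <- foldedness_curve(make_spectra(c(1, 1, 1)))
  expect_equal(fc$foldedness, rep(1, 3))
  fc2 <- foldedness_curve(make_spectra(c(1, 0.8, 0.5)))
  expect_equal(fc2$foldedness, c(1, 0.8, 0.5), tolerance = 1e-12)
  # no protein-free reference -> error
  bad <- dplyr::filter(make_spectra(c(1, 0.8, 0.5)), titrant_uM > 0)
  expect_error(foldedness_curve(bad), class = "quadbind_input_error")
})

test_that("foldedness is invariant to an instrument gain common to all spectra", {
  sp <- sim_cd_titration(seed = 21)
  sp_gain <- dplyr::mutate(sp, ellipticity = ellipticity * 3.7)
  expect_equal(foldedness_curve(sp)$foldedness,
    foldedness_curve(sp_gain)$foldedness, tolerance = 1e-12)
})

test_that("generator foldedness round-trips through the curve reader", {
  sp0 <- sim_cd_titration(noise = 0, seed = 22)
  fc <- foldedness_curve(sp0)
  expect_equal(fc$foldedness, attr(sp0, "truth")$foldedness, tolerance = 1e-10)
  # with noise, recovery within a few percent of the band amplitude
  sp <- sim_cd_titration(seed = 23)
  fcn <- foldedness_curve(sp)
  expect_equal(fcn$foldedness, attr(sp, "truth")$foldedness, tolerance = 0.1)
})

test_that("min-max variant anchors zero at an unfolded reference", {
  fc <- foldedness_curve(make_spectra(c(1, 0.8, 0.5)), unfolded_ref = 2)
  s262 <- 10 # band amplitude at 262 nm for foldedness 1
  expect_equal(fc$foldedness, (c(1, 0.8, 0.5) * s262 - 2) / (s262 - 2))
})

test_that("percent decrease in foldedness compares two constructs", {
  a <- foldedness_curve(make_spectra(c(1, 0.9, 0.8)))
  expect_equal(percent_decrease_foldedness(a, a, 25), 0)
  b <- foldedness_curve(make_spectra(c(1, 0.6, 0.28)))
  expect_equal(percent_decrease_foldedness(a, b, 25), 100 * (0.8 - 0.28) / 0.8)
  c12 <- foldedness_curve(make_spectra(c(1, 0.7, 0.44)))
  a50 <- foldedness_curve(make_spectra(c(1, 0.7, 0.5)))
  expect_equal(percent_decrease_foldedness(a50, c12, 25), 12)
  # interpolation between sampled concentrations
  expect_equal(percent_decrease_foldedness(a, b, 15),
    100 * (0.85 - 0.44) / 0.85)
  zero <- foldedness_curve(make_spectra(c(1, 0.5, 0)))
  expect_error(percent_decrease_foldedness(zero, b, 25),
    class = "quadbind_input_error")
})

test_that("noise-free melting fit recovers Tm essentially exactly", {
  tr <- sim_cd_melt(noise = 0, seed = 31)
  fit <- fit_melting(tr)
  expect_true(fit$converged)
  expect_equal(fit$tm_C, 80.5, tolerance = 0.1 / 80.5)
  expect_equal(fit$dh_vh, 50, tolerance = 1e-3)
})

test_that("melting Tm is invariant to affine rescaling of the signal", {
  tr <- sim_cd_melt(seed = 32)
  tr_aff <- dplyr::mutate(tr, ellipticity = -2.5 * ellipticity + 40)
  expect_equal(fit_melting(tr_aff)$tm_C, fit_melting(tr)$tm_C,
    tolerance = 1e-6)
})

test_that("a featureless monotone trace is flagged, not fitted", {
  tr <- tibble::tibble(temperature_C = seq(10, 100, 0.5))
  tr$ellipticity <- 10 - 0.05 * tr$temperature_C
  fit <- fit_melting(tr)
  expect_false(fit$converged)
  expect_equal(fit$flag, "no_transition")
})

test_that("a melt centred outside the scanned range is flagged", {
  tr <- sim_cd_melt(tm_C = 115, dh_vh = 50, noise = 0, seed = 33)
  fit <- fit_melting(tr)
  expect_false(fit$converged)
})

test_that("noisy melts at a lower midpoint recover within a degree", {
  tm <- purrr::map_dbl(1:25, function(i) {
    fit_melting(sim_cd_melt(tm_C = 68, seed = 300 + i))$tm_C
  })
  expect_lt(abs(stats::median(tm) - 68), 1)
})

test_that("flat-baseline variant works on short traces", {
  tr <- sim_cd_melt(slope_f = 0, slope_u = 0, noise = 0, seed = 34)
  fit <- fit_melting(tr, baselines = "flat")
  expect_true(fit$converged)
  expect_equal(fit$tm_C, 80.5, tolerance = 1e-3)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})
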