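paper_schedule <- function() {
  itc_schedule(cell_conc_uM = 5, syringe_conc_uM = 200)
}

test_that("displacement bookkeeping matches the exact dilution recursion", {
  sch <- paper_schedule()
  iso <- itc_isotherm(sch, rep(0, 20))
  exact <- oracle_itc_concentrations(5, 200, sch$injection_ul, 200)
  expect_equal(iso$xt_uM[20], unname(exact[20, "xt"]), tolerance = 0.01)
  expect_equal(iso$mt_uM[20], unname(exact[20, "mt"]), tolerance = 0.01)
  expect_true(all(diff(iso$molar_ratio) > 0))
  # vanishing injected volume leaves the cell untouched
  tiny <- itc_isotherm(itc_schedule(5, 200, injection_ul = rep(1e-9, 5)),
    rep(0, 5))
  expect_equal(tiny$mt_uM, rep(5, 5), tolerance = 1e-9)
  expect_equal(tiny$xt_uM, rep(0, 5), tolerance = 1e-6)
})

test_that("overfilling the cell warns but still defines the model", {
  expect_warning(itc_schedule(5, 200, injection_ul = rep(30, 10)),
    "exceeds the cell volume")
})

test_that("one-site heats have the right limiting behavior", {
  sch <- paper_schedule()
  # athermal binding: every normalized heat equals the baseline
  flat <- itc_predict(sch, n = 1, kd_uM = 1, dh = 0, baseline = -0.3)
  expect_equal(flat$ndh_kcal_mol, rep(-0.3, 20))
  # stoichiometric limit: heats step from dH to ~0 at molar ratio = n; the
  # displaced-volume term leaves sub-0.03% residuals after saturation
  step <- itc_predict(sch, n = 0.8, kd_uM = 1e-8, dh = -40)
  pre <- step$ndh_kcal_mol[step$molar_ratio < 0.7]
  post <- step$ndh_kcal_mol[step$molar_ratio > 0.95]
  expect_equal(pre, rep(-40, length(pre)), tolerance = 1e-3)
  expect_lt(max(abs(post)), 0.01 * 40)
})

test_that("predicted sigmoid inflects near the stoichiometry point", {
  sch <- itc_schedule(cell_conc_uM = 5, syringe_conc_uM = 100,
    injection_ul = rep(0.5, 80))
  inflection <- function(kd) {
    pred <- itc_predict(sch, n = 0.82, kd_uM = kd, dh = -41.88)
    slopes <- diff(pred$ndh_kcal_mol) / diff(pred$molar_ratio)
    mid <- (pred$molar_ratio[-1] + pred$molar_ratio[-nrow(pred)]) / 2
    mid[which.max(slopes)]
  }
  # at c ~ 4.5 the shallow sigmoid inflects below n; in the tight-binding
  # limit the inflection converges onto the stoichiometry point
  expect_gt(inflection(0.92), 0.5)
  expect_lt(inflection(0.92), 0.82)
  expect_equal(inflection(1e-4), 0.82, tolerance = 0.05)
})

test_that("noise-free fit recovers the generating parameters", {
  iso <- sim_itc(n = 1.04, kd_uM = 2.37, dh = -19.7, noise = 0, seed = 1)
  fit <- fit_itc(iso)
  expect_true(fit$converged)
  expect_equal(fit$n, 1.04, tolerance = 1e-4)
  expect_equal(fit$kd_uM, 2.37, tolerance = 1e-4)
  expect_equal(fit$dh, -19.7, tolerance = 1e-4)
  expect_equal(fit$baseline, 0, tolerance = 1e-6)
})

test_that("shallow isotherms are flagged low-confidence by the Wiseman c-value", {
  iso <- sim_itc(n = 1.06, kd_uM = 9.0, dh = -0.67, noise = 0, seed = 2)
  fit <- fit_itc(iso)
  expect_lt(fit$c_value, 1)
  expect_equal(fit$flag, "low_c")
})

test_that("dilution correction modes agree and behave", {
  sch <- paper_schedule()
  iso <- sim_itc(noise = 0, seed = 3)
  # subtracting an all-zero control is the identity
  ctrl0 <- itc_isotherm(sch, rep(0, 20))
  expect_equal(correct_dilution(iso, control = ctrl0)$ndh_kcal_mol,
    iso$ndh_kcal_mol)
  # constant dilution heat: control subtraction == tail averaging, once the
  # tail is genuinely saturated (tight binding) so no binding heat remains
  iso_d <- sim_itc(n = 1, kd_uM = 0.005, dh = -30, noise = 0,
    dilution_heat_ucal = 1.5, seed = 4)
  ctrl <- itc_isotherm(sch, rep(1.5, 20))
  by_control <- correct_dilution(iso_d, control = ctrl)
  by_tail <- correct_dilution(iso_d, tail_k = 3)
  expect_equal(by_control$ndh_kcal_mol, by_tail$ndh_kcal_mol, tolerance = 0.02)
  # saturated tail goes to ~0 after tail correction
  expect_lt(max(abs(utils::tail(by_tail$ndh_kcal_mol, 3))), 1e-3)
  # length mismatch is an error
  expect_error(correct_dilution(iso, control = itc_isotherm(
    itc_schedule(5, 200, injection_ul = rep(2, 10)), rep(0, 10))),
    class = "quadbind_input_error")
})

test_that("corrected total heat matches n * cell content * dH when saturating", {
  iso <- sim_itc(n = 1, kd_uM = 0.01, dh = -30, noise = 0, seed = 5)
  total_ucal <- sum(iso$heat_ucal)
  # n * M0[uM] * V0[ul] * dH[kcal/mol] * 1e-3 -> ucal
  expected <- 1 * 5 * 200 * -30 * 1e-3
  expect_equal(total_ucal, expected, tolerance = 0.02)
})

test_that("fit is equivariant under a uniform heat-unit rescaling", {
  iso <- sim_itc(noise = 0, seed = 6)
  sch <- paper_schedule()
  iso_k <- itc_isotherm(sch, iso$heat_ucal * 1000)
  f1 <- fit_itc(iso)
  fk <- fit_itc(iso_k)
  expect_equal(fk$n, f1$n, tolerance = 1e-6)
  expect_equal(fk$kd_uM, f1$kd_uM, tolerance = 1e-6)
  expect_equal(fk$dh, f1$dh * 1000, tolerance = 1e-4)
})

test_that("first-injection discard drops it from residuals but not bookkeeping", {
  iso <- sim_itc(noise = 0, seed = 8)
  fit <- fit_itc(iso, discard_first = TRUE)
  expect_false(fit$residuals$used[1])
  expect_equal(fit$kd_uM, 0.92, tolerance = 1e-3)
})

test_that("simulate-fit round trip stays within Monte-Carlo scatter for published truths", {
  tab <- reference_thermo_table()[1:9, ]
  reps <- 50
  for (r in seq_len(nrow(tab))) {
    fits <- purrr::map(seq_len(reps), function(i) {
      iso <- sim_itc(n = tab$n[r], kd_uM = tab$kd_uM[r], dh = tab$dH[r],
        seed = 9000 + r * 100 + i)
      fit_itc(iso)
    })
    kd <- purrr::map_dbl(fits, "kd_uM")
    n <- purrr::map_dbl(fits, "n")
    dh <- purrr::map_dbl(fits, "dh")
    expect_lt(abs(stats::median(kd) - tab$kd_uM[r]), 3 * stats::sd(kd))
    expect_lt(abs(stats::median(n) - tab$n[r]), 3 * stats::sd(n))
    expect_lt(abs(stats::median(dh) - tab$dH[r]), 3 * stats::sd(dh))
  }
})

test_that("derived thermodynamics satisfy the identities", {
  iso <- sim_itc(n = 1.04, kd_uM = 2.37, dh = -19.7, noise = 0, seed = 9)
  fit <- fit_itc(iso)
  th <- derive_thermodynamics(fit)
  expect_equal(th$dG, -7.67, tolerance = 0.02 / 7.67)
  expect_equal(th$TdS, th$dH - th$dG)
  td <- tidy(fit)
  expect_setequal(td$term, c("n", "kd_uM", "dh", "baseline"))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("thermogram integration recovers known injection heats", {
  # synthetic power trace: Gaussian response pulses on a drifting baseline
  spacing <- 180
  inj_times <- spacing * (seq_len(10) - 1) + 10
  tt <- seq(0, 1810, by = 2)
  truth <- -(10 - seq_len(10) * 0.8) # ucal per injection, approaching zero
  pow <- 0.05 + 1e-5 * tt # slow instrument drift
  for (i in seq_len(10)) {
    tau <- 10
    pow <- pow + truth[i] / (tau * sqrt(2 * pi)) *
      exp(-(tt - inj_times[i] - 45)^2 / (2 * tau^2))
  }
  th <- tibble::tibble(time_s = tt, power_ucal_s = pow)
  heats <- integrate_thermogram(th, inj_times)
  expect_equal(nrow(heats), 10)
  expect_equal(heats$heat_ucal, truth, tolerance = 0.02)
  # malformed inputs error
  expect_error(integrate_thermogram(th, c(5000)), class = "quadbind_input_error")
  expect_error(
    integrate_thermogram(tibble::tibble(time_s = c(1, 1), power_ucal_s = 0:1),
      c(1)),
    class = "quadbind_input_error")
})
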