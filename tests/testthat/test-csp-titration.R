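make_series <- function(h_shifts, n_shifts, residue = "G#2",
                        protein_uM = 138) {
  # single-residue series from explicit per-step shift offsets
  n_step <- length(h_shifts)
  tibble::tibble(
    step = seq_len(n_step) - 1L, protein_uM = protein_uM,
    ligand_uM = protein_uM * c(0, seq_len(n_step - 1)),
    residue = residue, h_ppm = 8.2 + h_shifts, n_ppm = 118 + n_shifts
  )
}

test_that("combined CSP statistic follows the 1H/15N formula and is sign-invariant", {
  s <- make_series(c(0, 0.03, -0.03), c(0, 0.20, 0.20))
  tr <- csp_combine(s)
  expect_equal(tr$dobs[tr$step == 0], 0)
  expect_equal(tr$dobs[tr$step == 1], sqrt(0.03^2 + (0.20 / 5)^2)) # 0.05
  expect_equal(tr$dobs[tr$step == 2], 0.05) # sign of the 1H change irrelevant
  # alternative nitrogen scaling
  tr10 <- csp_combine(s, n_scale = 10)
  expect_equal(tr10$dobs[tr10$step == 1], sqrt(0.03^2 + 0.02^2))
})

test_that("CSPs are invariant to a uniform reference-frequency offset", {
  s <- sim_csp_titration(seed = 11)
  s_off <- dplyr::mutate(s, h_ppm = h_ppm + 0.37, n_ppm = n_ppm - 2.1)
  expect_equal(csp_combine(s)$dobs, csp_combine(s_off)$dobs, tolerance = 1e-12)
})

test_that("residues missing at any step are dropped with a warning", {
  s <- make_series(c(0, 0.02, 0.04), c(0, 0.1, 0.2))
  s2 <- dplyr::bind_rows(
    s,
    tibble::tibble(step = 0:1, protein_uM = 138,
      ligand_uM = c(0, 138), residue = "Y244",
      h_ppm = 7.9, n_ppm = 121)
  )
  expect_warning(tr <- csp_combine(s2), "Y244")
  expect_setequal(unique(tr$residue), "G#2")
})

test_that("individual fit recovers noise-free parameters and flags degeneracy", {
  tr <- make_trajectory(kd = 11, ddmax = 0.15)
  fit <- fit_csp_individual(tr)
  expect_true(fit$converged)
  expect_equal(fit$kd_uM, 11, tolerance = 1e-6)
  expect_equal(fit$ddmax, 0.15, tolerance = 1e-6)
  # flat trajectory is non-identifiable, not a silent success
  flat <- dplyr::mutate(tr, dobs = 0)
  fit0 <- fit_csp_individual(flat)
  expect_false(fit0$converged)
  expect_equal(fit0$flag, "non_identifiable")
})

test_that("global fit equals the individual fit for a single residue", {
  tr <- make_trajectory(kd = 7.3, ddmax = 0.21)
  ind <- fit_csp_individual(tr)
  glob <- fit_csp_global(tr)
  expect_equal(glob$kd_uM, ind$kd_uM, tolerance = 1e-8)
})

test_that("global fit recovers a shared Kd exactly from noise-free trajectories", {
  tr <- dplyr::bind_rows(
    make_trajectory(11, 0.10, residue = "resA"),
    make_trajectory(11, 0.25, residue = "resB")
  )
  fit <- fit_csp_global(tr)
  expect_true(fit$converged)
  expect_equal(fit$kd_uM, 11, tolerance = 1e-6)
  expect_equal(sort(fit$per_residue$ddmax), c(0.10, 0.25), tolerance = 1e-6)
})

test_that("fit is invariant to a concentration unit change", {
  tr <- dplyr::bind_rows(
    make_trajectory(11, 0.12, residue = "resA"),
    make_trajectory(11, 0.22, residue = "resB")
  )
  tr_nM <- dplyr::mutate(tr, protein_uM = protein_uM * 1000,
    ligand_uM = ligand_uM * 1000)
  kd_uM <- fit_csp_global(tr)$kd_uM
  kd_nM <- fit_csp_global(tr_nM)$kd_uM
  expect_equal(kd_nM / 1000, kd_uM, tolerance = 1e-6)
})

test_that("heterogeneous per-residue Kds inflate the shared-Kd residual", {
  homo <- dplyr::bind_rows(
    make_trajectory(11, 0.2, residue = "resA"),
    make_trajectory(11, 0.2, residue = "resB")
  )
  hetero <- dplyr::bind_rows(
    make_trajectory(5, 0.2, residue = "resA"),
    make_trajectory(50, 0.2, residue = "resB")
  )
  rss_homo <- fit_csp_global(homo)$rss
  rss_hetero <- fit_csp_global(hetero)$rss
  expect_lt(rss_homo, 1e-10)
  expect_gt(rss_hetero, 100 * max(rss_homo, 1e-12))
})

test_that("perturbation classifier isolates responsive residues", {
  # quiet spectrum: nothing flagged
  quiet <- dplyr::bind_rows(purrr::map(sprintf("r%02d", 1:10), function(r) {
    make_trajectory(11, 0, residue = r)
  }))
  expect_false(any(classify_perturbed(quiet)$perturbed))
  # one large responder among 13 near-silent residues
  mix <- dplyr::bind_rows(
    purrr::map(sprintf("r%02d", 1:13), function(r) {
      make_trajectory(11, 0.005, residue = r)
    })
  ) |>
    dplyr::bind_rows(make_trajectory(11, 0.21, residue = "hot"))
  cls <- classify_perturbed(mix)
  expect_equal(cls$residue[cls$perturbed], "hot")
  # the classic mean + 1 SD rule agrees when the responder is a lone outlier
  cls_sd <- classify_perturbed(mix, rule = "mean_sd")
  expect_equal(cls_sd$residue[cls_sd$perturbed], "hot")
})

test_that("classifier finds most responsive residues under noise", {
  withr::local_seed(7)
  ddmax <- c(runif(8, 0.10, 0.30), rep(0, 6))
  s <- sim_csp_titration(ddmax = ddmax, seed = 77)
  cls <- classify_perturbed(csp_combine(s))
  responsive <- sprintf("res%02d", 1:8)
  expect_gte(sum(cls$perturbed[cls$residue %in% responsive]), 7)
  expect_false(any(cls$perturbed[!cls$residue %in% responsive]))
})

test_that("global Kd recovery over seeded replicates is accurate and calibrated", {
  reps <- 100
  res <- purrr::map(seq_len(reps), function(i) {
    s <- sim_csp_titration(seed = 5000 + i)
    fit <- fit_csp_global(csp_combine(s))
    tibble::tibble(kd = fit$kd_uM, se = fit$kd_se, ok = fit$converged)
  }) |>
    purrr::list_rbind()
  expect_true(all(res$ok))
  expect_lt(abs(stats::median(res$kd) - 11) / 11, 0.15)
  coverage <- mean(abs(res$kd - 11) <= res$se)
  expect_gte(coverage, 0.60)
})

test_that("averaging individual Kds gives a sane secondary estimate", {
  s <- sim_csp_titration(seed = 31)
  ind <- fit_csp_individual(csp_combine(s))
  avg <- average_individual_kd(ind)
  expect_gt(avg$n_residues, 10)
  expect_true(avg$kd_mean > 3 && avg$kd_mean < 30)
})

test_that("tidiers expose the global fit parameters", {
  s <- sim_csp_titration(seed = 12)
  fit <- fit_csp_global(csp_combine(s))
  td <- tidy(fit)
  expect_equal(td$term[1], "kd_uM")
  expect_equal(nrow(td), 15) # shared Kd + 14 saturation shifts
  gl <- glance(fit)
  expect_equal(gl$kd_uM, fit$kd_uM)
  expect_s3_class(autoplot(fit), "ggplot")
})
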