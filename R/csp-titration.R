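# Combined chemical shift perturbations from HSQC titration peak lists and
# per-residue / global Kd fitting under the fast-exchange 1:1 depletion model.

#' Assemble a titration series from per-step peak lists
#'
#' Binds per-step peak lists (as returned by [read_peaklist()]) into the long
#' titration-series table the CSP functions consume, attaching the
#' concentration schedule. Step 0 must be the ligand-free reference and ligand
#' concentrations must be non-decreasing.
#'
#' @param peaklists A list of data frames, each with columns `residue`,
#'   `h_ppm`, `n_ppm`, ordered by titration step.
#' @param protein_uM Total protein concentration per step (uM); recycled if
#'   length 1 (no dilution correction is applied — supply per-step values if
#'   the schedule diluted the protein).
#' @param ligand_uM Total ligand (RNA) concentration per step (uM); first
#'   element must be 0.
#' @return A tibble with columns `step`, `protein_uM`, `ligand_uM`,
#'   `residue`, `h_ppm`, `n_ppm`.
#' @export
titration_series <- function(peaklists, protein_uM, ligand_uM) {
  n_step <- length(peaklists)
  if (n_step < 3) {
    rlang::abort("A titration needs at least 3 steps.", class = "quadbind_input_error")
  }
  protein_uM <- rep_len(protein_uM, n_step)
  if (length(ligand_uM) != n_step) {
    rlang::abort("`ligand_uM` must have one value per step.", class = "quadbind_input_error")
  }
  if (ligand_uM[1] != 0) {
    rlang::abort("Step 0 must be the ligand-free reference (ligand_uM = 0).",
      class = "quadbind_input_error")
  }
  if (is.unsorted(ligand_uM)) {
    rlang::abort("`ligand_uM` must be non-decreasing across steps.",
      class = "quadbind_input_error")
  }
  purrr::map2(peaklists, seq_len(n_step), function(pl, i) {
    tibble::tibble(
      step = i - 1L, protein_uM = protein_uM[i], ligand_uM = ligand_uM[i],
      residue = pl$residue, h_ppm = pl$h_ppm, n_ppm = pl$n_ppm
    )
  }) |>
    purrr::list_rbind()
}

#' Combined chemical shift perturbations relative to the free state
#'
#' For every residue present at every titration step, computes the combined
#' amide CSP against the step-0 (ligand-free) reference:
#' \deqn{\delta_{obs} = \sqrt{(\Delta\delta_H)^2 + (\Delta\delta_N / s)^2}}
#' with the nitrogen shift change scaled down by `n_scale` (default 5) to
#' account for the wider 15N dispersion. Residues missing at any step are
#' dropped with a warning rather than an error.
#'
#' @param series A titration-series tibble (see [titration_series()]) with
#'   columns `step`, `protein_uM`, `ligand_uM`, `residue`, `h_ppm`, `n_ppm`.
#' @param n_scale Scaling divisor for the 15N dimension (> 0, default 5).
#' @return A tibble of trajectories: `residue`, `step`, `protein_uM`,
#'   `ligand_uM`, `dobs` (ppm, 0 at step 0).
#' @export
csp_combine <- function(series, n_scale = 5) {
  stopifnot(all(c("step", "protein_uM", "ligand_uM", "residue", "h_ppm", "n_ppm")
    %in% names(series)))
  if (!is.numeric(n_scale) || n_scale <= 0) {
    rlang::abort("`n_scale` must be > 0.", class = "quadbind_input_error")
  }
  n_steps <- dplyr::n_distinct(series$step)
  counts <- dplyr::count(series, .data$residue)
  incomplete <- counts$residue[counts$n < n_steps]
  if (length(incomplete) > 0) {
    rlang::warn(paste0(
      "Dropping ", length(incomplete),
      " residue(s) not observed at every step: ",
      paste(incomplete, collapse = ", ")
    ))
    series <- dplyr::filter(series, !.data$residue %in% incomplete)
  }
  ref <- series |>
    dplyr::filter(.data$step == min(.data$step)) |>
    dplyr::select("residue", h0 = "h_ppm", n0 = "n_ppm")
  series |>
    dplyr::left_join(ref, by = "residue") |>
    dplyr::mutate(
      dobs = sqrt((.data$h_ppm - .data$h0)^2 +
        ((.data$n_ppm - .data$n0) / n_scale)^2)
    ) |>
    dplyr::select("residue", "step", "protein_uM", "ligand_uM", "dobs") |>
    dplyr::arrange(.data$residue, .data$step)
}

# Shared single-trajectory least squares. Returns a one-row tibble.
.fit_one_trajectory <- function(df, kd_lower = 1e-3, kd_upper = 1e5,
                                ddmax_upper = 5) {
  df_fit <- dplyr::filter(df, .data$ligand_uM > 0)
  out <- tibble::tibble(
    kd_uM = NA_real_, kd_se = NA_real_, ddmax = NA_real_, ddmax_se = NA_real_,
    rss = NA_real_, n_points = nrow(df_fit), converged = FALSE,
    flag = NA_character_
  )
  if (nrow(df_fit) < 3) {
    out$flag <- "too_few_points"
    return(out)
  }
  dd0 <- max(df_fit$dobs)
  if (dd0 <= 1e-9) {
    out$flag <- "non_identifiable"
    return(out)
  }
  # kd init: ligand concentration at half-maximal observed shift (interpolated)
  kd0 <- tryCatch(
    stats::approx(df$dobs, df$ligand_uM, xout = dd0 / 2, ties = "ordered")$y,
    error = function(e) NA_real_
  )
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(df_fit$ligand_uM)
  kd0 <- min(max(kd0, kd_lower * 2), kd_upper / 2)
  res_fn <- function(par) {
    df_fit$dobs - csp_predicted(df_fit$protein_uM, df_fit$ligand_uM,
      par[1], par[2])
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(kd0, dd0), fn = res_fn,
      lower = c(kd_lower, 0), upper = c(kd_upper, ddmax_upper),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !(fit$info %in% 1:4)) {
    out$flag <- "non_convergence"
    return(out)
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
    error = function(e) c(NA_real_, NA_real_))
  out$kd_uM <- fit$par[1]
  out$ddmax <- fit$par[2]
  out$kd_se <- se[1]
  out$ddmax_se <- se[2]
  out$rss <- fit$deviance
  out$converged <- TRUE
  at_lo <- fit$par[1] <= kd_lower * (1 + 1e-6)
  at_hi <- fit$par[1] >= kd_upper * (1 - 1e-6)
  if (at_lo || at_hi) {
    out$flag <- "kd_at_bound"
    out$converged <- FALSE
  }
  out
}

#' Per-residue apparent Kd fits
#'
#' Fits each residue's CSP trajectory independently with the 1:1
#' ligand-depletion model (two parameters: apparent \eqn{K_d} and
#' \eqn{\Delta\delta_{max}}), unit point weights, Levenberg-Marquardt with box
#' bounds (\eqn{K_d \in (10^{-3}, 10^5)} uM, \eqn{\Delta\delta_{max} \in
#' (0, 5)} ppm). Initialization: \eqn{\Delta\delta_{max}} at the largest
#' observed shift, \eqn{K_d} at the interpolated ligand concentration of
#' half-maximal shift. Degenerate or non-converged trajectories come back
#' flagged, never silently.
#'
#' @param trajectories CSP trajectory tibble from [csp_combine()].
#' @return A tibble with one row per residue: `residue`, `kd_uM`, `kd_se`,
#'   `ddmax`, `ddmax_se`, `rss`, `n_points`, `converged`, `flag`.
#' @export
fit_csp_individual <- function(trajectories) {
  trajectories |>
    dplyr::group_by(.data$residue) |>
    dplyr::group_modify(~ .fit_one_trajectory(.x)) |>
    dplyr::ungroup()
}

#' Summarize individual apparent Kds into one number
#'
#' A simple secondary statistic: the mean (and SD) of converged per-residue
#' apparent \eqn{K_d}s. The shared-\eqn{K_d} simultaneous regression of
#' [fit_csp_global()] is the primary estimator; this average is reported
#' alongside it because per-residue fits are the more common first look.
#'
#' @param individual_fits Output of [fit_csp_individual()].
#' @return A one-row tibble: `kd_mean`, `kd_sd`, `n_residues`.
#' @export
average_individual_kd <- function(individual_fits) {
  ok <- dplyr::filter(individual_fits, .data$converged)
  tibble::tibble(
    kd_mean = mean(ok$kd_uM), kd_sd = stats::sd(ok$kd_uM),
    n_residues = nrow(ok)
  )
}

#' Global shared-Kd fit across residues
#'
#' Simultaneous least squares over all residues and titration steps with a
#' single shared \eqn{K_d} and one free \eqn{\Delta\delta_{max}} per residue
#' (so for R residues, R + 1 parameters). Uncertainty on the shared
#' \eqn{K_d} comes from the asymptotic covariance; optionally also from a
#' seeded case bootstrap that resamples residues with replacement, which is
#' more honest when the residue count is small.
#'
#' @param trajectories CSP trajectory tibble from [csp_combine()].
#' @param boot Number of bootstrap replicates (0 = asymptotic SE only;
#'   500 is a sensible choice when enabled).
#' @param seed Optional integer seed for the bootstrap resampling.
#' @return An object of class `csp_fit` with elements `kd_uM`, `kd_se`,
#'   `kd_se_boot`, `per_residue` (tibble of \eqn{\Delta\delta_{max}} with
#'   SEs), `residuals` (tibble), `rss`, `df_residual`, `converged`, `flag`,
#'   `fit_kind = "global"`.
#' @export
fit_csp_global <- function(trajectories, boot = 0, seed = NULL) {
  residues <- unique(trajectories$residue)
  if (length(residues) < 1) {
    rlang::abort("No residues to fit.", class = "quadbind_input_error")
  }
  fit <- .fit_global_core(trajectories, residues)
  kd_se_boot <- NA_real_
  if (boot > 0 && length(residues) >= 2) {
    boot_one <- function(i) {
      take <- sample(residues, replace = TRUE)
      traj_b <- purrr::imap(take, function(r, j) {
        dplyr::mutate(
          dplyr::filter(trajectories, .data$residue == r),
          residue = paste0(r, "_b", j)
        )
      }) |>
        purrr::list_rbind()
      fb <- tryCatch(.fit_global_core(traj_b, unique(traj_b$residue)),
        error = function(e) NULL)
      if (is.null(fb) || !fb$converged) NA_real_ else fb$kd_uM
    }
    boot_kds <- if (is.null(seed)) {
      purrr::map_dbl(seq_len(boot), boot_one)
    } else {
      withr::with_seed(seed, purrr::map_dbl(seq_len(boot), boot_one))
    }
    kd_se_boot <- stats::sd(boot_kds, na.rm = TRUE)
  }
  fit$kd_se_boot <- kd_se_boot
  fit
}

.fit_global_core <- function(trajectories, residues,
                             kd_lower = 1e-3, kd_upper = 1e5, ddmax_upper = 5) {
  df <- dplyr::filter(trajectories, .data$ligand_uM > 0) |>
    dplyr::mutate(rid = match(.data$residue, residues))
  nres <- length(residues)
  dd0 <- purrr::map_dbl(seq_len(nres), function(i) {
    max(df$dobs[df$rid == i], 0)
  })
  if (max(dd0) <= 1e-9) {
    return(structure(list(
      kd_uM = NA_real_, kd_se = NA_real_, kd_se_boot = NA_real_,
      per_residue = tibble::tibble(residue = residues, ddmax = NA_real_,
        ddmax_se = NA_real_),
      residuals = NULL, rss = NA_real_, df_residual = NA_integer_,
      converged = FALSE, flag = "non_identifiable", fit_kind = "global"
    ), class = "csp_fit"))
  }
  # shared kd init: median of per-residue half-max interpolations
  ind <- fit_csp_individual(trajectories)
  kd0 <- stats::median(ind$kd_uM[ind$converged], na.rm = TRUE)
  if (!is.finite(kd0)) kd0 <- stats::median(df$ligand_uM)
  kd0 <- min(max(kd0, kd_lower * 2), kd_upper / 2)
  res_fn <- function(par) {
    kd <- par[1]
    ddmax <- par[-1][df$rid]
    df$dobs - csp_predicted(df$protein_uM, df$ligand_uM, kd, ddmax)
  }
  fit <- minpack.lm::nls.lm(
    par = c(kd0, pmax(dd0, 1e-6)), fn = res_fn,
    lower = c(kd_lower, rep(0, nres)),
    upper = c(kd_upper, rep(ddmax_upper, nres)),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  converged <- fit$info %in% 1:4
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
    error = function(e) rep(NA_real_, nres + 1))
  flag <- NA_character_
  if (!converged) flag <- "non_convergence"
  if (fit$par[1] <= kd_lower * (1 + 1e-6) || fit$par[1] >= kd_upper * (1 - 1e-6)) {
    flag <- "kd_at_bound"
    converged <- FALSE
  }
  resid_tbl <- dplyr::mutate(df,
    fitted = .data$dobs - res_fn(fit$par),
    residual = res_fn(fit$par)
  ) |>
    dplyr::select("residue", "step", "ligand_uM", "dobs", "fitted", "residual")
  structure(list(
    kd_uM = fit$par[1], kd_se = se[1], kd_se_boot = NA_real_,
    per_residue = tibble::tibble(
      residue = residues, ddmax = fit$par[-1], ddmax_se = se[-1]
    ),
    residuals = resid_tbl, rss = fit$deviance,
    df_residual = nrow(df) - (nres + 1),
    converged = converged, flag = flag, fit_kind = "global"
  ), class = "csp_fit")
}

#' Flag perturbed residues from end-point CSPs
#'
#' Labels a residue "perturbed" when its final-step combined CSP exceeds an
#' adaptive threshold with an absolute floor, so a quiet spectrum flags
#' nothing. Two rules are provided. The default, `"frac_max"`, thresholds at
#' `frac_max` times the largest end-point CSP: it keys on the responsive
#' residues themselves and so still works when most of the panel responds —
#' the situation for a short binding motif saturated with ligand. The
#' `"mean_sd"` rule thresholds at mean + `n_sd` SD over all residues; it is
#' the classic choice when only a minority responds, but provably cannot
#' flag a responsive majority (the threshold then sits above the responders'
#' own values), which is why it is not the default.
#'
#' @param trajectories CSP trajectory tibble from [csp_combine()].
#' @param rule `"frac_max"` (default) or `"mean_sd"`.
#' @param frac_max Fraction of the largest end-point CSP (default 0.15).
#' @param n_sd SD multiplier for the `"mean_sd"` rule (default 1).
#' @param floor_ppm Absolute minimum CSP to qualify (default 0.01 ppm, the
#'   scale of the combined-CSP noise at instrument-class shift precision).
#' @return A tibble: `residue`, `dobs_final`, `threshold`, `perturbed`.
#' @export
classify_perturbed <- function(trajectories, rule = c("frac_max", "mean_sd"),
                               frac_max = 0.15, n_sd = 1, floor_ppm = 0.01) {
  rule <- match.arg(rule)
  finals <- trajectories |>
    dplyr::group_by(.data$residue) |>
    dplyr::slice_max(.data$step, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("residue", dobs_final = "dobs")
  vals <- finals$dobs_final
  adaptive <- if (rule == "frac_max") {
    frac_max * max(vals)
  } else {
    spread <- stats::sd(vals)
    mean(vals) + n_sd * (if (is.finite(spread)) spread else 0)
  }
  thr <- max(adaptive, floor_ppm)
  dplyr::mutate(finals,
    threshold = thr,
    perturbed = .data$dobs_final > thr
  )
}

#' @export
print.csp_fit <- function(x, ...) {
  cat("Global CSP fit (shared Kd, fast-exchange 1:1 depletion model)\n")
  cat(sprintf("  Kd = %.3g +/- %.2g uM (asymptotic SE)\n", x$kd_uM, x$kd_se))
  if (is.finite(x$kd_se_boot)) {
    cat(sprintf("  bootstrap SE = %.2g uM\n", x$kd_se_boot))
  }
  cat(sprintf("  %d residues, RSS = %.3g, converged: %s\n",
    nrow(x$per_residue), x$rss, x$converged))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}
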