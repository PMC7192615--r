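# One-site ITC isotherm modelling: Origin-style displacement bookkeeping for
# a fixed-volume perfusion cell, the single-site Wiseman binding model, heat
# of dilution correction, and Levenberg-Marquardt fitting of (n, Kd, dH).

#' Describe an ITC experiment's geometry
#'
#' @param cell_conc_uM Macromolecule concentration loaded in the cell (uM);
#'   here the RNA.
#' @param syringe_conc_uM Titrant concentration in the syringe (uM); here the
#'   protein.
#' @param injection_ul Ordered injection volumes (ul); default 20 x 2 ul.
#' @param cell_volume_ul Active cell volume (ul); default 200 (iTC200-class
#'   instrument).
#' @param temperature Temperature (K), default 298.15.
#' @param spacing_s Injection spacing (s), metadata only.
#' @return An object of class `itc_schedule` (a named list).
#' @export
itc_schedule <- function(cell_conc_uM, syringe_conc_uM,
                         injection_ul = rep(2, 20), cell_volume_ul = 200,
                         temperature = 298.15, spacing_s = 180) {
  if (cell_conc_uM <= 0 || syringe_conc_uM <= 0 || cell_volume_ul <= 0 ||
    any(injection_ul <= 0)) {
    rlang::abort("Concentrations and volumes must all be > 0.",
      class = "quadbind_input_error")
  }
  if (sum(injection_ul) > cell_volume_ul) {
    rlang::warn("Cumulative injected volume exceeds the cell volume; the displacement approximation degrades.")
  }
  structure(list(
    cell_conc_uM = cell_conc_uM, syringe_conc_uM = syringe_conc_uM,
    injection_ul = injection_ul, cell_volume_ul = cell_volume_ul,
    temperature = temperature, spacing_s = spacing_s
  ), class = "itc_schedule")
}

# Cell concentrations after each injection under the conventional
# displacement approximation for an overflow cell: with dV = cumulative
# injected volume, the macromolecule is diluted by
#   (1 - dV/2V0) / (1 + dV/2V0)
# and the titrant accumulates to
#   Xs * (dV/V0) / (1 + dV/2V0).
# This first-order bookkeeping matches the vendor-software family and agrees
# with the exact exponential-dilution recursion to < 1% at 40 ul into 200 ul.
.itc_concentrations <- function(schedule) {
  v0 <- schedule$cell_volume_ul
  dv <- cumsum(schedule$injection_ul)
  tibble::tibble(
    injection = seq_along(dv),
    injection_ul = schedule$injection_ul,
    cum_vol_ul = dv,
    mt_uM = schedule$cell_conc_uM * (1 - dv / (2 * v0)) / (1 + dv / (2 * v0)),
    xt_uM = schedule$syringe_conc_uM * (dv / v0) / (1 + dv / (2 * v0)),
    molar_ratio = .data$xt_uM / .data$mt_uM
  )
}

#' Build an ITC isotherm table from a schedule and integrated heats
#'
#' Tracks titrant and macromolecule concentrations in the cell through the
#' injection series (displacement-corrected) and normalizes each integrated
#' heat by the moles of titrant delivered in that injection.
#'
#' @param schedule An [itc_schedule()].
#' @param heat_ucal Integrated heat per injection (ucal), one per injection.
#' @return A tibble of class `itc_isotherm` with columns `injection`,
#'   `injection_ul`, `cum_vol_ul`, `mt_uM`, `xt_uM`, `molar_ratio`,
#'   `heat_ucal`, `ndh_kcal_mol` (heat per mole of injectant); the schedule
#'   travels along as an attribute.
#' @export
itc_isotherm <- function(schedule, heat_ucal) {
  stopifnot(inherits(schedule, "itc_schedule"))
  if (length(heat_ucal) != length(schedule$injection_ul)) {
    rlang::abort("`heat_ucal` must have one value per injection.",
      class = "quadbind_input_error")
  }
  conc <- .itc_concentrations(schedule)
  # moles injected (mol) = Xs[uM]*1e-6 * dv[ul]*1e-6 ; ucal -> kcal: 1e-9
  out <- dplyr::mutate(conc,
    heat_ucal = heat_ucal,
    ndh_kcal_mol = heat_ucal * 1e-9 /
      (schedule$syringe_conc_uM * 1e-6 * .data$injection_ul * 1e-6)
  )
  attr(out, "schedule") <- schedule
  class(out) <- c("itc_isotherm", class(out))
  out
}

.get_schedule <- function(isotherm) {
  sch <- attr(isotherm, "schedule")
  if (is.null(sch)) {
    rlang::abort("Isotherm has lost its schedule attribute; rebuild with itc_isotherm().",
      class = "quadbind_input_error")
  }
  sch
}

#' Predicted one-site ITC heats
#'
#' Single-class-of-sites model: after injection i the concentration of bound
#' titrant follows the 1:1 depletion quadratic with site concentration
#' \eqn{n \cdot M_t}; the cell heat content is \eqn{Q_i = n \Theta_i M_{t,i}
#' V_0 \Delta H}, and the heat evolved by injection i is
#' \deqn{\Delta Q_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0}\,\frac{Q_i + Q_{i-1}}{2},}
#' the last term accounting for heat content carried out in the displaced
#' volume. Heats are returned both raw (ucal) and normalized per mole of
#' injectant (kcal/mol) with the constant `baseline` (kcal/mol of injectant,
#' e.g. residual heat of dilution) added to the normalized values.
#'
#' @param schedule An [itc_schedule()].
#' @param n Stoichiometry (sites per macromolecule, > 0).
#' @param kd_uM Dissociation constant (uM, > 0).
#' @param dh Binding enthalpy (kcal/mol).
#' @param baseline Offset per mole of injectant (kcal/mol), default 0.
#' @return A tibble: `injection`, `molar_ratio`, `heat_ucal`, `ndh_kcal_mol`.
#' @export
itc_predict <- function(schedule, n, kd_uM, dh, baseline = 0) {
  stopifnot(inherits(schedule, "itc_schedule"))
  if (n <= 0 || kd_uM <= 0) {
    rlang::abort("`n` and `kd_uM` must be > 0.", class = "quadbind_input_error")
  }
  conc <- .itc_concentrations(schedule)
  v0 <- schedule$cell_volume_ul
  theta <- fraction_bound(n * conc$mt_uM, conc$xt_uM, kd_uM)
  # heat content of the cell after each injection, in ucal:
  # n*Theta*Mt[uM]*V0[ul]*dH[kcal/mol] * 1e-3  (uM*ul = 1e-12 mol; kcal=1e9 ucal)
  q <- n * theta * conc$mt_uM * v0 * dh * 1e-3
  q_prev <- c(0, q[-length(q)])
  dq <- q - q_prev + (conc$injection_ul / v0) * (q + q_prev) / 2
  moles_inj_kcal <- schedule$syringe_conc_uM * 1e-6 * conc$injection_ul * 1e-6
  ndh <- dq * 1e-9 / moles_inj_kcal + baseline
  tibble::tibble(
    injection = conc$injection,
    molar_ratio = conc$molar_ratio,
    heat_ucal = ndh * moles_inj_kcal * 1e9,
    ndh_kcal_mol = ndh
  )
}

#' Correct an isotherm for the heat of dilution
#'
#' Either subtracts a matched buffer-titration control isotherm
#' injection-by-injection, or subtracts the mean normalized heat of the last
#' `tail_k` (saturated) injections.
#'
#' @param isotherm An [itc_isotherm()].
#' @param control Optional control [itc_isotherm()] with the same number of
#'   injections (protein-into-buffer titration).
#' @param tail_k When no control is given, number of final injections to
#'   average (default 3).
#' @return The corrected isotherm (same class/attributes).
#' @export
correct_dilution <- function(isotherm, control = NULL, tail_k = 3) {
  sch <- .get_schedule(isotherm)
  if (!is.null(control)) {
    if (nrow(control) != nrow(isotherm)) {
      rlang::abort("Control isotherm length does not match.",
        class = "quadbind_input_error")
    }
    offset <- control$ndh_kcal_mol
  } else {
    offset <- mean(utils::tail(isotherm$ndh_kcal_mol, tail_k))
  }
  moles_inj_kcal <- sch$syringe_conc_uM * 1e-6 * isotherm$injection_ul * 1e-6
  out <- dplyr::mutate(isotherm,
    ndh_kcal_mol = .data$ndh_kcal_mol - offset,
    heat_ucal = .data$ndh_kcal_mol * moles_inj_kcal * 1e9
  )
  attr(out, "schedule") <- sch
  if (!inherits(out, "itc_isotherm")) class(out) <- c("itc_isotherm", class(out))
  out
}

#' Fit the one-site model to an ITC isotherm
#'
#' Least squares over (n, Kd, dH, baseline), all floating, on the normalized
#' per-injection heats. Initialization: baseline from the mean of the last
#' three heats, dH from the first usable heat relative to that baseline, n
#' from the molar ratio at the steepest descent of the sigmoid, Kd at the
#' cell concentration. Reports asymptotic standard errors and the Wiseman
#' c-value \eqn{c = n [M] / K_d}; fits with c < 1 are flagged low-confidence
#' because the isotherm is then too shallow to pin all three parameters.
#'
#' @param isotherm An [itc_isotherm()], ideally dilution-corrected.
#' @param discard_first Drop the first injection from the residuals (its
#'   volume still counts toward the concentration bookkeeping); default
#'   FALSE.
#' @return An object of class `itc_fit`: `n`, `n_se`, `kd_uM`, `kd_se`, `dh`,
#'   `dh_se`, `baseline`, `baseline_se`, `c_value`, `residuals` (tibble),
#'   `rss`, `df_residual`, `converged`, `flag`, `schedule`.
#' @export
fit_itc <- function(isotherm, discard_first = FALSE) {
  sch <- .get_schedule(isotherm)
  use <- rep(TRUE, nrow(isotherm))
  if (discard_first) use[1] <- FALSE
  if (sum(use) < 6) {
    rlang::abort("Need at least 6 usable injections.", class = "quadbind_input_error")
  }
  y <- isotherm$ndh_kcal_mol
  base0 <- mean(utils::tail(y, 3))
  dh0 <- y[which(use)[1]] - base0
  if (abs(dh0) < 1e-8) dh0 <- sign(dh0 + 1e-12) * 1e-3
  slope_at <- which.max(abs(diff(y)))
  n0 <- mean(isotherm$molar_ratio[c(slope_at, slope_at + 1)])
  n0 <- min(max(n0, 0.05), 50)
  kd0 <- sch$cell_conc_uM
  res_fn <- function(par) {
    pred <- itc_predict(sch, par[1], par[2], par[3], par[4])$ndh_kcal_mol
    (y - pred)[use]
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(n0, kd0, dh0, base0), fn = res_fn,
      lower = c(1e-2, 1e-4, -1e6, -1e6), upper = c(100, 1e6, 1e6, 1e6),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(list(
      n = NA_real_, n_se = NA_real_, kd_uM = NA_real_, kd_se = NA_real_,
      dh = NA_real_, dh_se = NA_real_, baseline = NA_real_,
      baseline_se = NA_real_, c_value = NA_real_, residuals = NULL,
      rss = NA_real_, df_residual = NA_integer_, converged = FALSE,
      flag = "non_convergence", schedule = sch
    ), class = "itc_fit"))
  }
  converged <- fit$info %in% 1:4
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
    error = function(e) rep(NA_real_, 4))
  c_value <- fit$par[1] * sch$cell_conc_uM / fit$par[2]
  flag <- NA_character_
  if (!converged) flag <- "non_convergence"
  if (is.na(flag) && c_value < 1) flag <- "low_c"
  pred <- itc_predict(sch, fit$par[1], fit$par[2], fit$par[3], fit$par[4])
  resid_tbl <- tibble::tibble(
    injection = isotherm$injection, molar_ratio = isotherm$molar_ratio,
    observed = y, fitted = pred$ndh_kcal_mol,
    residual = y - pred$ndh_kcal_mol, used = use
  )
  structure(list(
    n = fit$par[1], n_se = se[1], kd_uM = fit$par[2], kd_se = se[2],
    dh = fit$par[3], dh_se = se[3], baseline = fit$par[4], baseline_se = se[4],
    c_value = c_value, residuals = resid_tbl, rss = fit$deviance,
    df_residual = sum(use) - 4, converged = converged, flag = flag,
    schedule = sch
  ), class = "itc_fit")
}

#' Derive the full thermodynamic signature from an ITC fit
#'
#' @param fit An `itc_fit` object.
#' @param temperature Temperature (K); defaults to the schedule's.
#' @return A one-row tibble: `kd_uM`, `dG`, `dH`, `TdS`, `n`, `temperature`.
#' @export
derive_thermodynamics <- function(fit, temperature = NULL) {
  stopifnot(inherits(fit, "itc_fit"))
  if (is.null(temperature)) temperature <- fit$schedule$temperature
  thermo_from_kd_dh(fit$kd_uM, fit$dh, temperature, n = fit$n)
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("One-site ITC fit\n")
  cat(sprintf("  n  = %.3f +/- %.3f\n", x$n, x$n_se))
  cat(sprintf("  Kd = %.3g +/- %.2g uM\n", x$kd_uM, x$kd_se))
  cat(sprintf("  dH = %.3g +/- %.2g kcal/mol, baseline %.3g\n",
    x$dh, x$dh_se, x$baseline))
  cat(sprintf("  Wiseman c = %.2f, converged: %s\n", x$c_value, x$converged))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Integrate a raw ITC thermogram into per-injection heats
#'
#' Secondary input path for instruments whose export is power versus time
#' rather than integrated heats. Each injection's segment (from its start to
#' the next injection, or to the end of the trace) is baseline-corrected
#' with a straight line anchored on the median power just before the
#' injection mark and in the window at the segment's far edge (where the
#' signal has returned to baseline), then integrated by the trapezoidal
#' rule.
#'
#' @param thermogram Tibble with columns `time_s` (strictly increasing) and
#'   `power_ucal_s` (differential power, ucal/s).
#' @param injection_times_s Start time of each injection (s), strictly
#'   increasing, all within the trace.
#' @param edge_points Number of points averaged (median) at each segment
#'   edge for the baseline anchors (default 5).
#' @return A tibble: `injection`, `t_start_s`, `t_end_s`, `heat_ucal`.
#' @export
integrate_thermogram <- function(thermogram, injection_times_s,
                                 edge_points = 5) {
  stopifnot(all(c("time_s", "power_ucal_s") %in% names(thermogram)))
  tt <- thermogram$time_s
  pp <- thermogram$power_ucal_s
  if (is.unsorted(tt, strictly = TRUE)) {
    rlang::abort("`time_s` must be strictly increasing.",
      class = "quadbind_input_error")
  }
  if (is.unsorted(injection_times_s, strictly = TRUE) ||
    min(injection_times_s) < tt[1] || max(injection_times_s) > tt[length(tt)]) {
    rlang::abort("`injection_times_s` must be increasing and inside the trace.",
      class = "quadbind_input_error")
  }
  bounds <- c(injection_times_s, tt[length(tt)])
  purrr::map(seq_along(injection_times_s), function(i) {
    sel <- which(tt >= bounds[i] & tt <= bounds[i + 1])
    if (length(sel) < 2 * edge_points + 2) {
      rlang::abort(sprintf("Injection %d: too few thermogram points.", i),
        class = "quadbind_input_error")
    }
    ts <- tt[sel]
    ps <- pp[sel]
    pre <- which(tt < bounds[i])
    if (length(pre) >= edge_points) {
      pre <- utils::tail(pre, edge_points)
      a0 <- stats::median(pp[pre])
      t0 <- mean(tt[pre])
    } else {
      a0 <- stats::median(utils::head(ps, edge_points))
      t0 <- mean(utils::head(ts, edge_points))
    }
    a1 <- stats::median(utils::tail(ps, edge_points))
    t1 <- mean(utils::tail(ts, edge_points))
    base <- a0 + (a1 - a0) * (ts - t0) / (t1 - t0)
    y <- ps - base
    tibble::tibble(
      injection = i, t_start_s = bounds[i], t_end_s = bounds[i + 1],
      heat_ucal = sum(diff(ts) * (y[-1] + y[-length(y)]) / 2)
    )
  }) |>
    purrr::list_rbind()
}
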