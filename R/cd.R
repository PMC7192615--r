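# CD spectrum normalization, G-quadruplex foldedness tracking at 262 nm, and
# two-state van't Hoff thermal melting fits.

#' Molar ellipticity per residue
#'
#' Standard CD normalization
#' \deqn{[\theta] = \theta_{mdeg} / (10 \cdot l \cdot c \cdot N)}
#' with path length \eqn{l} in cm, strand concentration \eqn{c} in mol/L and
#' \eqn{N} residues per strand; units deg cm^2 dmol^-1.
#'
#' @param ellipticity_mdeg Observed ellipticity (mdeg), vectorized.
#' @param path_cm Cuvette path length (cm, > 0).
#' @param conc_M Strand concentration (mol/L, > 0).
#' @param n_residues Number of residues (nucleotides) per strand (> 0).
#' @return Molar ellipticity per residue (deg cm^2 dmol^-1).
#' @export
molar_ellipticity <- function(ellipticity_mdeg, path_cm, conc_M, n_residues) {
  if (path_cm <= 0 || conc_M <= 0 || n_residues <= 0) {
    rlang::abort("`path_cm`, `conc_M` and `n_residues` must be > 0.",
      class = "quadbind_input_error")
  }
  ellipticity_mdeg / (10 * path_cm * conc_M * n_residues)
}

# nearest sampled wavelength within `tol` nm; no spectral interpolation
.signal_at <- function(wavelength_nm, ellipticity, target, tol = 1) {
  i <- which.min(abs(wavelength_nm - target))
  if (abs(wavelength_nm[i] - target) > tol) {
    rlang::abort(sprintf("No sampled wavelength within %g nm of %g nm.", tol, target),
      class = "quadbind_input_error")
  }
  ellipticity[i]
}

#' Relative foldedness versus titrant concentration
#'
#' Reads the G-quadruplex band (262 nm for a parallel RNA quadruplex) from
#' each spectrum of a protein-titration series and normalizes it to the
#' protein-free spectrum: \eqn{F(c) = \theta_{262}(c) / \theta_{262}(0)}.
#' Values are not clipped, so noise can push them slightly above 1. With
#' `unfolded_ref` given, a min-max variant
#' \eqn{(\theta(c) - \theta_u) / (\theta(0) - \theta_u)} is used instead,
#' anchoring 0 at a fully-unfolded reference signal.
#'
#' @param spectra Long tibble of the titration series: columns `titrant_uM`,
#'   `wavelength_nm`, `ellipticity` (any consistent ellipticity unit; the
#'   ratio cancels it). Must include a `titrant_uM == 0` spectrum.
#' @param wavelength Band to track (nm, default 262); read at the nearest
#'   sampled wavelength within `tol`.
#' @param tol Wavelength lookup tolerance (nm, default 1).
#' @param unfolded_ref Optional ellipticity of the fully-unfolded state at
#'   the target wavelength (same unit as `ellipticity`).
#' @return A tibble of class `foldedness_curve`: `titrant_uM`, `signal`,
#'   `foldedness`, ordered by concentration; foldedness is 1 at zero titrant
#'   by construction.
#' @export
foldedness_curve <- function(spectra, wavelength = 262, tol = 1,
                             unfolded_ref = NULL) {
  stopifnot(all(c("titrant_uM", "wavelength_nm", "ellipticity") %in% names(spectra)))
  if (!any(spectra$titrant_uM == 0)) {
    rlang::abort("A titrant-free (titrant_uM = 0) reference spectrum is required.",
      class = "quadbind_input_error")
  }
  curve <- spectra |>
    dplyr::group_by(.data$titrant_uM) |>
    dplyr::summarise(
      signal = .signal_at(.data$wavelength_nm, .data$ellipticity, wavelength, tol),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$titrant_uM)
  s0 <- curve$signal[curve$titrant_uM == 0][1]
  if (is.null(unfolded_ref)) {
    curve$foldedness <- curve$signal / s0
  } else {
    curve$foldedness <- (curve$signal - unfolded_ref) / (s0 - unfolded_ref)
  }
  class(curve) <- c("foldedness_curve", class(curve))
  curve
}

#' Percent decrease in foldedness between two titration curves
#'
#' Compares how much further a second protein construct unfolds the
#' quadruplex than a reference construct at one protein concentration:
#' \deqn{100 \cdot (F_{ref}(c) - F_{alt}(c)) / F_{ref}(c).}
#' Curves are linearly interpolated to `at_conc` when it is not a sampled
#' point.
#'
#' @param curve_ref Reference [foldedness_curve()] (e.g. UP1).
#' @param curve_alt Comparison [foldedness_curve()] (e.g. UP1+RGG).
#' @param at_conc Protein concentration at which to compare (uM).
#' @return Percent decrease (positive when `curve_alt` unfolds more).
#' @export
percent_decrease_foldedness <- function(curve_ref, curve_alt, at_conc) {
  fa <- .interp_curve(curve_ref, at_conc)
  fb <- .interp_curve(curve_alt, at_conc)
  if (abs(fa) < .Machine$double.eps^0.5) {
    rlang::abort("Reference foldedness is 0 at `at_conc`; percent decrease undefined.",
      class = "quadbind_input_error")
  }
  100 * (fa - fb) / fa
}

.interp_curve <- function(curve, at_conc) {
  rng <- range(curve$titrant_uM)
  if (at_conc < rng[1] || at_conc > rng[2]) {
    rlang::abort(sprintf("Concentration %g uM outside the curve's range [%g, %g].",
      at_conc, rng[1], rng[2]), class = "quadbind_input_error")
  }
  stats::approx(curve$titrant_uM, curve$foldedness, xout = at_conc,
    ties = "ordered")$y
}

#' Fraction folded under the two-state van't Hoff model
#'
#' \deqn{f(T) = \left[1 + \exp\!\big(\tfrac{\Delta H_{vH}}{R}
#'   (\tfrac{1}{T_m} - \tfrac{1}{T})\big)\right]^{-1}}
#' with absolute temperatures; exactly 1/2 at \eqn{T_m}.
#'
#' @param temperature_C Temperature (degC), vectorized.
#' @param tm_C Melting midpoint (degC).
#' @param dh_vh van't Hoff enthalpy of unfolding (kcal/mol, > 0 for a
#'   transition that melts on heating).
#' @return Fraction folded in (0, 1).
#' @export
fraction_folded <- function(temperature_C, tm_C, dh_vh) {
  t_k <- temperature_C + 273.15
  tm_k <- tm_C + 273.15
  1 / (1 + exp((dh_vh / .R_KCAL) * (1 / tm_k - 1 / t_k)))
}

#' Fit a two-state thermal melting curve
#'
#' Models a fixed-wavelength melting trace as a two-state folded/unfolded
#' equilibrium with linearly sloped (or flat) baselines:
#' \deqn{\theta(T) = (\theta_f + m_f T) f(T) + (\theta_u + m_u T) (1 - f(T))}
#' with \eqn{f(T)} from [fraction_folded()]. \eqn{T_m} is initialized at the
#' extremum of a lightly smoothed numerical derivative; a trace whose
#' steepest slope sits at an endpoint (no transition within the scanned
#' range) is returned flagged rather than fitted blindly.
#'
#' @param trace Tibble with columns `temperature_C` (strictly increasing,
#'   >= 20 points) and `ellipticity` (any consistent unit; mdeg typical).
#' @param baselines `"sloped"` (default) or `"flat"`.
#' @return An object of class `melt_fit`: `tm_C`, `tm_se`, `dh_vh`,
#'   `dh_vh_se`, baseline parameters, `residuals` (tibble), `rss`,
#'   `converged`, `flag`.
#' @export
fit_melting <- function(trace, baselines = c("sloped", "flat")) {
  baselines <- match.arg(baselines)
  stopifnot(all(c("temperature_C", "ellipticity") %in% names(trace)))
  tt <- trace$temperature_C
  yy <- trace$ellipticity
  if (length(tt) < 20) {
    rlang::abort("A melting trace needs at least 20 points.",
      class = "quadbind_input_error")
  }
  if (is.unsorted(tt, strictly = TRUE)) {
    rlang::abort("`temperature_C` must be strictly increasing.",
      class = "quadbind_input_error")
  }
  failed <- function(flag) {
    structure(list(
      tm_C = NA_real_, tm_se = NA_real_, dh_vh = NA_real_, dh_vh_se = NA_real_,
      theta_f = NA_real_, slope_f = NA_real_, theta_u = NA_real_,
      slope_u = NA_real_, baselines = baselines, residuals = NULL,
      rss = NA_real_, converged = FALSE, flag = flag
    ), class = "melt_fit")
  }
  # Tm init at the extremum of a 5-point running-mean smoothed derivative
  k <- 5
  ys <- stats::filter(yy, rep(1 / k, k), sides = 2)
  dy <- diff(as.numeric(ys)) / diff(tt)
  ok <- which(is.finite(dy))
  if (length(ok) < 5) return(failed("no_transition"))
  imax <- ok[which.max(abs(dy[ok]))]
  edge <- max(3, round(0.02 * length(dy)))
  if (imax <= ok[1] + edge - 1 || imax >= ok[length(ok)] - edge + 1) {
    return(failed("no_transition"))
  }
  tm0 <- tt[imax]
  n_edge <- max(5, round(length(tt) * 0.1))
  head_i <- seq_len(n_edge)
  tail_i <- seq(length(tt) - n_edge + 1, length(tt))
  cf <- unname(stats::coef(stats::lm(yy[head_i] ~ tt[head_i])))
  cu <- unname(stats::coef(stats::lm(yy[tail_i] ~ tt[tail_i])))
  par0 <- c(tm0, 50, cf[1], cf[2], cu[1], cu[2])
  if (baselines == "flat") par0 <- c(tm0, 50, mean(yy[head_i]), 0, mean(yy[tail_i]), 0)
  model <- function(par, t) {
    f <- fraction_folded(t, par[1], par[2])
    (par[3] + par[4] * t) * f + (par[5] + par[6] * t) * (1 - f)
  }
  free <- if (baselines == "sloped") 1:6 else c(1, 2, 3, 5)
  res_fn <- function(p) {
    par <- par0
    par[free] <- p
    yy - model(par, tt)
  }
  amp <- diff(range(yy))
  lo <- c(min(tt), 1, rep(-Inf, 4))
  hi <- c(max(tt), 1000, rep(Inf, 4))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = par0[free], fn = res_fn, lower = lo[free], upper = hi[free],
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !(fit$info %in% 1:4)) return(failed("non_convergence"))
  par <- par0
  par[free] <- fit$par
  se_free <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
    error = function(e) rep(NA_real_, length(free)))
  se <- rep(NA_real_, 6)
  se[free] <- se_free
  # a midpoint pinned to the range edge, or an enthalpy so small the
  # "transition" is flatter than the scan window (the model then degenerates
  # to a sloped line), means no real melt was captured
  flag <- NA_character_
  converged <- TRUE
  amp_tm <- abs((par[3] + par[4] * par[1]) - (par[5] + par[6] * par[1]))
  degenerate <- par[1] <= min(tt) + 1e-6 || par[1] >= max(tt) - 1e-6 ||
    par[2] <= 2 || amp_tm < 0.05 * max(diff(range(yy)), .Machine$double.eps)
  if (degenerate) {
    flag <- "no_transition"
    converged <- FALSE
  }
  fitted <- model(par, tt)
  structure(list(
    tm_C = par[1], tm_se = se[1], dh_vh = par[2], dh_vh_se = se[2],
    theta_f = par[3], slope_f = par[4], theta_u = par[5], slope_u = par[6],
    baselines = baselines,
    residuals = tibble::tibble(temperature_C = tt, observed = yy,
      fitted = fitted, residual = yy - fitted),
    rss = sum((yy - fitted)^2), converged = converged, flag = flag
  ), class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat("Two-state melting fit\n")
  cat(sprintf("  Tm = %.2f +/- %.2g degC\n", x$tm_C, x$tm_se))
  cat(sprintf("  van't Hoff dH = %.3g +/- %.2g kcal/mol\n", x$dh_vh, x$dh_vh_se))
  cat(sprintf("  baselines: %s, converged: %s\n", x$baselines, x$converged))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}
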