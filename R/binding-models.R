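# Closed-form 1:1 binding mathematics and thermodynamic relations shared by
# the CSP, ITC and CD fitting layers. All concentrations share one unit
# (canonically uM); unit conversion is the caller's responsibility.

#' Gas constant in kcal mol^-1 K^-1
#' @keywords internal
.R_KCAL <- 1.987e-3

#' Fraction of protein bound under 1:1 binding with ligand depletion
#'
#' Solves the 1:1 mass-balance quadratic for the bound complex and returns the
#' fraction of total protein in the complex,
#' \deqn{f = \frac{P + L + K_d - \sqrt{(P + L + K_d)^2 - 4 P L}}{2 P}.}
#' Unlike the Langmuir form \eqn{L/(L + K_d)}, this accounts for depletion of
#' free ligand by binding, which matters whenever the protein concentration is
#' comparable to (or exceeds) \eqn{K_d} — the regime of an NMR-detected
#' titration at hundreds of micromolar protein.
#'
#' All three arguments must be in the same concentration unit. The square-root
#' argument can dip a hair below zero by floating-point round-off when
#' \eqn{P \approx L} and \eqn{K_d \to 0}; it is clamped at zero (tolerance
#' 1e-12 relative).
#'
#' @param p_total Total protein concentration (> 0).
#' @param l_total Total ligand (RNA) concentration (>= 0).
#' @param kd Equilibrium dissociation constant (> 0), same unit.
#' @return Fraction bound in \[0, 1\], vectorized over the inputs.
#' @examples
#' fraction_bound(138, 414, kd = 11)
#' fraction_bound(1, 1, kd = 1) # (3 - sqrt(5)) / 2
#' @export
fraction_bound <- function(p_total, l_total, kd) {
  if (any(!is.finite(p_total)) || any(p_total <= 0)) {
    rlang::abort("`p_total` must be finite and > 0.", class = "quadbind_input_error")
  }
  if (any(!is.finite(kd)) || any(kd <= 0)) {
    rlang::abort("`kd` must be finite and > 0.", class = "quadbind_input_error")
  }
  if (any(!is.finite(l_total)) || any(l_total < 0)) {
    rlang::abort("`l_total` must be finite and >= 0.", class = "quadbind_input_error")
  }
  s <- p_total + l_total + kd
  disc <- s^2 - 4 * p_total * l_total
  disc[disc < 0] <- 0
  (s - sqrt(disc)) / (2 * p_total)
}

#' Predicted chemical shift perturbation under fast exchange
#'
#' In the fast-exchange NMR regime the observed combined shift change of a
#' residue is the population-weighted average of its free and bound positions,
#' so \eqn{\Delta\delta_{obs} = \Delta\delta_{max} \cdot f_{bound}} with
#' \eqn{f_{bound}} from [fraction_bound()].
#'
#' @inheritParams fraction_bound
#' @param ddmax Shift change at full saturation (ppm, >= 0).
#' @return Predicted combined CSP in ppm.
#' @export
csp_predicted <- function(p_total, l_total, kd, ddmax) {
  if (any(!is.finite(ddmax)) || any(ddmax < 0)) {
    rlang::abort("`ddmax` must be finite and >= 0.", class = "quadbind_input_error")
  }
  ddmax * fraction_bound(p_total, l_total, kd)
}

#' Binding free energy from a dissociation constant
#'
#' \eqn{\Delta G = R T \ln(K_d)} with \eqn{K_d} converted from uM to the 1 M
#' standard state and \eqn{R = 1.987 \times 10^{-3}} kcal mol^-1 K^-1.
#'
#' @param kd_uM Dissociation constant in uM (> 0).
#' @param temperature Temperature in K (default 298.15, i.e. 25 degC).
#' @return Free energy change in kcal/mol (negative for sub-molar \eqn{K_d}).
#' @examples
#' delta_g_from_kd(2.37) # approx -7.67 kcal/mol
#' @export
delta_g_from_kd <- function(kd_uM, temperature = 298.15) {
  if (any(!is.finite(kd_uM)) || any(kd_uM <= 0)) {
    rlang::abort("`kd_uM` must be finite and > 0.", class = "quadbind_input_error")
  }
  if (any(temperature <= 0)) {
    rlang::abort("`temperature` must be > 0 K.", class = "quadbind_input_error")
  }
  .R_KCAL * temperature * log(kd_uM * 1e-6)
}

#' Entropic term from enthalpy and free energy
#'
#' \eqn{T\Delta S = \Delta H - \Delta G}; exact subtraction, kcal/mol in and out.
#'
#' @param dh Enthalpy change (kcal/mol).
#' @param dg Free energy change (kcal/mol).
#' @return \eqn{T\Delta S} in kcal/mol.
#' @export
tds_from_dh_dg <- function(dh, dg) {
  dh - dg
}

#' Full thermodynamic parameter set from Kd and enthalpy
#'
#' Convenience constructor: derives \eqn{\Delta G} from \eqn{K_d} and
#' \eqn{T\Delta S = \Delta H - \Delta G} at the given temperature.
#'
#' @inheritParams delta_g_from_kd
#' @param dh Enthalpy change (kcal/mol).
#' @param n Binding stoichiometry (default NA).
#' @return A tibble with columns `kd_uM`, `dG`, `dH`, `TdS`, `n`,
#'   `temperature`.
#' @export
thermo_from_kd_dh <- function(kd_uM, dh, temperature = 298.15, n = NA_real_) {
  dg <- delta_g_from_kd(kd_uM, temperature)
  tibble::tibble(
    kd_uM = kd_uM, dG = dg, dH = dh, TdS = tds_from_dh_dg(dh, dg),
    n = n, temperature = temperature
  )
}

#' Check internal consistency of a thermodynamics table
#'
#' Verifies, row by row, the two identities a one-site ITC parameter table
#' must satisfy: \eqn{\Delta G = R T \ln K_d} (1 M standard state) and
#' \eqn{\Delta G = \Delta H - T\Delta S}, each within `tol` kcal/mol.
#' Useful both for validating fits and for spotting transcription errors in
#' published tables.
#'
#' @param thermo A data frame with columns `kd_uM`, `dG`, `dH`, `TdS`.
#' @param temperature Temperature in K used for the \eqn{\Delta G}-from-Kd
#'   identity.
#' @param tol Tolerance in kcal/mol (default 0.02, i.e. printed-precision
#'   rounding).
#' @return The input with logical columns `dg_consistent`, `tds_consistent`
#'   and `consistent` appended.
#' @export
check_thermo_consistency <- function(thermo, temperature = 298.15, tol = 0.02) {
  stopifnot(all(c("kd_uM", "dG", "dH", "TdS") %in% names(thermo)))
  dg_calc <- delta_g_from_kd(thermo$kd_uM, temperature)
  dg_id <- dplyr::mutate(
    tibble::as_tibble(thermo),
    dg_consistent = abs(dg_calc - .data$dG) <= tol,
    tds_consistent = abs((.data$dH - .data$dG) - .data$TdS) <= tol,
    consistent = .data$dg_consistent & .data$tds_consistent
  )
  dg_id
}

#' Published thermodynamic parameters for hnRNPA1 constructs binding TERRA RNA
#'
#' Reference one-site ITC parameters (25 degC, 100 mM KCl) for the
#' interactions of the hnRNPA1 UP1 domain, UP1+RGG, and the isolated RGG-box
#' with single-stranded RNA and with TERRA RNA G-quadruplexes of tetrameric
#' (TERRA-6), dimeric (TERRA-12) and intramolecular (TERRA-24) topology.
#' Values are stored verbatim as printed; run [check_thermo_consistency()] to
#' see that one row's printed \eqn{T\Delta S} is inconsistent with its own
#' \eqn{\Delta H - \Delta G} (a transcription error in the source table).
#'
#' @return A tibble with columns `experiment`, `kd_uM`, `kd_se`, `dG`, `dH`,
#'   `dh_se`, `TdS`, `n`, `n_se` (energies kcal/mol, Kd uM).
#' @export
reference_thermo_table <- function() {
  tibble::tribble(
    ~experiment,                          ~kd_uM, ~kd_se, ~dG,   ~dH,    ~dh_se, ~TdS,   ~n,   ~n_se,
    "UP1:ssRNA-18",                       2.37,   0.49,   -7.67, -19.7,  1.23,   -12.03, 1.04, 0.05,
    "UP1+RGG:ssRNA-18",                   2.28,   0.26,   -7.69, -20.4,  0.71,   -12.71, 0.97, 0.03,
    "UP1:TERRA-6",                        2.02,   0.17,   -7.76, -31.31, 1.4,    -23.55, 1.22, 0.04,
    "UP1+RGG:TERRA-6",                    2.38,   0.23,   -7.66, -38.84, 2.74,   -31.18, 1.14, 0.07,
    "UP1:TERRA-12",                       2.04,   0.47,   -7.75, -36.38, 5.61,   -28.63, 0.93, 0.12,
    "UP1+RGG:TERRA-12",                   1.07,   0.14,   -8.13, -43.01, 2.48,   -34.88, 0.88, 0.04,
    "UP1:TERRA-24",                       1.71,   0.17,   -7.86, -29.66, 0.95,   -37.52, 0.80, 0.02,
    "UP1+RGG:TERRA-24",                   0.92,   0.17,   -8.23, -41.88, 2.81,   -33.65, 0.82, 0.04,
    "UP1+RGG:TERRA-24 (20% PEG 200)",     3.0,    0.55,   -7.53, -40.89, 4.15,   -33.36, 1.14, 0.09,
    "RGG:TERRA-24",                       9.0,    4.3,    -6.88, -0.67,  0.27,   6.21,   1.06, 0.34
  )
}
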