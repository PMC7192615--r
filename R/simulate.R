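# Seeded forward simulators for the three modalities. Each generator uses the
# same forward model its fitter assumes, so a noise-free simulation
# round-trips exactly; ground truth travels on the "truth" attribute.

#' Simulate a fast-exchange CSP titration
#'
#' Generates per-step HSQC peak positions for a panel of residues titrated
#' with ligand under the 1:1 depletion model. Each residue gets a reference
#' position and a fixed direction in the (1H, 15N) plane drawn once from the
#' seed, so its peak walks colinearly from free to bound — the fast-exchange
#' signature. The combined CSP along that walk equals
#' [csp_predicted()] exactly; the 1H/15N split is a random partition
#' consistent with the combined statistic (15N scaled by `n_scale`).
#' Gaussian noise is added per dimension at every step, the reference
#' included.
#'
#' Defaults mirror a typical high-concentration protein-observed design:
#' 138 uM protein, RNA at 0.2/0.5/1/2/3 molar ratios, 14 residues with
#' saturation shifts of 0.05-0.30 ppm, and instrument-class noise of
#' 0.005 ppm (1H) / 0.025 ppm (15N).
#'
#' @param kd_uM True dissociation constant (uM).
#' @param n_residues Number of residues when `ddmax` is not supplied.
#' @param ddmax Per-residue saturation shifts (ppm); default drawn uniformly
#'   from 0.05-0.30.
#' @param protein_uM Total protein concentration (uM, constant across steps).
#' @param ratios Ligand:protein molar ratios, starting at 0.
#' @param sigma_h,sigma_n Gaussian noise SDs on the 1H and 15N peak positions
#'   (ppm).
#' @param n_scale 15N scaling divisor of the combined CSP statistic.
#' @param seed Integer seed (required).
#' @return A titration-series tibble (columns as [titration_series()]) with
#'   attribute `truth`: list of `kd_uM`, `ddmax` (tibble residue/ddmax),
#'   `protein_uM`, `ligand_uM`.
#' @export
sim_csp_titration <- function(kd_uM = 11, n_residues = 14, ddmax = NULL,
                              protein_uM = 138,
                              ratios = c(0, 0.2, 0.5, 1, 2, 3),
                              sigma_h = 0.005, sigma_n = 0.025,
                              n_scale = 5, seed) {
  if (missing(seed)) rlang::abort("`seed` is required.", class = "quadbind_input_error")
  ligand_uM <- protein_uM * ratios
  sim <- withr::with_seed(seed, {
    if (is.null(ddmax)) ddmax <- stats::runif(n_residues, 0.05, 0.30)
    n_residues <- length(ddmax)
    residues <- sprintf("res%02d", seq_len(n_residues))
    h0 <- stats::runif(n_residues, 7.5, 9.5)
    n0 <- stats::runif(n_residues, 105, 130)
    phi <- stats::runif(n_residues, 0, 2 * pi)
    steps <- purrr::map(seq_along(ligand_uM), function(i) {
      dobs <- csp_predicted(protein_uM, ligand_uM[i], kd_uM, ddmax)
      tibble::tibble(
        step = i - 1L, protein_uM = protein_uM, ligand_uM = ligand_uM[i],
        residue = residues,
        h_ppm = h0 + dobs * cos(phi) + stats::rnorm(n_residues, 0, sigma_h),
        n_ppm = n0 + n_scale * dobs * sin(phi) +
          stats::rnorm(n_residues, 0, sigma_n)
      )
    }) |>
      purrr::list_rbind()
    list(steps = steps, ddmax = ddmax, residues = residues)
  })
  steps <- sim$steps
  attr(steps, "truth") <- list(
    kd_uM = kd_uM,
    ddmax = tibble::tibble(residue = sim$residues, ddmax = sim$ddmax),
    protein_uM = protein_uM, ligand_uM = ligand_uM
  )
  steps
}

#' Simulate a one-site ITC experiment
#'
#' Forward-models per-injection heats with [itc_predict()] and adds Gaussian
#' noise with a per-injection SD of `noise` times the injection's heat
#' magnitude, floored at `noise_floor_ucal`. An optional constant heat of
#' dilution per injection can be layered on, to exercise the correction
#' routines.
#'
#' Defaults reproduce a tight RNA-protein titration: 5 uM macromolecule in a
#' 200 ul cell, 200 uM syringe, 20 x 2 ul injections, 2% heat noise.
#'
#' @param n,kd_uM,dh True stoichiometry, dissociation constant (uM) and
#'   enthalpy (kcal/mol).
#' @param schedule An [itc_schedule()]; default 200 uM into 5 uM, 20 x 2 ul.
#' @param noise Relative heat noise (fraction of each injection's predicted
#'   heat magnitude), default 0.02.
#' @param noise_floor_ucal Absolute noise floor (ucal), default 0.02.
#' @param dilution_heat_ucal Constant additional heat per injection (ucal),
#'   default 0.
#' @param seed Integer seed (required).
#' @return An [itc_isotherm()] with attribute `truth`: list of `n`, `kd_uM`,
#'   `dh`, `dilution_heat_ucal`.
#' @export
sim_itc <- function(n = 0.82, kd_uM = 0.92, dh = -41.88,
                    schedule = itc_schedule(cell_conc_uM = 5,
                      syringe_conc_uM = 200),
                    noise = 0.02, noise_floor_ucal = 0.02,
                    dilution_heat_ucal = 0, seed) {
  if (missing(seed)) rlang::abort("`seed` is required.", class = "quadbind_input_error")
  pred <- itc_predict(schedule, n, kd_uM, dh)
  sigma <- pmax(noise * abs(pred$heat_ucal), noise_floor_ucal)
  if (noise == 0) sigma <- 0
  heats <- withr::with_seed(seed,
    pred$heat_ucal + stats::rnorm(nrow(pred), 0, sigma) + dilution_heat_ucal)
  iso <- itc_isotherm(schedule, heats)
  attr(iso, "truth") <- list(n = n, kd_uM = kd_uM, dh = dh,
    dilution_heat_ucal = dilution_heat_ucal)
  iso
}

#' Simulate a CD protein-titration series of a parallel G-quadruplex
#'
#' Builds wavelength scans from a parameterized parallel-quadruplex reference
#' shape — a positive Gaussian band near 262 nm and a negative trough near
#' 240 nm — whose amplitude scales with foldedness. Foldedness decays
#' exponentially with titrant concentration, \eqn{F(c) = \exp(-c /
#' c_{decay})}, emulating progressive protein-driven unfolding; any other
#' profile can be supplied directly. Gaussian noise is `noise` times the
#' 262 nm band amplitude.
#'
#' @param titrant_uM Protein concentrations of the series (uM), starting
#'   at 0.
#' @param foldedness Optional explicit foldedness per concentration; default
#'   `exp(-titrant_uM / decay_uM)`.
#' @param decay_uM Exponential decay scale of foldedness (uM), default 25.
#' @param wavelength_nm Scan grid (nm), default 225-325 in 1 nm steps.
#' @param band_amp Amplitude of the 262 nm band at full foldedness (mdeg),
#'   default 10.
#' @param noise Relative noise (fraction of `band_amp`), default 0.01.
#' @param seed Integer seed (required).
#' @return A spectra tibble (`titrant_uM`, `wavelength_nm`, `ellipticity`)
#'   with attribute `truth`: tibble of `titrant_uM`, `foldedness`.
#' @export
sim_cd_titration <- function(titrant_uM = c(0, 2.5, 5, 10, 15, 20, 25),
                             foldedness = NULL, decay_uM = 25,
                             wavelength_nm = 225:325, band_amp = 10,
                             noise = 0.01, seed) {
  if (missing(seed)) rlang::abort("`seed` is required.", class = "quadbind_input_error")
  if (is.null(foldedness)) foldedness <- exp(-titrant_uM / decay_uM)
  stopifnot(length(foldedness) == length(titrant_uM), titrant_uM[1] == 0)
  shape <- band_amp * exp(-(wavelength_nm - 262)^2 / (2 * 6^2)) -
    0.5 * band_amp * exp(-(wavelength_nm - 240)^2 / (2 * 5^2))
  out <- withr::with_seed(seed, purrr::map(seq_along(titrant_uM), function(i) {
    tibble::tibble(
      titrant_uM = titrant_uM[i],
      wavelength_nm = wavelength_nm,
      ellipticity = foldedness[i] * shape +
        stats::rnorm(length(wavelength_nm), 0, noise * band_amp)
    )
  }) |>
    purrr::list_rbind())
  attr(out, "truth") <- tibble::tibble(titrant_uM = titrant_uM,
    foldedness = foldedness)
  out
}

#' Simulate a two-state CD melting trace
#'
#' Forward model of [fit_melting()]: two-state van't Hoff transition between
#' sloped folded and unfolded baselines, sampled on a regular temperature
#' grid. Noise SD is `noise` times the folded-unfolded amplitude at the
#' midpoint.
#'
#' @param tm_C True melting midpoint (degC), default 80.5.
#' @param dh_vh van't Hoff unfolding enthalpy (kcal/mol), default 50 — the
#'   middle of the range reported for intramolecular telomeric-repeat
#'   quadruplex unfolding.
#' @param theta_f,slope_f Folded-baseline intercept (mdeg) and slope
#'   (mdeg/degC).
#' @param theta_u,slope_u Unfolded-baseline intercept and slope.
#' @param temperature_C Temperature grid (degC), default 10-100 every 0.5.
#' @param noise Relative noise (fraction of the transition amplitude at
#'   `tm_C`), default 0.02.
#' @param seed Integer seed (required).
#' @return A melting-trace tibble (`temperature_C`, `ellipticity`) with
#'   attribute `truth`: list of the generating parameters.
#' @export
sim_cd_melt <- function(tm_C = 80.5, dh_vh = 50,
                        theta_f = 10, slope_f = -0.01,
                        theta_u = 1.5, slope_u = -0.005,
                        temperature_C = seq(10, 100, by = 0.5),
                        noise = 0.02, seed) {
  if (missing(seed)) rlang::abort("`seed` is required.", class = "quadbind_input_error")
  f <- fraction_folded(temperature_C, tm_C, dh_vh)
  clean <- (theta_f + slope_f * temperature_C) * f +
    (theta_u + slope_u * temperature_C) * (1 - f)
  amp <- abs((theta_f + slope_f * tm_C) - (theta_u + slope_u * tm_C))
  out <- tibble::tibble(
    temperature_C = temperature_C,
    ellipticity = clean +
      withr::with_seed(seed, stats::rnorm(length(clean), 0, noise * amp))
  )
  attr(out, "truth") <- list(tm_C = tm_C, dh_vh = dh_vh, theta_f = theta_f,
    slope_f = slope_f, theta_u = theta_u, slope_u = slope_u)
  out
}
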