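---
title: "Quantifying protein–G-quadruplex binding from CSP, ITC and CD data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein–G-quadruplex binding from CSP, ITC and CD data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadbind)
```

quadbind quantifies 1:1 protein–nucleic-acid binding from three solution
experiments that see the same interaction through different observables:
per-residue NMR chemical shift perturbations (CSPs), calorimetric heats
(ITC), and circular dichroism (CD) of the nucleic-acid fold. This vignette
is the package's account of the underlying models, the choices made where
the methodology is genuinely open, and what the built-in simulators do and
do not establish.

The motivating system is hnRNPA1 binding TERRA, the telomeric
repeat-containing RNA. TERRA repeats fold into parallel G-quadruplexes —
four-stranded structures of stacked guanine tetrads with a CD maximum near
262 nm — and hnRNPA1 engages them through its folded UP1 domain and its
disordered arginine-glycine-glycine (RGG) motif region. Everything below is
generic 1:1 machinery, but defaults are set to that system's experimental
designs.

## The shared binding model

All three modalities rest on one piece of mathematics: the 1:1 mass-balance
quadratic. With total protein $P$, total ligand $L$ and dissociation
constant $K_d$ in one shared concentration unit, the fraction of protein in
the complex is

$$
f = \frac{P + L + K_d - \sqrt{(P + L + K_d)^2 - 4 P L}}{2P}.
$$

The familiar Langmuir form $L/(L + K_d)$ is its $P \to 0$ limit; at the
concentrations where NMR and ITC operate (tens to hundreds of micromolar,
often well above $K_d$), free-ligand depletion is substantial and the
quadratic is mandatory. `fraction_bound()` implements it with one numerical
guard: the discriminant can round to $-\varepsilon$ when $P \approx L$ and
$K_d \to 0$, so it is clamped at zero (relative scale $10^{-12}$). The
implementation is verified in the test suite against a brute-force
`uniroot()` solution of the mass balance to $10^{-10}$ over 1,000 random
$(P, L, K_d)$ triples.

Thermodynamic conversions use $\Delta G = R T \ln K_d$ with the 1 M
standard state, $R = 1.987 \times 10^{-3}$ kcal mol$^{-1}$ K$^{-1}$, and a
default $T = 298.15$ K, plus $T\Delta S = \Delta H - \Delta G$. The
reference temperature matters at the 0.01 kcal/mol level only; both
298 K and 298.15 K reproduce the shipped reference table
(`reference_thermo_table()`) to its printed precision, and 298.15 K (25 °C,
the nominal experimental temperature) was adopted. One row of that table
carries a printed $T\Delta S$ inconsistent with its own $\Delta H - \Delta G$
by 15.7 kcal/mol; `check_thermo_consistency()` flags it, and the package
treats the $K_d$, $\Delta G$ and $\Delta H$ columns (which are mutually
consistent) as the reliable ones.

## CSP titrations

In the fast-exchange NMR regime a residue shows one population-averaged
peak that walks from its free to its bound position as ligand is added. The
combined amide CSP against the ligand-free reference is

$$
\delta_{obs} = \sqrt{(\Delta\delta_H)^2 + (\Delta\delta_N / s)^2},
$$

with the $^{15}$N change scaled down by $s = 5$ — the conventional factor
compensating the wider nitrogen shift dispersion, exposed as `n_scale` for
users who prefer 6.5 or a gyromagnetic-ratio-based value. Because
$\delta_{obs} = \Delta\delta_{max} \cdot f$, each trajectory carries
information on $K_d$ and on its own saturation shift.

`fit_csp_individual()` fits every residue alone: two parameters, uniform
point weights (peak lists carry no per-point errors), Levenberg–Marquardt
with box bounds $K_d \in (10^{-3}, 10^{5})$ µM and $\Delta\delta_{max} \in
(0, 5)$ ppm, initialized at the largest observed shift and the interpolated
ligand concentration of half-maximal shift. `fit_csp_global()` is the
primary estimator: one shared $K_d$, one free $\Delta\delta_{max}$ per
residue, fitted simultaneously. A phrase like "individual fits combined
into a global $K_d$" can mean either a simultaneous shared-parameter
regression or an average of apparent $K_d$s; the simultaneous regression is
standard practice and is what `fit_csp_global()` does, while
`average_individual_kd()` reports the averaging reading as a secondary
statistic.

Uncertainty on the shared $K_d$ comes from the asymptotic covariance, and
optionally from a case bootstrap that resamples residues with replacement
(`boot = 200`–`500`, seeded). With only ~14 residues the bootstrap is the
more honest error; it also absorbs genuine residue-to-residue heterogeneity
in apparent affinity, which the asymptotic error does not.

Degenerate inputs are flagged, never silently fitted: an all-zero
trajectory returns `non_identifiable`, a $K_d$ pinned at a box bound
returns `kd_at_bound`, and residues missing from any titration step are
dropped from `csp_combine()` with a warning naming them.

Two bookkeeping decisions follow the experimental reality. Ligand
concentration per step is whatever the user supplies (molar-ratio schedules
are converted by the caller or the simulator); no automatic dilution
correction is applied to the protein, since whether and how the protein was
diluted during a titration is instrument- and protocol-specific — the
per-step `protein_uM` column is the hook for dilution-corrected values.
Peak matching across steps is by identical residue label; minimum-distance
auto-tracking of unassigned peaks is deliberately out of scope.

`classify_perturbed()` separates responding from silent residues by
end-point CSP. The default rule thresholds at 15% of the largest end-point
CSP with an absolute floor of 0.01 ppm (the scale of combined-CSP noise at
~0.005 ppm shift precision). A mean + 1 SD rule over all residues is
available as `rule = "mean_sd"`, but it is not the default for a structural
reason: when most of the panel responds — the normal situation for a short
binding motif — the responders inflate their own threshold, and that rule
provably cannot flag a responsive majority.

## One-site ITC

An overflow perfusion cell holds a fixed active volume $V_0$; injecting
$dV$ displaces an equal volume of mixed contents. The package uses the
conventional first-order bookkeeping (the same family as the vendor
software): after cumulative injected volume $\Delta V$, the macromolecule
is diluted by $(1 - \Delta V/2V_0)/(1 + \Delta V/2V_0)$ and titrant
accumulates to $X_s (\Delta V/V_0)/(1 + \Delta V/2V_0)$. Against an exact
exponential-dilution recursion the error is below 1% for 40 µl injected
into 200 µl (tested). The cell volume is not usually quoted in papers;
200 µl — the iTC200 instrument class — is the default and is configurable.

With site concentration $n M_t$ and occupancy $\Theta$ from the shared
quadratic, the cell heat content is $Q_i = n \Theta_i M_{t,i} V_0 \Delta H$
and the measured heat of injection $i$ is

$$
\Delta Q_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0} \frac{Q_i + Q_{i-1}}{2},
$$

normalized per mole of injectant for fitting. `fit_itc()` floats all four
parameters $(n, K_d, \Delta H, \text{baseline})$, initializing the baseline
from the mean of the last three heats, $\Delta H$ from the first usable
heat, $n$ from the molar ratio at the steepest descent, and $K_d$ at the
cell concentration. Standard errors are asymptotic, as in the vendor
software family (support-plane errors are not implemented). The Wiseman
parameter $c = n[M]/K_d$ governs identifiability; fits with $c < 1$ are
flagged `low_c` because the isotherm is then too shallow to pin $n$, $K_d$
and $\Delta H$ separately.

Heat-of-dilution correction (`correct_dilution()`) subtracts either a
matched buffer-titration control or the mean of the last $k = 3$ saturated
heats. The two agree when the dilution heat is constant *and* the tail is
truly saturated; for a moderate-affinity system the tail still contains
binding heat, and tail-averaging then removes some signal — the control
titration is the better mode whenever one was measured. First-injection
discard is available (`discard_first = TRUE`, volume still counted in the
bookkeeping) but off by default, since not every protocol discards it.

## CD foldedness and thermal melting

Spectra are normalized as molar ellipticity per residue,
$[\theta] = \theta_{mdeg} / (10\, l\, c\, N)$ with path length $l$ in cm,
strand concentration $c$ in mol/L and $N$ residues. The parallel-quadruplex
band is read at the sampled wavelength nearest 262 nm (tolerance 1 nm, no
spectral interpolation), and relative foldedness during a protein titration
is the plain ratio $F(c) = \theta_{262}(c)/\theta_{262}(0)$. Whether such a
normalization should first subtract a fully-unfolded offset is ambiguous in
practice; the plain ratio is the default and a min–max variant against an
unfolded reference signal is available via `unfolded_ref`. $F$ is not
clipped, so noise can push it slightly above 1. `percent_decrease_foldedness()`
compares two constructs at one concentration,
$100 (F_{ref} - F_{alt})/F_{ref}$, interpolating linearly between sampled
concentrations.

Melting traces are modelled as a two-state van't Hoff equilibrium between
sloped linear baselines,

$$
\theta(T) = (\theta_f + m_f T) f(T) + (\theta_u + m_u T)(1 - f(T)),
\qquad
f(T) = \Big[1 + e^{\frac{\Delta H_{vH}}{R}(\frac{1}{T_m} - \frac{1}{T})}\Big]^{-1},
$$

so the fraction folded is exactly 1/2 at $T_m$. $T_m$ is initialized at the
extremum of a 5-point running-mean smoothed derivative (smoothing is used
only for initialization, never applied to the fitted data); baselines are
initialized from straight-line fits to the first and last 10% of points. A
`"flat"` baseline option exists for short traces. Three degeneracies return
a `no_transition` flag instead of numbers: the steepest smoothed slope at a
scan endpoint, a fitted midpoint pinned to the temperature range edge, and
a fitted transition amplitude below 5% of the data range (the model has
then degenerated to a line). $T_m$ is invariant to affine rescaling of the
signal, so the fit does not care whether input is mdeg or normalized
ellipticity.

## The simulators

Each generator is the exact forward model of its fitter, so a noise-free
simulation round-trips to numerical tolerance — that is a correctness
check, not evidence about real data. All are driven by a mandatory integer
seed through `withr::with_seed`, leaving the caller's RNG state untouched,
and byte-identical under seed reuse.

* `sim_csp_titration()` — defaults mirror the NMR design: 138 µM protein,
  ligand at 0/0.2/0.5/1/2/3 molar ratios, 14 residues with saturation
  shifts drawn once from U(0.05, 0.30) ppm, true $K_d$ = 11 µM. Each
  residue gets a fixed random direction in the ($^1$H, $^{15}$N) plane, so
  its peak walks colinearly — the fast-exchange signature. Gaussian noise
  of 0.005 ppm ($^1$H) and 0.025 ppm ($^{15}$N) — instrument-class shift
  precision — is added to every peak position, reference included.
* `sim_itc()` — defaults mirror the calorimetric design: 5 µM cell, 200 µM
  syringe, 20 × 2 µl; noise is 2% of each injection's heat with a 0.02 µcal
  floor; a constant dilution heat can be layered on.
* `sim_cd_titration()` — parameterized parallel-quadruplex spectral shape
  (positive Gaussian band at 262 nm, negative trough at 240 nm) scaled by
  an exponential-decay foldedness profile; noise 1% of the band amplitude.
* `sim_cd_melt()` — the two-state model over 10–100 °C every 0.5 °C; the
  default midpoint 80.5 °C is the intramolecular TERRA quadruplex value,
  and the default van't Hoff enthalpy of 50 kcal/mol sits mid-range of
  published values for intramolecular telomeric-repeat quadruplex
  unfolding (the melting experiments report only $T_m$). Noise is 2% of the
  transition amplitude at $T_m$.

What the simulators do **not** emulate: exchange broadening and peak
overlap (NMR), baseline drift and injection-to-injection integration error
(ITC), instrument drift and wavelength-dependent noise (CD), and any
deviation from 1:1 stoichiometric binding. Passing recovery tests therefore
demonstrates that the estimators are correct and well-calibrated *for the
model class*; they cannot certify behavior on pathological real data.

A note on precision at the default designs, as measured by the package's
own seeded replicate tests: the global CSP $K_d$ is recovered with a median
within 15% of truth, but a 138 µM protein titration of an 11 µM binder is
partly stoichiometric, so individual replicates scatter by a few µM. A
single 2%-noise melting trace with free sloped baselines determines $T_m$
to roughly ±0.5–0.8 °C (asymptotic SE); sub-0.5 °C statements are median
statements over replicates.

## Problem sizes

The shipped tests use 100 seeded replicates for CSP recovery and melting
round-trip properties, 50 replicates per parameter set for ITC recovery
(nine published parameter sets), and 1,000 random triples for the
quadratic-solver equivalence — sizes at which the medians under comparison
are stable to well within the tolerances being asserted. The acceptance
script uses 20 CSP replicates, 50 ITC replicates and one melting trace,
matching how the corresponding quantities are defined.

## Known limitations

Single-site 1:1 binding only: no cooperative or multi-site polynomials, no
competitive ITC, no slow/intermediate-exchange lineshape analysis, no
automated resonance assignment or peak tracking, no spectral deconvolution
or quadruplex topology classification from CD. The primary ITC input is
pre-integrated heats; `integrate_thermogram()` provides a secondary path
from power-versus-time traces (linear per-injection baseline, trapezoidal
integration) but does not model baseline artifacts beyond a straight line.
Asymptotic errors assume approximately Gaussian residuals; for small
residue panels prefer the bootstrap.
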