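# Independent oracles used across the suite.

# Brute-force 1:1 mass-balance solution: find the complex concentration C
# with uniroot on  (P - C)(L - C)/C = Kd  and return C / P.
oracle_fraction_bound <- function(p, l, kd) {
  if (l == 0) return(0)
  g <- function(cc) (p - cc) * (l - cc) - kd * cc
  upper <- min(p, l)
  stats::uniroot(g, c(0, upper), tol = 1e-15)$root / p
}

# Exact stepwise perfusion dilution: each injection of volume dv into a
# constant-volume cell dilutes the contents by exp(-dv/V0) while the titrant
# relaxes toward the syringe concentration.
oracle_itc_concentrations <- function(cell_conc, syringe_conc, injections, v0) {
  m <- cell_conc
  x <- 0
  out <- matrix(NA_real_, nrow = length(injections), ncol = 2,
    dimnames = list(NULL, c("mt", "xt")))
  for (i in seq_along(injections)) {
    d <- exp(-injections[i] / v0)
    m <- m * d
    x <- x * d + syringe_conc * (1 - d)
    out[i, ] <- c(m, x)
  }
  out
}

# Minimal noise-free single-residue CSP trajectory for a given schedule.
make_trajectory <- function(kd, ddmax, protein_uM = 138,
                            ligand_uM = 138 * c(0, 0.2, 0.5, 1, 2, 3),
                            residue = "resA") {
  tibble::tibble(
    residue = residue, step = seq_along(ligand_uM) - 1L,
    protein_uM = protein_uM, ligand_uM = ligand_uM,
    dobs = csp_predicted(protein_uM, ligand_uM, kd, ddmax)
  )
}
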