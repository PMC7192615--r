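Package: quadbind
Title: Quantifying Protein Binding to RNA G-Quadruplexes from NMR, ITC
    and CD Titrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis workflow for characterizing protein binding to
    nucleic-acid G-quadruplexes, built around the hnRNPA1 RGG-box / UP1
    interaction with telomeric repeat-containing RNA (TERRA). Computes
    combined amide chemical shift perturbations (CSPs) from HSQC titration
    peak lists and fits per-residue and global dissociation constants with
    the 1:1 ligand-depletion isotherm; models and fits one-site isothermal
    titration calorimetry (ITC) isotherms with Origin-style displacement
    bookkeeping; normalizes circular dichroism (CD) spectra, tracks
    G-quadruplex foldedness at 262 nm during protein titrations, and fits
    two-state van't Hoff thermal melts. Seeded synthetic-data generators
    for all three modalities allow every stage to be exercised and
    validated with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
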