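Package: foldstab
Title: Site-Specific Protein Fold Stability Curves from 2D NMR Peak Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-residue two-state thermodynamic analysis of protein thermal
    and cold denaturation from temperature series of 2D NMR (15N-HSQC) peak
    volumes. Fits the modified Gibbs-Helmholtz stability curve (dHm, Tm, dCp)
    to folded-population data by Levenberg-Marquardt least squares, with
    covariance-based error propagation and derived characteristic
    temperatures (cold-denaturation temperature Tc, temperature of maximum
    stability Ts). Includes a structure-based RAD burial score (exteriority
    times relative amide-nitrogen accessibility) for selecting hydrophobic
    core reporters, classification of residues against a buried-core
    reference curve, and a synthetic-data generator that emulates the NMR
    artefacts (exchange broadening, differential relaxation, solvent
    exchange) that can distort apparent stability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    bio3d,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
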