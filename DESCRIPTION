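Package: plscore
Title: End-Point Protein-Ligand Scoring with Truncated Active-Site Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for end-point protein-ligand binding affinity scoring on
    truncated, capped active-site models. Reads PDB and Tripos Mol2 structures,
    builds capped pocket models around overlaid ligand series with explicit
    charge bookkeeping, and assembles a five-term binding score (gas-phase
    interaction energy, desolvation penalty, ligand strain, a
    Henderson-Hasselbalch-weighted proton-transfer correction, and a
    rotatable-bond entropy penalty) on top of a pluggable energy-backend
    contract. Ships a self-contained classical test backend, a Becke-Johnson
    damped pairwise dispersion term, a text interface for external
    semiempirical engines, benchmark evaluation by per-target squared Pearson
    correlation, and a deterministic synthetic-fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vctrs,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
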