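Package: ffbench
Title: Multi-Measure Force-Field Benchmarking for Disordered Peptide Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores conformational ensembles of the R2-FUS-LC amyloid trimer
    (three 16-residue peptides) against experimental reference structures using
    three complementary measures: a radius-of-gyration score based on a
    two-component Gaussian mixture fit of the trimer Rg distribution compared
    with U-shaped, L-shaped and Flory random-coil references; an intra-peptide
    contact-map score based on the Matthews correlation coefficient of
    snapshot contact maps against a reference cross-beta contact map; and a
    secondary-structure-propensity log-likelihood score against reference
    helix/strand/coil assignments. Raw scores are min-max normalized across
    force fields and combined multiplicatively into a final ranking. A
    synthetic trimer-ensemble generator with controlled compactness, secondary
    structure and contact statistics makes every stage testable without
    molecular-dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
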