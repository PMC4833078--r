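Package: immunotrace
Title: Annotation of Innate-Immunity Gene Repertoires in Arthropod Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native pipeline for annotating innate-immunity gene
    families (peptidoglycan recognition proteins, beta-glucan recognition
    proteins, thioester-containing proteins, Toll-like receptors, Relish-type
    NF-kB factors, Nimrod-superfamily receptors) in predicted arthropod
    proteomes. Combines affine-gap local alignment, reciprocal-best-hit
    orthology, orthogroup clustering, position-specific scoring matrix domain
    scans and degenerate motif scans with residue-anchored functional
    classification (amidase zinc-binding triad, glucanase active-site
    glutamate pair, GCGEQ thioester motif, single versus multiple
    cysteine-cluster receptor architecture) and heuristic structural feature
    prediction (transmembrane helices, signal peptides, leucine-rich
    repeats). Produces per-species copy-number matrices and midpoint-rooted,
    bootstrapped neighbor-joining gene trees. Includes a synthetic-proteome
    generator with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    ape,
    phangorn,
    igraph,
    yaml,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
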