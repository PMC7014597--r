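Package: palmviper
Title: Comparative Venom-Gland Transcriptomics for Palm-Pitvipers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative venom-gland transcriptomic analysis of
    closely related pitviper species: compositional (centered log-ratio)
    expression-divergence outlier detection against a nontoxin null,
    coverage-based transcript presence/absence and chimera screening,
    cross-sample k-mer bleed-through filtering, identity-based transcript
    clustering, orthogroup duplication/loss classification, a simplified
    negative-binomial Wald differential-expression stage, weighted
    coexpression submodule detection, and pairwise Nei-Gojobori dN/dS
    selection screens. Includes synthetic-data generators with planted
    ground truth for every stage and curated Bothriechis toxin tables as
    worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    ape,
    Biostrings,
    car,
    cluster,
    withr,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
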