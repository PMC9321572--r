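Package: barcodediv
Title: Diversification Inference from Short-Marker Molecular Units
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying macroevolutionary diversification in clades
    known mainly through a short, slowly evolving barcode marker (such as the
    ~520-bp variable region of the SSU rRNA gene in arbuscular mycorrhizal
    fungi). Delineates species-like evolutionary units on a haplotype
    phylogeny by combining a monophyly criterion with an average
    pairwise-similarity threshold; assesses sampling completeness with
    rarefaction curves and the Chao2 incidence estimator; fits constant,
    time-exponential and environment-dependent birth-death diversification
    models to ultrametric trees with incomplete sampling, compared by AICc;
    computes per-unit nucleotide diversity (Tajima's theta-pi), niche-width
    principal components and rate-trait regressions; and provides a
    simulation workbench (species trees, grafted within-species coalescents,
    slow-marker sequence evolution) that quantifies how species lumping by a
    slow marker biases unit counts and inferred speciation-rate declines.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    deSolve,
    nlme,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
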