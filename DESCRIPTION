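Package: ggxe
Title: Genetical Genomics Across Environments: eQTL Mapping, Plasticity and
    Hotspot Analysis in Recombinant Inbred Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genotype-by-environment genetical-genomics analyses on
    recombinant inbred line (RIL) populations. Simulates RIL genotypes and
    two-environment expression data with a known effect architecture; maps
    expression QTL by marker regression with optional forward-selected
    cofactors; calibrates genome-wide significance by Churchill-Doerge
    permutation and by Storey q-values with a simulation-based correction for
    marker correlation; calls and classifies local/distant eQTL peaks; detects
    hotspots of transcript regulation; compares experiments through signed
    -log10(P) profile correlations to identify plastic and opposite-effect
    regulation; and provides broad-sense heritability, transgression,
    hypergeometric enrichment and interval-membership statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
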