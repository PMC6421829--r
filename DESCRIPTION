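Package: benthodiv
Title: Downstream Diversity Statistics for Benthic Archaeal zOTU Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of zero-radius OTU (zOTU) community tables
    from deep-sea sediment amplicon surveys with paired DNA (entire community)
    and RNA (potentially active community) fractions. Implements
    rarefaction-based alpha diversity (richness, Shannon, Faith's phylogenetic
    diversity) with repeated-rarefaction averaging, Michaelis-Menten coverage
    estimation from rarefaction and species-accumulation curves, four community
    dissimilarities (weighted and unweighted Bray-Curtis and UniFrac),
    single-covariate PERMANOVA with a repeated-rarefaction,
    epsilon-corrected pooled pseudo-F permutation test, Spearman
    environmental-correlation screens, and a synthetic ocean-transect
    generator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    picante,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phyloseq,
    optparse
Config/testthat/edition: 3
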