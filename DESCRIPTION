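Package: uvma
Title: UV Mutation Accumulation: Spectra, Rates, Fluctuation Tests and a
    Two-Damage-Type Lethality Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing mutation-accumulation experiments under UV
    irradiation in bacteria. Classifies genome-wide base-pair substitutions
    against a coding annotation (synonymous, nonsynonymous, RNA gene,
    intergenic), computes folded six-class mutational spectra with Monte
    Carlo error bars and spectrum comparisons, profiles the local sequence
    context of substitutions against a spectrum-matched Monte Carlo null
    (including dipyrimidine enrichment), estimates genome-wide substitution
    accumulation rates and dN/dS via the synonymous fraction F(syn),
    estimates mutation rates from Luria-Delbrueck fluctuation assays by the
    Ma-Sandri-Sarkar maximum-likelihood method, and fits a two-damage-type
    Poisson model that partitions UV killing into lethal mutations and
    lethal physiological side effects. Includes synthetic-data generators
    (annotated genomes, context-biased mutation sets, fluctuation cultures,
    growth curves) and a simulator of a serial-transfer evolution protocol
    with a UV-transmission ladder.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    Rcpp,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
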