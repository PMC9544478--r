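Package: onsenfate
Title: Fate, Phenotyping and Population Genetics of Heat-Induced ONSEN
    Retrotransposon Insertions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for studying how heat-mobilised copies of the
    Arabidopsis thaliana ONSEN (AtCOPIA78) retrotransposon can produce
    drought-tolerant lines. Provides a forward-in-time Wright-Fisher simulator
    (partial selfing, hard selection, episodic drought events) for the
    short-term fate of a recessive transposon insertion, together with an
    exact Markov-chain oracle; quantification of vital and necrotic leaf area
    from segmentation label images with in-image scale calibration and a
    drought-tolerance classifier; pot-weight water-loss modelling against
    plant size; parsing and candidate filtering of transposon insertion
    polymorphism (TIP) catalogues with PCR band-pattern zygosity calls and
    Mendelian F2 expectations; delta-delta-Ct qPCR copy-number estimation;
    and a natural-accession association stage (minor-allele-frequency filter,
    KING-robust kinship pruning, one-random-effect linear mixed model with
    variance explained, linkage disequilibrium). A synthetic-data module
    generates every input with known ground truth so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    car,
    vcfR,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    tiff,
    withr
Config/testthat/edition: 3
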