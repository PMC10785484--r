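Package: lowpasshap
Title: Low-Pass Sequencing Imputation and Haplotype Consistency Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation and evaluation pipeline for low-pass
    whole-genome sequencing with reference-panel genotype imputation.
    Simulates a phased multi-breed haplotype reference panel, a target cohort
    carrying a recessive causal locus, and per-site read pileups across a
    grid of sequencing depths; converts pileups to genotype likelihoods;
    imputes and phases genotypes with an exact diploid Li-Stephens
    haplotype-copying hidden Markov model; and evaluates the results with
    genotype and haplotype concordance metrics (MAF-binned r2, non-reference
    discordance, switch error), mixed-model single-marker association,
    cross-population extended haplotype homozygosity (XP-EHH) scans, and
    haplotype-consistency diagnostics across sequencing depths (regional
    distinct-haplotype counts, depth-deviation tests, windowed discordance
    metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
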