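Package: rcnvclock
Title: Recurrent Copy-Number Variant Detection and Shared-Haplotype
    Coalescence Dating in Founder Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing recurrent copy-number variants (rCNVs) in
    founder-population cohorts genotyped on SNP arrays. Implements
    dual-caller consensus filtering of CNV calls (reciprocal overlap,
    probe-count and size thresholds), clustering of consensus calls into
    recurrent loci with carrier frequencies and gene annotation, allele age
    estimation from maximum shared flanking haplotypes via the Gamma method
    (with a five-SNP mismatch rescue rule and quantile-based confidence
    intervals), KING-robust kinship estimation, kinship-aware carrier
    association testing, power-based minimum detectable carrier frequency,
    and per-individual CNV burden statistics. A synthetic cohort generator
    simulates a CNV-bearing founder haplotype descending a configurable
    number of generations under recombination against a local genetic map,
    with noisy dual-caller output and binary phenotypes, so the full
    pipeline can be exercised with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ape,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
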