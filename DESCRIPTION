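Package: pancprs
Title: Candidate-SNP Association and Polygenic Risk Scores for
    Pancreatic Cancer Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a candidate-SNP case-control analysis pipeline for
    pancreatic adenocarcinoma risk: genotype quality control (per-sample call
    rate, duplicate concordance, exact Hardy-Weinberg test in controls,
    monomorphic-locus detection), per-SNP logistic association under allelic,
    codominant and dominant inheritance models adjusted for age and sex with a
    Cochran-Armitage trend test, ancestry-stratified allele-frequency
    comparisons against reference populations, and unweighted, weighted and
    missingness-scaled polygenic risk scores with control-based quintile odds
    ratios. Ships a synthetic-cohort generator drawing control genotypes from
    Hardy-Weinberg proportions and case genotypes from the tilted distribution
    implied by an additive logistic disease model, so every stage runs and is
    verified without access to individual-level study data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
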