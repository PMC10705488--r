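Package: lohdrive
Title: Loss-of-Heterozygosity and Mutation-Rate Analysis for Gene-Drive
    Mutation-Accumulation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hybrid-diploid mutation-accumulation (MA)
    experiments designed to detect mutagenic side effects of CRISPR-Cas9
    gene-drive elements. Simulates MA cohorts with known ground truth on
    dense heterozygous marker maps; calls loss-of-heterozygosity (LOH)
    tracts and events from marker genotypes with midpoint boundary
    estimation, 10-kb tract merging, terminal/interstitial classification,
    double-strand-break breakpoint localisation, and an
    inverse-detection-probability correction for undetected events;
    identifies de novo single-nucleotide mutations and indels with
    founder-genotype imputation and complex-event merging; estimates event
    and conversion rates at genome, chromosome-arm and 50-kb window scales
    with bootstrap confidence intervals, permutation and Wasserstein
    resampling tests; computes theoretical (Poisson) and observed
    (pooled-resampling) statistical power of an MA design; provides
    closed-form expectations for mutations arising inside integrated
    constructs; and scans genomes for PAM-adjacent sites scored for gRNA
    similarity with the MIT/Hsu scheme.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
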