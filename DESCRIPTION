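Package: cnascan
Title: Copy-Number Aberration Analysis for Amplifier-Type Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cohort-scale analysis of array-based DNA copy-number profiles
    with a focus on amplifier-type tumor genomes such as HER2-positive breast
    cancer. Provides circular binary segmentation with a permutation split
    test, sample-adaptive CNA state calling, GISTIC-style recurrence scoring
    with a cyclic-shift permutation null, shortest-region-of-overlap (SRO)
    delineation of amplicon cores, firestorm amplification pattern detection,
    co-amplification and mutual-exclusivity statistics, fraction-of-genome-
    altered summaries, and permutation-calibrated copy-number and expression
    dosage analysis. Includes a synthetic cohort generator that plants
    ledgered aberration events so every pipeline stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
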