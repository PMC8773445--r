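Package: founderhap
Title: Founder-Haplotype Sharing Detection and Coalescent Dating of Rare-Variant Carriers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether reportedly unrelated carriers of a rare
    mutation inherited it from a common ancestor. Implements array-style
    quality control (missingness, exact Hardy-Weinberg test with Bonferroni
    correction, minor allele frequency, sliding-window LD pruning), genotype
    PCA and method-of-moments genome-wide identity-by-descent with an
    empirical top-percentile relatedness screen, detection of the maximal
    haplotype segment shared by carriers around a focal mutation with
    genome-wide empirical rank statistics and patient-control nulls, analytic
    coalescent dating (tMRCA) of the shared segment from its genetic length,
    and a synthetic phased-cohort simulator with a planted founder event for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
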