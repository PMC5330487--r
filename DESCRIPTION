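Package: admixscan
Title: Admixture Mapping and Credible-Set Fine Mapping for Admixed Cohorts
Version: 0.1.0
Authors@R: person("admixscan", "developers", email = "admixscan@example.org",
    role = c("aut", "cre"))
Description: Tools for admixture mapping of quantitative traits in recently
    admixed populations: per-marker linear regression of inverse-normal
    transformed traits on local-ancestry dosage with Max(T) label-swapping
    permutation control of the family-wise error rate, conditional scans,
    additive genotype association with inverse-variance fixed-effects
    meta-analysis, Wakefield approximate-Bayes-factor 99 percent credible
    sets, and extrapolation of parental-population allele frequencies from
    admixed cohorts. Includes a seeded generator of three-way admixed
    synthetic cohorts (local ancestry, ancestry-conditional genotypes and
    lipid-like phenotypes) so the whole pipeline can be exercised and
    calibrated without individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
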