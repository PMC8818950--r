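Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Maintainer", "Packages", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization workflow operating
    on GWAS summary statistics: reading and validating delimited association
    tables, genome-wide significance filtering, greedy LD clumping with proxy
    lookup, allele harmonization with frequency-based strand inference for
    palindromic variants, five causal-effect estimators (inverse-variance
    weighted, MR-Egger, weighted median, simple and weighted mode),
    heterogeneity and pleiotropy diagnostics (Cochran's Q, Egger intercept,
    leave-one-out, funnel coordinates, instrument F-statistics), the E-value
    for unmeasured confounding, and a seeded synthetic summary-statistic
    generator with a known causal model for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
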