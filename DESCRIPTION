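Package: ivwmr
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with a small set of
    genetic instruments, built around the Wald ratio estimator and
    inverse-variance-weighted fixed-effects pooling. Includes harmonization
    of GWAS summary statistics across studies, conversion between odds-ratio
    and log-odds reporting, Cochran's Q and I-squared heterogeneity with
    Q-profile confidence intervals, instrument validation (F-statistics,
    Bonferroni-corrected confounder screens, pairwise linkage-disequilibrium
    gating), analytic power and minimal-detectable-effect calculations, and
    a generative simulator of genotype-exposure-outcome cohorts for
    verifying estimator behaviour. Ships the published per-variant summary
    statistics for the effect of 25-hydroxyvitamin D-lowering alleles on
    asthma, childhood asthma, atopic dermatitis, and total serum IgE as a
    worked data set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
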