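Package: perioMR
Title: Two-Sample Mendelian Randomization of Periodontal Disease
    Liability on Cardiovascular Outcomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@periomr.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) with GWAS
    summary statistics, built around the study design that screens genetic
    liability for periodontal disease (dental caries and periodontitis)
    against eight cardiovascular outcomes.  Provides validated readers and
    writers for summary-statistic tables, instrument selection at
    genome-wide significance with outcome-side exclusion, effect-allele
    harmonization including palindromic-variant policies, the
    inverse-variance-weighted, MR-Egger and weighted-median causal
    estimators with heterogeneity and pleiotropy diagnostics, a study-grid
    pipeline with Bonferroni correction and forest-table output, and a
    synthetic two-sample GWAS generator with known causal truth for
    calibration and robustness experiments.  The 47 periodontal instrument
    variants ship as a bundled fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, graphics, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'methods.R'
    'instruments.R'
    'harmonize.R'
    'estimators.R'
    'summary-io.R'
    'fixture.R'
    'perioMR-package.R'
    'simulate.R'
    'pipeline.R'
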