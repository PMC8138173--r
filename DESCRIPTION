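Package: prandem
Title: Prandial-State and Adiposity Differential DNA Methylation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Probe-wise differential methylation analysis for small paired
    fasting/postprandial whole-blood methylation-array cohorts. Calls CpGs
    whose methylation (tested on the M-value scale) associates with BMI or
    blood fatty-acid fractions using normality-adaptive Pearson/Spearman
    correlation, and CpGs that differ between fasting and postprandial
    states within a BMI class using paired t or exact Wilcoxon signed-rank
    tests, with a dual significance-plus-effect-size (delta-beta) calling
    rule and optional leukocyte-composition adjustment. Includes probe
    filtering (SNP-affected, sex-chromosome, detection failure, missing
    data, age-associated), CpG-island shore/shelf geography, set-level
    summaries (overlaps, direction proportions, genomic-context and
    beta-quartile distributions, hypergeometric gene-set
    over-representation), and a seeded synthetic-cohort generator with
    planted, fully recorded effects for offline validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
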