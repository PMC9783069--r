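Package: twosexlt
Title: Age-Stage, Two-Sex Life Table Analysis for Insect Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes age-stage, two-sex life tables from individual daily
    life-history records of a synchronized insect cohort: age-stage survival
    (s_xj), age-specific survival (l_x) and fecundity (m_x), net maternity,
    life expectancy (e_xj) and reproductive value (v_xj), and the population
    parameters R0, intrinsic rate of increase r (discrete Euler-Lotka),
    finite rate lambda and mean generation time T. Includes bootstrap
    standard errors and a paired bootstrap test for comparing treatments,
    deterministic age-stage-structured population projection, an
    individual-based cohort simulator for testing and power studies, and
    analysis of two-choice feeding-preference assays (arcsine-square-root
    transform, ANOVA with Tukey HSD and compact letter displays).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
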