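Package: phytodemog
Title: Cohort Life-Table Demography for Predatory Mite Diet Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs cohort life tables (age-specific survival lx and
    fecundity mx schedules) from individual-level rearing records of
    phytoseiid mites, computes Birch's demographic parameters (net
    reproductive rate R0, mean generation time T, intrinsic rate of
    increase rm, finite rate of increase lambda) by solving the discrete
    Euler-Lotka equation, attaches jackknife pseudovalue standard errors,
    and performs unadjusted pairwise diet comparisons with compact letter
    displays. Includes an individual-based synthetic-cohort generator
    emulating a laboratory rearing experiment (stage-structured immature
    development observed at half-day resolution, daily adult observation,
    pre-/ovi-/post-oviposition schedule with daily egg counts), so the
    whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
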