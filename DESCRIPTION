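Package: mutscreen
Title: In Silico Screening of Enzyme Mutants by Reaction Barrier Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for high-throughput in silico screening of
    combinatorial enzyme mutants by estimated reaction barriers. Enumerates
    multi-mutants from a per-position substitution library under steric
    exclusion constraints, generates constrained reaction-coordinate
    interpolation schedules for an external semi-empirical energy backend,
    extracts and quality-filters barrier heights from energy profiles,
    classifies mutants as activity-improving or activity-degrading by a
    barrier cutoff, and benchmarks predictions against experimental
    fold-wild-type activities. Ships transcribed benchmark tables for the
    amidase activity engineering study of Candida antarctica lipase B (CalB)
    and a seeded synthetic-profile generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
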