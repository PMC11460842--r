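Package: rapidscore
Title: Rubric-Based Rapid Scoring and Prioritization of Investigational Therapeutics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A configurable implementation of a rapid scoring workflow for
    triaging large portfolios of investigational therapeutics. Provides
    rubric definition, loading and validation (criteria with mutually
    exclusive integer-scored characteristics on a universal -10..+10 scale,
    plus -100 exclusion sentinels), additive overall-benefit scoring,
    deterministic portfolio ranking with interval statements and
    rank-stability sensitivity analysis, dual independent rater entry with
    discrepancy detection, adjudication and stability-streak tracking,
    six-month review scheduling, Likert panel consensus validation
    (2-of-3 rule with a 75 percent statement threshold), percent-agreement
    and Cohen's kappa reliability statistics, and seeded synthetic fixtures
    so the whole workflow is testable without external data.
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
    lubridate,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
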