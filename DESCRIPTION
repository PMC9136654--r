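Package: ehrwow
Title: Work-Outside-Work Analysis of Electronic Health Record Access Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how much time clinicians spend in the
    electronic health record (EHR) during versus outside their actual
    scheduled clinic hours, from raw time-stamped access-log events.
    Per-action access time is estimated from inter-event gaps with an idle
    cutoff, clinic-hour windows are built from scheduled patient visits with
    a preparation/closing margin, every action's duration is decomposed into
    during/outside segments, actions are categorized by a clinical and a
    conceptual taxonomy, and cohort surfaces (per-physician-per-workday
    hours, category tables, top actions, high-user subgroups) are produced
    together with crossed random-effects models partitioning variance into
    fixed, provider, and day components. A seedable synthetic-cohort
    simulator generates roster, visit schedules, action vocabularies, and
    event streams with known ground truth for end-to-end validation.
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
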