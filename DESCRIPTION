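Package: sbirtcti
Title: Stage-Based Computer-Tailored SBIRT Engine for Risky Drug Use
Version: 0.1.0
Authors@R: person("Pro", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A rule-based engine for Screening, Brief Intervention, and
    Referral to Treatment (SBIRT) in primary care. Administers and scores
    the WHO ASSIST screening instrument across nine substance classes with
    skip-pattern logic, maps scores to validated risk categories, selects
    the most problematic drug with expert-ranking tie-breakers, stages
    patients on the transtheoretical model (TTM) of behavior change, and
    assembles a stage-matched computer-tailored intervention session with
    goal setting and a treatment-readiness branch for high-risk patients.
    Generates a 30-day schedule of stage-matched text messages with weekly
    activity links and appointment reminders, renders provider dashboards,
    printable summaries, and patient reports, validates tagged content
    libraries against a Flesch-Kincaid readability threshold, scores
    5-point Likert acceptability surveys against a benchmark, and ships a
    synthetic-cohort generator so every component is testable without real
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
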