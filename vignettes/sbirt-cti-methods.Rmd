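---
title: "Methods: stage-based SBIRT tailoring in sbirtcti"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-based SBIRT tailoring in sbirtcti}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbirtcti)
```

## The problem

Screening, Brief Intervention, and Referral to Treatment (SBIRT) asks a
primary-care clinic to (1) screen every patient for substance-use risk with a
validated instrument, (2) deliver a brief intervention matched to the
patient's risk and readiness, and (3) refer high-risk patients to specialty
treatment. The two chronic barriers are provider time and patient motivation:
most at-risk patients are not ready to change, so advice pitched at "action"
misses them. `sbirtcti` implements a rule-based engine that carries the
mechanical load of this protocol: scoring the screen, picking the behavior to
target, classifying readiness, assembling stage-matched content for the
patient and a stage-matched script for the provider, and scheduling a month
of follow-up text messages.

## Screening model

The screening instrument is the WHO ASSIST: up to 7 items per substance class
across 9 classes (plus an "other" slot), with two skip rules — a substance
never used ends its branch at item 1, and no use in the past 3 months skips
the past-3-month items (3–5) but still asks the lifetime concern and
failed-cut-down items (6, 7). Tobacco omits item 5. The substance involvement
score is the weighted sum over items 2–7; item 1 never contributes.

The item weights and the skip table are **configuration, not code**
(`inst/extdata/assist_config.json`): the source publication delegates them to
the instrument manual, so the package ships the manual's V3.0 conventions
(score range 0–39) as a versioned, editable document. Risk bands are the
validated uniform cutoffs: low 0–3, moderate 4–26, high 27+. The four-level
*display* category adds "none" for substances with no lifetime use; "low"
means a 0–3 score with some use history. The manual's substance-specific
alcohol cutoffs are deliberately not implemented: the engine applies the one
printed uniform set, and a site wanting the variant can edit the config.

A consequence of the V3.0 weight table worth knowing: a score of exactly 1 is
not constructible (the smallest nonzero weight is 2), so the synthetic-cohort
generator treats 1 — like 40 — as an unachievable target and raises an error.

## Target-drug selection and tracks

The intervention targets the *most problematic* drug — the highest-scoring
eligible substance — rather than the one the patient volunteers, because
flexible/self-selected targeting performed worse in the SBIRT outcome
literature the design drew on. Ties break by an expert harm ranking with
opioids at the top and cannabis at the bottom; the full order between those
endpoints is a package default (opioids > amphetamine-type stimulants >
cocaine > sedatives > inhalants > hallucinogens > other > tobacco > alcohol >
cannabis) and is configurable, since only the endpoints were fixed by the
source material. Tobacco and alcohol are excluded from targeting by default —
the program addresses risky *drug* use — but the eligible set is also
configuration.

Patients whose best eligible score stays below 4 are screened out: their
session carries only the risk chart. Moderate (4–26) and high (27+) scores
map to the moderate and high intervention tracks. A target score ≥ 27
additionally activates the treatment-readiness branch.

## Staging model

Readiness follows the transtheoretical model's five stages, derived from two
questions: has the change been made (and when), else how soon is it intended?

* change made, less than 6 months ago → **action**
* change made, 6 months or more ago → **maintenance**
* intends within 30 days → **preparation**
* intends within 6 months → **contemplation**
* no intention in 6 months → **precontemplation**

"6 months" is a date-arithmetic convention the source leaves open; the
package fixes it at 183 days with "less than" strict, so day 182 is action
and day 183 is maintenance. Staging is total and exclusive by construction:
every valid answer combination maps to exactly one stage, and the boundary
days are pinned by tests.

Each (stage, purpose) pair maps to exactly 3 change-process modules and a
goal menu, both configuration
(`inst/extdata/tailoring_config.json`) following canonical
transtheoretical-model assignments (e.g. precontemplation leads with the
pros-of-change module alongside consciousness raising and dramatic relief).
The engine guarantees the count and determinism; the clinical wording of the
modules is out of scope.

## Content library and readability

All patient- and provider-facing text lives in a tagged template library
(`inst/extdata/content_library.json`): channel (CTI feedback, SMS, activity,
provider script), drug, risk, stage, purpose, and `{placeholders}` resolved
from session fields. `validate_library()` is report-only: it enumerates
coverage of every cell the library's requirements declare and grades each
patient-facing template with `fk_grade()`.

The readability constraint is a Flesch-Kincaid grade ceiling of 5.0. The
grade formula is exact —
`0.39·(words/sentences) + 11.8·(syllables/words) − 15.59` — but syllable
counting is necessarily heuristic: the package counts maximal vowel groups
(including y), subtracts a trailing silent "e" (except consonant+"le"), and
carries a small exception list. The heuristic is documented, tested
(including its invariance under whitespace changes and self-concatenation),
and applied after placeholders are replaced with representative words so
`{drug}` is scored as text. A different tokenizer would produce slightly
different grades; the ceiling is asserted under *this* heuristic. The bundled
content is placeholder prose written at or below grade 5 that mimics the tone
of stage-matched coaching; it claims no clinical fidelity.

## Message scheduling

A schedule spans 30 days. Cadence depends on the quit stage via a configured
gap map — precontemplation 3 days, contemplation 2, preparation 1, action 1,
maintenance 2 — chosen inside the stated 1–3-day range so that less-ready
patients get lower message pressure and patients near or in change get daily
support; the exact pilot cadence was never printed. One message per 7-day
window of days 1–28 carries a link to one of the 4 Personal Activity Center
activities (days 29–30 never do), reproducing the printed count of 4 weekly
activities. The PAC slot goes to the first scheduled message of each window.

Template choice among equally tagged candidates is the only randomness: a
seeded shuffle fixes a rotation, and no template id repeats until every
matching template has been used once. Appointment reminders insert extra
messages on configured lead days (defaults 3 and 1 days before); insertion
can tighten gaps but never removes or moves a scheduled message, and an
appointment on day 1 is an error because no lead day remains. Re-adding the
same appointment is a no-op.

## Acceptability statistics

Surveys are 5-point Likert items (1 = strongly disagree … 5 = strongly
agree). Per item: n, mean, and **sample** SD (n−1). The overall rating is the
unweighted mean of the *item means*, with the sample SD of those means — this
convention reproduces all three of the study's printed aggregates (4.4 SD
0.4; 4.5 SD 0.3; 4.0 SD 0.4) from the printed item means. Pooling raw
responses instead would match the same one-decimal values, so the choice is
documented rather than empirically forced. Display rounding is half-up to
one decimal (base R's `round()` is half-to-even and would turn 4.45 into
4.4); full precision is kept internally, and the ≥ 4.0 benchmark verdict is
taken on the reported (rounded) value, matching how the study states its
criterion. A single-response item has undefined sample SD; it is reported as
0 with an explicit flag. Tie-breaks for lowest/highest items follow declared
item order.

## Synthetic cohort

`simulate_patient()` builds an interview whose scores hit the profile's
targets *exactly*, by deterministic lexicographic search over the configured
weight table (depth-first over items in order, codes ascending, trying the
skip-reduced branch first). Search, not sampling, was chosen so fixtures are
reproducible byte-for-byte without seed bookkeeping; the `seed` argument is
retained for interface stability. `pilot_fixture()` encodes the four pilot
patients: target scores 21 and 30 on opioids, 27 and 29 on cocaine; quit
stages contemplation, contemplation, action, maintenance (assigned as
21/29 → contemplation, 27 → action, 30 → maintenance, the only assignment
consistent with both the printed stage counts and the worked example of a
cocaine-29 contemplator); three of four flagged polysubstance. Non-target
scores, names, dates of birth, and treatment-readiness stages
(contemplation) were never printed and are synthetic, kept below the target
score so the target assignment is stable.

`simulate_likert()` hits target item means within 1/(2n) by rounding the
rating total and splitting it as evenly as possible; only the assignment of
ratings to respondents is seeded. Note the pilot's printed one-decimal means
are not all exactly attainable at n = 3 or 4 (4.3 at n = 3 has no integer
solution), which is why the acceptance pipeline feeds the *printed item
means* into `overall_acceptability()` and reports the simulated aggregate
alongside.

What a green test does **not** establish: the generator reproduces the
pilot's scores, stages, and survey aggregates, not real interview behavior —
no item-level response realism beyond skip-consistency, no longitudinal
change over the 30 days, no dropout.

## Degenerate inputs and numerical choices

* Out-of-range scores, unknown response codes, duplicate (substance, item)
  pairs, and skip violations fail fast with addressed messages.
* A substance "never used" cannot carry a nonzero score; its display
  category is "none".
* Dashboard lookup normalizes case and whitespace but is otherwise exact;
  two records sharing (name, DOB) raise an ambiguous-match error rather than
  guessing.
* Provider overrides recompute everything downstream and append the prior
  decision to an audit trail; a target-drug override must name a substance
  with lifetime use and fresh staging answers for the new behavior.
* All randomness (template rotation, Likert assignment) is seeded and
  restores the caller's RNG state.

## Known limitations

The engine is a faithful skeleton of the prototype's decision rules, not a
clinical product: bundled content is placeholder text; follow-up sessions
2–3, SMS transport, EHR integration, Spanish content, and injection-risk
follow-up items are out of scope; and the behavioral findings of the pilot
(session durations, retention) are not reproducible by computation and are
not claimed.
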