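# sbirtcti

A rule-based engine for **SBIRT** (Screening, Brief Intervention, and
Referral to Treatment) targeting risky drug use in primary care. It is aimed
at digital-health developers and behavioral researchers who need the
decision-rule skeleton of a stage-based computer-tailored intervention (CTI)
as tested, reusable code: screening and risk scoring, readiness staging,
stage-matched tailoring, a month of scheduled text messages, provider
dashboards, and the acceptability statistics used to evaluate such pilots.

## What it computes

**Screening.** The WHO ASSIST instrument: up to 7 items for each of 9
substance classes with skip patterns (never used → branch ends; not used in
the past 3 months → items 3–5 skipped). The substance involvement score is

```
S = Σ over items 2..7 of w(item, response)        S ∈ 0..39
```

with the weight table shipped as editable configuration. Risk bands are the
validated cutoffs **low 0–3, moderate 4–26, high 27+** (display adds *none*
for substances never used).

**Tailoring.** The target behavior is the highest-scoring eligible drug,
ties broken by an expert harm ranking (opioids top, cannabis bottom);
patients below moderate risk are screened out. Readiness uses the
transtheoretical model's five stages from intention windows (30 days / 6
months) and time since change (183-day boundary). Each stage gets exactly 3
change-process modules and a goal menu; a target score **≥ 27** activates
the treatment-readiness branch.

**Scheduling.** 30 days of stage-matched SMS at a 1–3-day cadence set by
stage, exactly 4 weekly activity links (days 1–28), optional appointment
reminders 3 and 1 days ahead, seeded template rotation.

**Acceptability.** 5-point Likert instruments: per-item mean and sample SD,
overall = mean of item means (sample SD of item means), half-up one-decimal
display, verdict against the 4.0 benchmark.

All patient-facing content must sit at or below **Flesch-Kincaid grade 5**:
`0.39·(words/sentences) + 11.8·(syllables/words) − 15.59` under a documented
syllable heuristic.

## Worked example

The bundled synthetic cohort reproduces the four pilot patients (target-drug
scores 21 and 30 on opioids, 27 and 29 on cocaine):

```r
library(sbirtcti)

fx <- pilot_fixture()
p  <- fx[[3]]                       # cocaine 27, action stage
session <- build_session(p$interview, p$quit_answers, p$treatment_answers)
session
#> <tailored_session>
#>   track: high
#>   target drug: cocaine (score 27, high risk)
#>   stage (quit): action
#>   stage (seek treatment): contemplation
```

The score 27 sits exactly at the high-risk cutoff, so the session carries the
treatment-readiness branch on top of the quit intervention. The risk chart
covers every substance class (this patient is a polysubstance user —
cannabis scores 13, moderate):

```r
head(risk_chart(p$interview), 4)
#>   substance score category
#> 1   tobacco     0     none
#> 2   alcohol     0     none
#> 3  cannabis    13 moderate
#> 4   cocaine    27     high
```

Action-stage patients get daily messages; 4 of the 30 carry activity links:

```r
sched <- build_schedule(session, start_date = as.Date("2017-06-05"), seed = 42)
sched
#> <message_schedule> 30 messages from 2017-06-05 | 4 PAC links | 0 reminders
```

The acceptability pipeline reproduces a pilot-style survey table: feeding the
six provider-survey item means in gives the overall rating

```r
overall_acceptability(c(4.3, 4.7, 4.3, 3.7, 5.0, 4.3))
#> <acceptability_summary> overall 4.4 (SD 0.4) across 6 items: meets benchmark 4.0
```

i.e. a mean across items of 4.4 (SD 0.4), which meets the ≥ 4.0 acceptability
benchmark.

## Layout

* `R/` — screening (`assist.R`), tailoring (`tailoring.R`), content library
  and readability (`content.R`), scheduler (`scheduler.R`), dashboard,
  documents and overrides (`dashboard.R`), Likert statistics
  (`acceptability.R`), synthetic cohort (`cohort.R`), CLI (`cli.R`).
* `inst/extdata/` — editable JSON configuration: ASSIST weights and skip
  table, tailoring rules, tagged content library, referral resources.
* `vignettes/sbirt-cti-methods.Rmd` — the model, its assumptions, defaults,
  and limitations.
* `tests/testthat/` — unit, property, and acceptance suites.
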