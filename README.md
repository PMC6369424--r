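# airplan

Asthma action-plan zone-of-control engine, reminder scheduler, and mHealth
utilization analytics — with a seeded synthetic-cohort simulator so the whole
pipeline can be developed and tested without patient data.

## The problem

Collaborative self-management (CSM) platforms for asthma give each patient a
provider-authored *action plan*: per-zone instructions keyed to a
traffic-light classification of current control. The platform's job is to
turn the patient's self-reports (daily symptoms, reliever use, optional peak
flow) into that zone — **green** (in control), **yellow** (uncontrolled),
**red** (dangerously uncontrolled) — to deliver the matching plan step, to
nudge adherence with rule-based reminder emails, and to log every
interaction so engagement and attrition can be measured. `airplan`
implements that computational core for analysts and platform engineers: the
decision algorithm, the reminder planner, Air Quality Health Index (AQHI)
risk banding, an append-only typed event log, and the cohort analytics that
summarize how such a platform is actually used.

## The decision algorithm

For an assessment at time *t*, journal entries in the trailing window
(*t* − 7 d, *t*] are aggregated into weekly control criteria and combined
with the latest in-window peak expiratory flow (PEF):

* **Symptom component** — red if any danger-level symptoms were reported;
  green if daytime symptom days < 4, night wakings < 1, reliever doses ≤ 3
  and no activity limitation (guideline-style weekly criteria, all
  configurable); yellow otherwise.
* **PEF component** — with personal best *PB* and default fractions,
  green if PEF ≥ 0.90·*PB*, red if PEF < 0.60·*PB*, yellow between
  (lower bounds inclusive; provider-entered absolute thresholds pass
  through unchanged).
* **Combination** — worst-of (red > yellow > green), the
  safety-conservative rule of traffic-light plans. With *no* in-window
  entries and no in-window PEF the result is **insufficient**, never a
  default zone. Executing the action plan *resets* the assessment: entries
  at or before the reset instant are consumed and no longer contribute.

Reminder rules: a welcome email at enrollment; one adherence email per day
at the patient's reminder time (default 19:00 local) while a controller
medication is prescribed; a check-in email after each run of 7 calendar
days without a login; bodies rotate uniformly through a ~30-message pool
with no immediate repeats.

## Worked example

```r
library(airplan)

prof <- patient_profile("P001", "2013-02-01T14:00:00Z", personal_best_pef = 500,
  medications = list(medication("budesonide/formoterol", "controller", "2 puffs BID"),
                     medication("salbutamol", "reliever", "2 puffs PRN")),
  action_plan = action_plan(
    green  = zone_instruction("green",  "Continue current controller dose.", requires_pef = TRUE),
    yellow = zone_instruction("yellow", "Double the controller dose for 7 days.", requires_pef = TRUE),
    red    = zone_instruction("red",    "Take reliever now and seek urgent care.", requires_pef = TRUE)))

entries <- journal_entries("P001",
  timestamp = as.POSIXct("2013-02-08 12:00:00", tz = "UTC") - (0:6) * 86400,
  daytime_symptoms = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
  night_waking     = c(TRUE, rep(FALSE, 6)),
  reliever_doses   = c(2L, 1L, 0L, 0L, 1L, 0L, 0L),
  pef = c(430, rep(NA, 6)))

assess_zone(prof, entries = entries, as_of = "2013-02-08T12:00:00Z")
#> <zone_result> YELLOW (basis: both)
#>   as of: 2013-02-08T12:00:00Z
#>   action plan: Double the controller dose for 7 days.
```

Four symptom days and a night waking fail the green criteria, and
430 L/min sits between 300 (0.60·PB) and 450 (0.90·PB): both components say
yellow, so the patient gets the yellow-zone plan step.

A full synthetic year for a 123-patient cohort, summarized:

```r
sim <- simulate_cohort(sim_params(), seed = 1)
utilization_summary(sim$log, sim$cohort)
#> <utilization_summary> 123 patients, 52 weeks
#>   events per patient per week (pppw):
#>     login                 17511  (2.74 pppw)
#>     journal               11366  (1.78 pppw)
#>     medication_report      1874  (0.29 pppw)
#>     peakflow_report        5143  (0.80 pppw)
#>     zone_calc             12910  (2.02 pppw)
#>     email_sent            42743  (6.68 pppw)
#>     reset                   760  (0.12 pppw)
#>     clinic_visit            246  (0.04 pppw)
#>   zone of control:
#>     green           6558  (50.80%)
#>     yellow          3069  (23.77%)
#>     red               92  (0.71%)
#>     insufficient    3191  (24.72%)
#>   weekly active: 100.0% (week 1) -> 55.3% (week 52)
#>   journaled days: 7619 good, 3747 episode (67.0% good)
```

The rates are events per patient per week (pppw, total events divided by
cohort size × 52); the weekly-active line is the attrition curve's
endpoints; a *good day* is a journaled day with no symptom flags and no
reliever use. `fit_attrition_decay(attrition_curve(sim$log, sim$cohort))`
fits the three-parameter engagement-decay model
p<sub>w</sub> = p<sub>∞</sub> + (p<sub>0</sub> − p<sub>∞</sub>)·e^(−λw)
to the weekly-active series.

A command-line wrapper (`exec/airplan`) exposes the same pipeline as
`simulate`, `assess`, `remind`, `analyze`, `env` and `log` subcommands.

## Cohort event-log schema

CSV (or JSON lines) with columns `patient_id`, `timestamp` (ISO-8601 UTC),
`event_type` (`login`, `journal`, `medication_report`, `peakflow_report`,
`zone_calc`, `email_sent`, `reset`, `clinic_visit`) and a type-specific
JSON `payload`. Cohorts are one JSON array of profile objects, each
embedding its medications, thresholds and action plan (see
`write_cohort()`).

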