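---
title: "Simulating hospital surge capacity in mass-casualty incidents"
author: "surgesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating hospital surge capacity in mass-casualty incidents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surgesim)
```

## The problem this package models

In a mass-casualty incident (MCI) the immediate need for care exceeds the
resources at hand: the question a hospital must be able to answer is *how
many casualties can we manage without preventable deaths or severe
complications*, and that number — the surge capacity — differs between the
emergency department, the operating theatres, the intensive care unit and
the supporting functions, and changes with the phase of the response.
Physical simulation exercises can measure it, but they are expensive to
repeat.  `surgesim` is an in-silico version of such a capacity test: a
discrete-event simulator in which synthetic casualties with time-critical
treatment needs flow from an incident scene through ambulance shuttles
into a hospital with finite, gradually mobilized resources, and in which
every death attributable to waiting is detected, attributed and counted.

The simulator is organised as a pipeline:

1. **Casualty model** (`casualty()`, `physiology_at()`, `triage()`):
   synthetic casualty "cards" with injuries (AIS-coded), trauma scores
   (ISS, NISS, coded RTS), a physiological trajectory that worsens with
   time and improves with completed treatment, per-treatment mortality and
   complication deadlines, and a flag saying whether optimal treatment
   would have saved the casualty.
2. **Scenario generator** (`scenario_template()`, `generate_scenario()`):
   a casualty mix scaled to any target size with preserved proportions.
3. **Prehospital module** (`ambulance_fleet()`, `simulate_evacuation()`):
   a finite shuttle fleet that produces the characteristic arrival
   *waves* of severely injured casualties, plus a continuous spontaneous
   stream of walking wounded.
4. **Hospital engine** (`run_hospital()`): the discrete-event core.
5. **Outcome module** (`score_outcomes()`, `load_curves()`,
   `determine_capacity()`): preventable-death attribution and the
   numerical capacity search.
6. **Coordination module** (`run_region()`, `inflow_signal()`,
   `distribute()`): the regional "one step ahead" layer.

## The deadline model of preventable mortality

Each treatment requirement carries a service time, a station (ED, CT, OR,
ICU, ward), staff and material consumption, and optionally two deadlines
in minutes post-incident:

* a **mortality deadline**: the treatment must be *completed* (not merely
  started) by this time or the casualty dies;
* a **complication deadline**, earlier than the mortality deadline:
  completion after it (but before the mortality deadline) is recorded as a
  severe complication.

Reading "must be done within a certain time" as *completed by* the
deadline is the conservative choice: it makes waiting time count in full.
A death is classified **preventable** when the casualty's
`survivable_if_optimal` flag is true — i.e. a feasible schedule meeting
every deadline existed, which the generator verifies with a greedy
earliest-deadline-first oracle at generation time — and the deadline
lapsed while the casualty was queued or blocked.  Each preventable death
is attributed to the station whose resource the casualty was waiting for;
in particular, a casualty kept out of an available theatre because no ICU
bed could be reserved for its post-operative care is attributed to the
**ICU**, not the OR, which is what makes "intensive care limits surgery"
visible in the output.

## The engine's semantics

Time is integer minutes from the incident (the exercise clock).  The
engine is event-driven but all state changes happen at integer minutes,
and simultaneous events are resolved in a fixed phase order: resource
mobilization, supply deliveries, service completions, deadline checks
(deaths before complications), arrivals, and finally a greedy dispatch
pass.  Dispatch visits stations in the order ED (major line before the
minor line), CT, OR, ICU, ward, then pending inter-station transfers, and
within each queue orders casualties by triage category, earliest
remaining mortality deadline, arrival time and id.  Because every rule is
deterministic, identical inputs reproduce identical event logs
byte-for-byte; the engine itself draws no random numbers.

Key structural rules:

* REDs are served by **major-incident trauma units** — a unit being a
  prepared room, its equipment and the minimal qualified team — which
  mobilize along a step function of time since alert, with separate
  office-hours and non-office-hours profiles.  YELLOW/GREEN casualties
  run in a separate low-resource line and never seize trauma units.
* Every treatment consumes its full service time, its staff demand
  (checked against the mobilized roster) and its consumables (checked
  against stock; shortage delays the treatment and logs a stock-out).
* A CT scanner outside the ED ties up the casualty's team for two
  transport legs in addition to the scan; this is how liberal CT use
  congests the trauma teams.
* Operating theatres occupied by planned surgery at alert all clear a
  configurable time after the alert (office profile); admission to
  surgery for a casualty needing post-operative intensive care requires a
  free ICU bed, which is reserved at incision (`or_icu_blocking`, on by
  default, off for what-if runs).
* Inter-station transfers seize a transport-staff token; when none is
  free a clinical staff member is seized instead and the event is logged
  as indirect capacity loss.

The test suite holds the engine to an exact standard: on randomized small
scenarios its event log must be *identical* to that of an independent
brute-force simulator that steps the clock one minute at a time and
re-evaluates the whole state with plain loops.

## What the synthetic data emulate — and what they do not

The generator emulates the structure of simulation-exercise casualty
cards: injury panels drawn from a per-category library, ATLS-style vitals
deteriorating at half the untreated-death time and stabilizing once the
first critical treatment completes, and deadlines jittered casualty by
casualty (±15% by default) around panel base values.  The panel values
themselves — durations, deadlines, staffing, consumption — are authored
for this package: the real card data such systems use are not public, and
no claim of clinical calibration is made.  Passing tests therefore show
that the *mechanics* (queueing, deadlines, attribution, capacity search)
are correct under realistic structure, not that any specific hospital's
capacity would equal the numbers computed here.  Real casualty mixes,
correlated injuries, triage errors (an error-rate knob exists but
defaults to perfect triage, since mis-triage was not what limited
capacity in the exercises this emulates), intra-day staffing variation
and blood-group-resolved transfusion logistics are all outside the
generated data.

## The shipped default configuration

The defaults describe a large university hospital and are deliberately
sized so that the simulator reproduces, qualitatively, the phase sequence
reported from physical capacity tests:

* **Fleet**: 12 ambulances, dispatch 5 min, load 5 min, transport 5 min,
  unload 5 min — so the first delivery reaches the ED 15 minutes after
  the incident (the calibration anchor) and deliveries arrive in waves
  with a 20-minute round-trip period.  80% of GREENs self-evacuate as a
  continuous Poisson stream.
* **ED**: up to 16 parallel trauma units, mobilizing over ~40 min
  (office) or ~50 min (non-office; staff off duty reach the hospital
  within half an hour to an hour of the alert).
* **OR**: 20 theatres, 14 occupied by planned surgery at alert and
  cleared 30 min later; the surgical roster (18 surgeons at full
  mobilization) is deliberately generous so the theatre block is never
  the binding constraint.
* **ICU**: 6 beds plus 2 reserve-ventilator places at +60 min — small on
  purpose; intensive care is the terminal bottleneck.
* **Horizon**: 720 min; scenario of 200 casualties (10% RED, 30% YELLOW,
  55% GREEN, 5% dead at scene) intentionally exceeds capacity.

Under these defaults an overload run shows: first preventable deaths at
the ED while the arrival waves outrun team mobilization; the OR never
saturated; and a growing tail of deaths attributed to the ICU, whose
blocking of surgery is what finally caps throughput.  The acceptance
suite asserts exactly this structure.

## Capacity determination

`determine_capacity()` defines the capacity of a component as the largest
scenario size `n` for which the full pipeline produces zero preventable
deaths — and, by default, zero severe complications — attributed to that
component.  The pass predicate is assumed monotone in `n`, found by
bisection, and then audited with a ±2 verification sweep; if the audit
fails (queueing systems are not guaranteed monotone) the search falls
back to an exhaustive linear sweep and warns.  For stochastic templates
the predicate can require zero events across `R` paired replicates
(`replicates = R`); the single physical exercise corresponds to `R = 1`.

## Regional coordination

The predictive-lookahead policy implements "always one step ahead": the
controller watches the (perfectly observed, by default 5 minutes delayed)
ambulance departure log, projects each hospital's trauma-unit occupancy
with an assumed 45-minute major-trauma service time, closes a hospital's
inflow when predicted arrivals within the 20-minute lookahead exceed free
plus soon-freeing units, and reopens it when free units reach the reopen
threshold.  When every hospital is closed the casualty goes to the
hospital with maximal slack — casualties cannot be held at the scene.
Policy comparisons use common random numbers: the same template, size and
seed, so the two policies face byte-identical casualty streams.

## Numerical and design choices

* **Time base**: integer minutes; ties broken by (phase, priority,
  casualty id), making every run reproducible to the byte.
* **Seeds**: one master seed per run, split deterministically into
  per-module sub-seeds (`split_seed()`), so the scenario, the spontaneous
  stream and replicate draws can be regenerated in isolation.
* **Phase windows** for the limiting-factor table default to 0–2 h,
  2–8 h and 8 h–horizon; they are reporting bins only and configurable.
* **Degenerate inputs**: `n_total = 0` gives an empty scenario; an empty
  stream yields a log containing only alert/mobilization events; a
  demand no roster can ever satisfy is rejected before simulation with a
  named configuration error.
* **Problem sizes in the test suite** (200-casualty default runs, a
  3×3×3 capacity grid searched over n ≤ 12, 25 oracle-equivalence
  scenarios of ≤ 10 casualties, 20 paired coordination replicates of 60)
  were chosen so the whole suite exercises every module while remaining
  quick to run routinely.

## Known limitations

* Attribution assigns each death to a single blocking station; composite
  causes (e.g. a transfer delayed by transport staff followed by an ICU
  queue) are attributed to the last blocking resource.
* The ICU reservation is made at surgery start; the alternative reading
  (a bed predicted free by surgery end) would be slightly less
  conservative.
* Ward care and ICU step-down relief streams are modelled only as
  configuration knobs (off by default), and the blood bank is a plain
  consumable counter without blood groups.
* Scene organisation is out of scope: scene triage is instantaneous by
  default and dead-at-scene casualties are never transported, so
  prehospital deaths in an overloaded fleet reflect transport capacity
  only.
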