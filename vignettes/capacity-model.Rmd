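---
title: "Modelling HD centre capacity for intrathecal therapy delivery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling HD centre capacity for intrathecal therapy delivery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdcapacity)
```

## The problem

The most advanced disease-modifying therapy candidates for Huntington's
disease (HD) are antisense oligonucleotides delivered intrathecally — by
lumbar puncture into the cerebrospinal fluid — on a fixed dosing cadence.
Delivering such a therapy is not only a question of drug supply: every
administration occupies a proceduralist (usually a neurologist), two
assisting nurses, and a suitable chair or bed for fixed spans of time. HD
clinics are small — a typical centre dedicates a neurologist about 1.25 days
a week (0.25 full-time equivalents, FTE) and nursing staff about 0.15 FTE —
so a therapy requiring six to seven procedures per patient per year for a
hundred-odd patients per centre can overwhelm current staffing.

`hdcapacity` implements a linear capacity model for this situation. It
answers, per centre: how many FTEs of each resource class does the
anticipated caseload require; how many are actually available once staff
willingness is accounted for; which resource is the bottleneck; what
fraction of anticipated patients can be covered; and how fast does a waiting
list grow after launch.

## The procedure profile

A `procedure_profile` is a table of steps, each occupying one resource class
for a number of minutes per person, with a count of persons engaged
simultaneously. Time is accounted in *person-minutes*: two nurses working 40
minutes contribute 80. The packaged default follows the GENERATION HD1 trial
protocol:

```{r}
prof <- default_generation_hd1_profile()
vapply(resource_classes(), per_procedure_minutes, numeric(1), profile = prof)
```

60 proceduralist person-minutes, 155 nurse person-minutes and 70 minutes of
chair/bed occupancy per procedure. Profiles are data, not code: alternative
protocols load from YAML with `load_procedure_profile()`.

Two conventions convert these minutes into annual FTEs, and both are
explicit, tunable parameters:

* **Dosing cadence** — `admins_per_patient_per_year = 6.5`, i.e. one
  administration every 8 weeks (52/8). The interview study counts patients
  per year but resources per procedure; 6.5 procedures/patient/year is the
  cadence under which its reported FTE requirements are recovered exactly.
* **FTE convention** — `fte_convention()` defaults to a 2080-hour working
  year (52 weeks × 5 days × 8 hours). Availability reported in clinic days
  per week converts via `days_per_week_to_fte()` (1.25 days/week → 0.25 FTE).

Under these defaults a caseload of 114 patients/centre/year — the sample
mean of the interview data the model was designed around — implies 741
procedures and

```{r}
round(vapply(resource_classes(), needed_fte, numeric(1),
             patients_per_year = 114, profile = prof), 2)
```

i.e. 0.36 proceduralist FTE and 0.92 nurse FTE, matching the study-reported
figures to their printed precision (raw values 0.35625 and 0.92031). We read
those figures as *total* needed FTEs rather than increments over current
resources, because the arithmetic reconciliation above supports that reading
exactly; the alternative is noted as an open interpretation.

## Available resources and willingness

A centre's available FTE per class is its interview-reported allocation,
multiplied by the fraction of that staff class willing to perform or assist
the procedure (`apply_willingness = TRUE` by default). Interviews put
proceduralist willingness at 60–70% (we use the midpoint 0.65 as a default)
and nurse willingness at 80%. The source describes willingness as "taken
into consideration" without a formula; a multiplicative haircut is the
simplest faithful reading and is easy to switch off for sensitivity
analysis.

## Coverage, bottlenecks and component classification

Per-class throughput is `available_fte × hours_per_year × 60 /
per_procedure_minutes`; a centre's capacity is the minimum across classes,
and the class attaining it is the bottleneck (ties broken in the fixed
order proceduralist, nurse, facility, for determinism). The coverage
fraction is `min(1, capacity / demand)`, defined as 1 when demand is zero.
Coverage within `1e-9` of 1 is snapped to 1 so that availabilities
back-solved from a full-coverage target are not misclassified by
floating-point rounding.

Separately from the FTE arithmetic, each centre carries interview-reported
flags for whether it *has* each component (a dedicated proceduralist,
nursing component, facility) in place for the procedure. `aggregate_gap()`
classifies centres as `all_three`, `lacks_one_of_nurse_or_facility`,
`lacks_both`, or `other` from these flags.

**Why flags are not derived from availability.** In the interview sample the
model emulates, the two measurements are inconsistent if read as one: 75% of
centres lack at least one component, yet only 45% of centres fall below 30%
coverage — impossible if "lacking" meant zero usable time, since a missing
required component implies zero capacity. The component question captures
whether a *dedicated, procedure-ready* component exists; the capacity
estimate also counts resources not currently dedicated to HD. The package
therefore keeps `has_component` as an independent survey field. When an
input file omits the flags they default to `availability > 0`.

## The waiting-list model

After launch, demand arrives at `demand_rate` procedures/year while the
centre can deliver `capacity_rate`. With zero initial backlog and constant
rates, the backlog after `t` months is `max(0, demand − capacity) × t/12`,
and we define waiting time as backlog over monthly throughput (a
Little's-law-style definition):

`waiting_time(t) = max(0, demand/capacity − 1) × t`.

A centre able to serve 2/7 of its demand — representative of a sample in
which most centres cover less than 30–50% of anticipated patients — waits
`(7/2 − 1) × 24 = 60` months by month 24: a five-year waiting list two years
after launch. Zero initial backlog is an assumption: no prevalent-pool size
at launch is reported by the interview study, and linear growth reproduces the
"emerges by the second year" framing. Zero-capacity centres would have
infinite waits; `average_waiting_time()` excludes them from the mean by
default and reports their count separately, keeping the average finite and
interpretable (an `Inf` sentinel is used in per-centre trajectories).

`simulate_des()` is a stochastic cross-check, not the primary model:
procedure demand arrives as a Poisson process; service-start tokens are
released at the centre's capacity rate, computed from the profile's step
minutes and the centre's per-class FTEs; patients start FIFO at the later of
arrival and token availability and then occupy the chair/bed for the
profile's facility minutes. We deliberately do not simulate the three
resource pools as discrete servers: available FTEs are fractions of a
person (0.15 FTE of nursing is not a nurse standing idle), so a discrete
multi-server model would misrepresent the data; the token formulation keeps
the simulator consistent with the capacity equations while adding arrival
noise. In the uncongested limit realized sojourns reduce to the procedure
duration; under congestion the simulated mean waiting time converges to the
fluid value (tested to within 10% at three demand/capacity ratios with 200
replicates each).

## The synthetic survey generator

The interview dataset behind the model is not deposited anywhere, so the
package ships a generator instead of data, and the generator's defaults
*are* the study conditions: 40 centres, mean demand 114 patients/centre/year,
mean allocations 0.25 / 0.15 / 0.20 FTE (proceduralist / nurse / facility —
the facility value is one clinic day per week, implied by the report that
two days per week would be double the current average), willingness 0.65 and
0.80, a 25/50/25 component split, and coverage strata of 6 centres at full
coverage, 25 below 50% and 18 below 30% (cumulative bands: the <30% band is
a subset of the <50% band).

`generate_reference_survey()` uses *exact stratified construction*:
component flags are apportioned exactly to the split; target coverage
fractions are assigned per stratum (interior points of each band, descending)
and per-class availabilities are back-solved through the capacity equations,
so the headline counts hold by construction and downstream checks are
deterministic. Demand values are gamma draws (coefficient of variation 0.5,
a modelling assumption — only the mean is reported) rescaled so the sample
mean is exactly 114. Component flags correlate with coverage: the
best-covered centres are the ones reporting all three components. Strata
assignment is integer arithmetic and draws come from a fixed, named RNG
(Mersenne-Twister/inversion, seeded locally), so the fixture is stable
across runs and platforms. Infeasible requests — e.g. more full-coverage
centres than all-three centres — error out rather than silently adjusting.

Because the fixture is constructed *to* the reported distribution, tests
against its headline counts are end-to-end consistency checks of the gap
engine, not independent reproductions of the study; the fixture's metadata
labels it a synthetic emulation.

`generate_random_survey()` is the property-testing source: nothing is
back-solved; demand is a rounded-gamma (over-dispersed count-like) draw,
availabilities are right-skewed gamma draws zeroed where a component is
absent, and nurse/facility presence is thinned independently at the
split-implied marginal rate (each present with probability 0.5 under the
defaults, recovering the 25/50/25 split in expectation).

## Numerical choices

* Coverage snapped to 1 within `1e-9`; all other comparisons exact.
* Bottleneck ties broken by fixed class order.
* Reported FTEs rounded to 2 decimals and percentages to whole numbers in
  human-readable output; machine-readable outputs keep raw values.
* A resource class with no profile steps is never limiting (infinite
  per-class throughput), so partial profiles degrade gracefully.
* Generators and the simulator seed a local RNG and restore the caller's
  RNG state.

## What the tests do and do not show

The test suite runs the generators at n = 40 to 10,000 centres, checks the
gap engine against a brute-force per-class oracle on 1,000 random centres,
property-tests coverage monotonicity and bounds, and compares the simulator
to the fluid model at three congestion levels with 200 replicates (sizes
chosen to keep the full suite under a minute on one CPU). Passing these
shows the pipeline is internally consistent and reproduces the reported
aggregate structure — it cannot show that real centres resemble the
synthetic ones, since per-centre interview data were never released.
Country labels are cosmetic; no country-level heterogeneity is modelled.

## Limitations

* The model is linear and static: no capacity growth, prioritisation or
  triage, no pharmacy/consenting/follow-up time, and no cost modelling.
* Willingness as a multiplicative haircut is one reading of an informally
  described adjustment.
* The 60-month headline wait is reproduced at a representative 2/7 access
  fraction, not as a cross-centre average of unreleased per-centre data.
* Coverage bands are read as cumulative counts; the interview study's
  phrasing supports but does not state this.
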