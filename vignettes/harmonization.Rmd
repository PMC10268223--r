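---
title: "Harmonizing heterogeneous ICU data with a concept dictionary"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing heterogeneous ICU data with a concept dictionary}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icuharm)
```

## The problem

Publicly available intensive-care databases are strikingly heterogeneous
for such a narrow clinical domain. Some report absolute timestamps,
others minutes relative to unit admission; some expose a full hierarchy
of identifiers (patient, hospital stay, ICU stay) while others key
everything to a single admission id — and even within one database,
different tables may use different identifier levels. Table layouts
range from long entity–attribute–value (EAV) event tables, where a
numeric item code distinguishes heart rate from creatinine, to wide
periodic tables with one column per signal. The practical consequence is
that even conceptually simple tasks — "give me hourly heart rate per ICU
stay" or "compute a Sepsis-3 label" — are re-implemented, differently,
by every research group and for every database.

`icuharm` addresses this with a *concept dictionary*: clinical variables
are defined once (name, accepted units, plausibility bounds, optional
OMOP vocabulary id, result shape, aggregation), and per-database
*extraction items* describe how to obtain each variable from a
particular source. A declarative *source configuration* describes the
database itself: its tables, column semantics, identifier systems and
time mode. `load_concepts()` then produces identical, analysis-ready
tables no matter which layout the data arrived in.

## Table model

All results are one of three kinds, each a `data.table` plus metadata:

* `id_tbl` — keyed by identifier only (e.g. sex, diabetes status);
* `ts_tbl` — adds a regular time index: integer minutes, every value a
  multiple of the table's `interval` (60 minutes by default). Negative
  indexes are legal — ward labs drawn before ICU admission are real;
* `win_tbl` — adds a duration column, for episodes such as mechanical
  ventilation.

All times are canonical integer minutes internally; display layers may
render hours. Binning floors toward negative infinity (an event 61
minutes *before* admission bins to −120), applied uniformly so the grid
is consistent on both sides of the origin. Aggregation defaults are
type-based — numeric columns take the median, logical columns `any`,
strings the first value in input order — and every concept may override
them (total insulin, for instance, must be summed, not median-filtered).

Duration values in a `win_tbl` are required to be non-negative at
construction; sanitizing negative durations silently would hide
upstream extraction errors.

## The loading pipeline

For an atomic concept, `load_concepts()` runs, in order: item
extraction (row selection by code, or a whole-column read) → item
callbacks → unit harmonization → plausibility-bound filtering →
identifier-system conversion → time binning → aggregation. Two ordering
choices are deliberate and tested:

* **Bounds before aggregation.** Bounds are closed intervals
  (`value ∈ [min, max]` is kept; a 300-bpm reading passes a 0–300
  rule). Filtering must precede aggregation so that an artifactual
  350-bpm reading cannot contaminate an hourly median.
* **Identifier conversion before binning.** Conversion shifts time
  origins; binning afterwards keeps every index a multiple of the grid.

Converting from a finer to a coarser identifier maps through the origin
tables and shifts the index by the difference in admission times.
Converting from coarser to finer assigns each time-stamped row to the
stay whose half-open window `[admission, discharge)` contains its
absolute time; rows outside every window are dropped with a reported
count rather than attached to a nearest stay — silent reassignment is
the kind of choice that makes downstream labels irreproducible. Static
rows (a hospital-stay diagnosis) are instead broadcast to every
contained ICU stay. When a discharge time is unknown the window stays
open until the next stay of the same coarser identifier, or
indefinitely.

Unit strings are compared case-insensitively against the concept's
accepted list; registered conversions (e.g. creatinine µmol/L → mg/dL,
factor 1/88.42) are applied, and unrecognized units are kept but
flagged and warned about, on the view that dropping data silently is
worse than surfacing a unit problem.

A source that declares an item for a concept but has no matching rows
yields an *empty* result; a source with no item at all raises an
availability error. The distinction matters: the first is "measured
nothing", the second "cannot measure".

## Recursive concepts and the clinical library

Recursive concepts compute from other concepts through a registered
callback; references in JSON are restricted to a tiny grammar (bare
registered names, or `factory(name)` such as
`transform_fun(grep_diab)`), so no arbitrary code can ride along in a
dictionary document. The shipped dictionary holds 119 concepts — 92
atomic and 27 recursive — across eleven categories (blood gas,
chemistry, hematology, neurological, output, respiratory, vitals,
medications, microbiology, demographics, outcome).

SOFA is computed per organ system on the *worst* value in a trailing
24-hour window (`slide()`), scored with the standard thresholds fixed
in `sofa_rule()`: e.g. platelets < 50×10³/µL score 3; bilirubin
2.0–5.9 mg/dL scores 2; a PaO2/FiO2 of 350 scores 1 (the respiratory
tiers 3–4 additionally require ventilation, and un-ventilated patients
cap at 2); MAP below 70 mmHg without vasopressors scores 1. At any hour
where a component has no value in its window, that component
contributes 0 to the total — an explicit, auditable choice. The
literature's wide spread of reported Sepsis-3 prevalence is driven
partly by exactly such silent assumptions, so this one is documented
and tested rather than implied.

Suspected infection pairs antibiotics with culture sampling (culture
within 24 h after the antibiotic, or antibiotic within 72 h after the
culture; onset is the earlier event of the earliest qualifying pair).
The Sepsis-3 label fires at the first time within −48 h/+24 h of onset
at which SOFA has risen by ≥ 2 points over the window minimum observed
before that time.

`ins24` (total insulin over the first 24 hours, binned with left-closed
breaks 0, 1, 10, 20, 40, ∞) and `diab` (ICD-9 codes matching
`^250\.?[0-9]{2}$`) are shipped in the dictionary under medications and
demographics respectively. The first-day filter acts on the
hourly-binned index, so an administration at minute 1470 (hour bin 24)
counts. A recursive concept's `aggregate` field applies to the loading
of its dependencies — `ins24` loads `ins` with `sum` so that several
administrations within one hour are not median-collapsed.

## The synthetic cohort and what it shows

Because the real databases require credentialed access, the package
ships a generator that is *not* a physiology simulator: signals are
simple noise processes with exactly recorded planted features, and its
value is that `truth_lookup()` can state, independently of the loading
pipeline, what harmonization must produce. The generator's defaults
define the study conditions and are not tuned: hourly vitals with ~1%
out-of-bounds heart-rate artifacts (350 bpm), 6-hourly lactate with
random gaps, daily chemistry and hematology, 4-hourly GCS components,
insulin in the first 36 h, ~20% in-ICU mortality, ~25% diabetes
prevalence, ~25% septic patients who receive an antibiotic/culture pair
at hour 48 and a sustained platelet drop (250 → 45×10³/µL) at exactly
that hour. Septic patients get otherwise benign, flat baselines so the
planted platelet drop is the only SOFA movement inside the Sepsis-3
window, making the expected label hour exact. The canonical test cohort
is `generate_cohort(20230615, 200)`.

One cohort renders into three dialects: `eav_absolute` (long item-coded
events, ISO-8601 times, patient < hospital stay < ICU stay, with labs
and microbiology keyed by *hospital* stay to exercise identifier
conversion, and heart rate carried under item codes 211/220045),
`wide_relative` (wide periodic tables, minutes from unit admission,
flat id), and `eav_relative` (long events, relative minutes, flat id,
creatinine reported in µmol/L to exercise unit conversion). All three
renderings carry the same observation multiset; the flagship property —
checked for every shipped atomic concept — is that harmonized output is
identical across dialects up to the name of the id column. To keep that
property exact, all planted observations fall inside ICU stay windows
and deaths occur within the final stay; the behavior for out-of-window
rows (dropping, with a logged count) is exercised by dedicated unit
tests on hand-built sources instead. Equally, sampling rates are
properties of the cohort, not of the dialect: a dialect that sampled
differently could not be compared observation-for-observation.

What passing these tests does *not* show: fidelity to real EHR
messiness — duplicated charting, unit chaos beyond the registered
conversions, inter-signal physiology, informative missingness. The
synthetic suite demonstrates that the *machinery* is correct, not that
any clinical finding transfers.

## Numerical and design notes

* Problem sizes: the default test suite uses a 12-patient fixture for
  module tests and the canonical 200-patient cohort (~50k observations)
  for the end-to-end suite; both run in well under a minute each.
* Floating-point: unit conversion multiplies/divides by 88.42, so
  cross-dialect equality is asserted at tolerance 1e-8; everything else
  is exact integer arithmetic on minutes.
* LOCF imputation is idempotent and leaves leading missing values
  missing; constant imputation requires an explicit fill value (missing
  death flags are set to `FALSE` by the caller, never implicitly).
* Merging concepts is a full outer join with no implicit imputation;
  `fill_gaps()`/`replace_na()` are separate, explicit steps.
* `ties`: pre-aggregation ordering is stable (input order), so `first`
  is deterministic; post-aggregation keys are unique by construction
  and re-validated after every verb.
* User dictionaries are discovered through `ICUHARM_CONFIG_PATH`
  (a path-separated directory list); later documents override earlier
  ones per concept name, with provenance recording the override.
* The command-line surface (`exec/icuharm`: `gen`, `load`,
  `dict list|stats|validate`, `sources describe`) is a thin wrapper
  over the exported functions; `icuharm_main()` is the testable
  dispatcher.

## Known limitations

The dictionary's per-source item codes for the five real ICU databases
are synthetic stubs except where a published extraction rule is
explicit (heart-rate item codes, the diabetes regex); they make the
availability accounting concrete but have not been validated against
the real schemas. The respiratory SOFA component treats ventilation as
a binary indicator; pressure-support nuances are out of scope. eGFR,
MEWS and NEWS use simplified published formulas/threshold subsets and
are intended as derived-concept examples rather than validated scores.
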