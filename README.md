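# icuharm

Harmonization of heterogeneous intensive-care EHR data through a
concept dictionary.

## The problem

Research on ICU electronic health records is fragmented by the data
themselves: databases differ in timestamp conventions (absolute times
vs. minutes from admission), identifier systems (a full
patient < hospital stay < ICU stay hierarchy vs. a single flat
admission id — sometimes inconsistently across tables of *one*
database), and table layout (long entity–attribute–value event tables
keyed by item codes vs. wide periodic tables). As a result, even
routine derivations — hourly vitals per ICU stay, a SOFA score, a
Sepsis-3 label — are re-implemented ad hoc for every dataset, with
silent choices that make results hard to compare.

`icuharm` is for clinical-data researchers who want dataset-agnostic
analysis code. It separates three declarative layers:

* a **source configuration** (JSON) describing a database's tables,
  column semantics, identifier systems and time mode;
* a **concept dictionary** (JSON): 119 shipped clinical concepts — 92
  atomic, 27 recursive — each with accepted units, plausibility bounds,
  an optional OMOP vocabulary id, a result shape, an aggregation rule,
  and per-source extraction items;
* the **loading engine**: `load_concepts()` extracts, applies
  callbacks, harmonizes units, filters bounds (before aggregation, so
  a 350-bpm artifact cannot shift an hourly median), converts
  identifier systems by stay-window containment, bins times onto a
  regular minute grid (flooring toward −∞), aggregates, resolves
  recursive concepts (SOFA and its six components, suspected
  infection, Sepsis-3, GCS, PaO2/FiO2, first-day insulin, …) and
  merges multiple concepts into one table.

Results are `id_tbl` / `ts_tbl` / `win_tbl` objects: `data.table`s
keyed by identifier, identifier + regular time index (integer minutes),
or identifier + start + duration.

Because the real databases need credentialed access, the package ships
a synthetic cohort generator with exact planted ground truth, rendered
into three schema dialects (`eav_absolute`, `wide_relative`,
`eav_relative`); every pipeline feature is tested by demanding
identical harmonized output from all three renderings and equality with
the generator's independent oracle.

## Worked example

```r
library(icuharm)

truth <- generate_cohort(seed = 42, n_patients = 6)
dir <- file.path(tempdir(), "demo")
src <- register_source(render_source(truth, "eav_absolute", dir), dir)

dat <- load_concepts(c("lact", "death", "sofa"), src, id_type = "icustay")
dat <- truncate_at_first(dat, "death")   # keep rows up to the death hour
dat <- fill_gaps(dat)                    # dense hourly grid per stay
dat <- replace_na(dat, c(NA, FALSE), type = c("locf", "const"),
                  vars = c("lact", "death"))
print(dat[!is.na(dat$lact)], n = 6)
```

```
# A `ts_tbl`: 529 x 5
# Id var:   `icustay_id`
# Units:     `lact` [mmol/L]
# Index var: `time` (1 hours)
   icustay_id  time  lact  death  sofa
        <int> <int> <num> <lgcl> <int>
1:     300001  1440   2.3  FALSE     2
2:     300001  1500   2.3  FALSE     1
3:     300001  1560   2.3  FALSE     1
4:     300001  1620   2.3  FALSE     1
5:     300001  1680   2.3  FALSE     2
6:     300001  1740   2.3  FALSE     1
# ... with 523 more rows
```

One table, keyed by ICU stay, on an hourly grid: lactate carried
forward between draws, missing death flags set to `FALSE` (here one
stay ends in death), and the SOFA total recomputed each hour from the
24-hour worst value of each organ component. Loading by OMOP id instead
of abbreviation names the column accordingly:

```r
load_concepts(37116947, src)
```

```
# An `id_tbl`: 9 x 2
# Id var:   `icustay_id`
   icustay_id omop_37116947
        <int>        <char>
1:     300001          Male
2:     300002          Male
3:     300003          Male
# ... with 6 more rows
```

The same calls work unchanged against the `wide_relative` and
`eav_relative` renderings — that is the point.

User concepts extend the shipped dictionary through JSON files on
`ICUHARM_CONFIG_PATH`, or programmatically with `item()`/`concept()`.
A command-line wrapper is installed as `exec/icuharm`
(`gen`, `load`, `dict list|stats|validate`, `sources describe`).

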