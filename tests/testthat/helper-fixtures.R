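library(data.table)

## fixtures are generated once per test run and memoized here
.fixture_env <- new.env()

## a cohort rendered into all three dialects, with registered handles
get_fixture <- function(seed = 101, n = 12) {
  key <- sprintf("fx_%d_%d", seed, n)
  if (is.null(.fixture_env[[key]])) {
    truth <- generate_cohort(seed, n)
    root <- file.path(tempdir(), key)
    handles <- list()
    for (d in c("eav_absolute", "wide_relative", "eav_relative")) {
      dir <- file.path(root, d)
      cfg <- render_source(truth, d, dir)
      handles[[d]] <- register_source(cfg, dir)
    }
    .fixture_env[[key]] <- list(truth = truth, handles = handles,
                                root = root)
  }
  .fixture_env[[key]]
}

## the canonical published test cohort
get_canonical_fixture <- function() get_fixture(20230615, 200)

quiet_load <- function(...) {
  suppressWarnings(suppressMessages(load_concepts(...)))
}

## comparison helper: same harmonized content modulo id-column naming
sorted_plain <- function(tb, id_name = "id") {
  dt <- as.data.frame(tb)
  for (a in c("id_vars", "index_var", "interval", "dur_var", "units")) {
    attr(dt, a) <- NULL
  }
  names(dt)[names(dt) == id_vars(tb)[1L]] <- id_name
  dt <- dt[do.call(order, dt[intersect(c(id_name, "time"), names(dt))]),
           , drop = FALSE]
  rownames(dt) <- NULL
  dt
}

## a hand-built absolute-time source: one patient, one hospital stay
## holding two ICU stays, for identifier-conversion edge cases
make_two_stay_source <- function() {
  if (!is.null(.fixture_env$two_stay)) return(.fixture_env$two_stay)
  dir <- file.path(tempdir(), "two_stay_src")
  dir.create(dir, showWarnings = FALSE)
  iso <- function(min) icuharm:::fmt_abs_minutes(min)
  base <- 21024000L
  ## hadm window [base, base+10d); icu1 [base+1d, base+3d);
  ## icu2 [base+5d, base+7d)
  writeLines(c("patient_id,first_adm,last_disch",
               sprintf("1,%s,%s", iso(base), iso(base + 14400L))),
             file.path(dir, "patients.csv"))
  writeLines(c("patient_id,hadm_id,admittime,dischtime",
               sprintf("1,10,%s,%s", iso(base), iso(base + 14400L))),
             file.path(dir, "admissions.csv"))
  writeLines(c("patient_id,hadm_id,icustay_id,intime,outtime",
               sprintf("1,10,100,%s,%s", iso(base + 1440L),
                       iso(base + 3 * 1440L)),
               sprintf("1,10,101,%s,%s", iso(base + 5 * 1440L),
                       iso(base + 7 * 1440L))),
             file.path(dir, "icustays.csv"))
  ## events: one before any ICU stay, one in stay 1, one in stay 2
  writeLines(c("hadm_id,charttime,itemid,value",
               sprintf("10,%s,7,1.0", iso(base + 600L)),
               sprintf("10,%s,7,2.0", iso(base + 1440L + 120L)),
               sprintf("10,%s,7,3.0", iso(base + 5 * 1440L + 60L))),
             file.path(dir, "labevents.csv"))
  cfg <- parse_source_config(list(
    name = "two_stay", time_mode = "absolute",
    id_systems = list(
      list(name = "patient", id_column = "patient_id",
           origin_table = "patients", start_column = "first_adm",
           end_column = "last_disch", rank = 1L),
      list(name = "hadm", id_column = "hadm_id",
           origin_table = "admissions", start_column = "admittime",
           end_column = "dischtime", rank = 2L),
      list(name = "icustay", id_column = "icustay_id",
           origin_table = "icustays", start_column = "intime",
           end_column = "outtime", rank = 3L)),
    tables = list(
      list(name = "patients", file = "patients.csv",
           columns = list(list(name = "patient_id", type = "id"),
                          list(name = "first_adm", type = "timestamp"),
                          list(name = "last_disch", type = "timestamp")),
           defaults = list(id_column = "patient_id")),
      list(name = "admissions", file = "admissions.csv",
           columns = list(list(name = "patient_id", type = "id"),
                          list(name = "hadm_id", type = "id"),
                          list(name = "admittime", type = "timestamp"),
                          list(name = "dischtime", type = "timestamp")),
           defaults = list(id_column = "hadm_id")),
      list(name = "icustays", file = "icustays.csv",
           columns = list(list(name = "patient_id", type = "id"),
                          list(name = "hadm_id", type = "id"),
                          list(name = "icustay_id", type = "id"),
                          list(name = "intime", type = "timestamp"),
                          list(name = "outtime", type = "timestamp")),
           defaults = list(id_column = "icustay_id")),
      list(name = "labevents", file = "labevents.csv",
           columns = list(list(name = "hadm_id", type = "id"),
                          list(name = "charttime", type = "timestamp"),
                          list(name = "itemid", type = "string"),
                          list(name = "value", type = "number")),
           defaults = list(id_column = "hadm_id",
                           index_column = "charttime",
                           value_column = "value")))))
  .fixture_env$two_stay <- register_source(cfg, dir)
  .fixture_env$two_stay
}

## paper-style heart-rate concept document
hr_concept_json <- '{
 "hr": {
  "unit": ["bpm", "/min"],
  "min": 0,
  "max": 300,
  "omopid": 4239408,
  "description": "heart rate",
  "category": "routine vital signs",
  "sources": {
   "mimic_demo": [
    {
     "ids": [211, 220045],
     "table": "chartevents",
     "sub_var": "itemid"
    }
   ]
  }
 }
}'
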