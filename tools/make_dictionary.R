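#!/usr/bin/env Rscript
## Regenerates inst/extdata/dictionary/*.json (the shipped concept
## dictionary). Run from the package root:  Rscript tools/make_dictionary.R

suppressMessages(pkgload::load_all(".", quiet = TRUE))

real_sources <- c("mimic", "eicu", "aumc", "hirid", "miiv")

## concepts missing per real source (editorial; availability per source
## is atomic-concept count minus these)
missing_by_source <- list(
  mimic = c("rass", "avpu", "etco2"),
  eicu  = c("be", "methb", "cai", "bnd", "esr"),
  aumc  = c("avpu", "bnd", "esr", "trig", "ckmb", "phn_rate", "dex"),
  hirid = c("disch", "rrt", "trach", "dnr", "diab", "height", "cort",
            "sed", "hep", "dex", "adh_rate", "phn_rate", "avpu", "rass",
            "urine", "supp_o2", "esr", "bnd"),
  miiv  = c("etco2", "avpu", "esr", "bnd", "methb")
)

num <- function(name, desc, cat, unit = NULL, min = NULL, max = NULL,
                omopid = NULL, target = "ts_tbl", aggregate = NULL) {
  list(name = name, class = "num_cncpt", description = desc,
       category = cat, unit = unit, min = min, max = max,
       omopid = omopid, target = target, aggregate = aggregate)
}
lgl <- function(name, desc, cat, target = "ts_tbl", omopid = NULL,
                aggregate = "any") {
  list(name = name, class = "lgl_cncpt", description = desc,
       category = cat, omopid = omopid, target = target,
       aggregate = aggregate)
}
fct <- function(name, desc, cat, levels, target = "ts_tbl",
                omopid = NULL, aggregate = "first") {
  list(name = name, class = "fct_cncpt", description = desc,
       category = cat, levels = levels, omopid = omopid, target = target,
       aggregate = aggregate)
}
rec <- function(name, desc, cat, depends, callback, target = "ts_tbl",
                aggregate = NULL, omopid = NULL) {
  list(name = name, class = "rec_cncpt", description = desc,
       category = cat, concepts = depends, callback = callback,
       target = target, aggregate = aggregate, omopid = omopid)
}

atomic <- list(
  ## blood gas (9)
  num("po2", "arterial oxygen partial pressure", "blood gas",
      c("mmHg"), 0, 700, omopid = 4094581),
  num("pco2", "arterial carbon dioxide partial pressure", "blood gas",
      c("mmHg"), 0, 250, omopid = 4097882),
  num("ph", "arterial pH", "blood gas", NULL, 6.5, 8, omopid = 4097822),
  num("be", "base excess", "blood gas", c("mEq/L"), -50, 50),
  num("bicar", "bicarbonate", "blood gas", c("mEq/L", "mmol/L"), 0, 60,
      omopid = 4194291),
  num("lact", "lactate", "blood gas", c("mmol/L"), 0, 50,
      omopid = 4191725),
  num("methb", "methemoglobin fraction", "blood gas", c("%"), 0, 100),
  num("cai", "ionized calcium", "blood gas", c("mmol/L"), 0, 5),
  num("tco2", "total carbon dioxide", "blood gas", c("mEq/L"), 0, 80),
  ## chemistry (20)
  num("alb", "albumin", "chemistry", c("g/dL"), 0, 10, omopid = 4097664),
  num("alp", "alkaline phosphatase", "chemistry", c("IU/L"), 0, 3000),
  num("alt", "alanine aminotransferase", "chemistry", c("IU/L"), 0, 10000),
  num("ast", "aspartate aminotransferase", "chemistry", c("IU/L"), 0,
      10000),
  num("bili", "total bilirubin", "chemistry", c("mg/dL"), 0, 100,
      omopid = 4118986),
  num("bili_dir", "direct bilirubin", "chemistry", c("mg/dL"), 0, 50),
  num("bun", "blood urea nitrogen", "chemistry", c("mg/dL"), 0, 300),
  num("ca", "calcium", "chemistry", c("mg/dL"), 0, 20),
  num("cl", "chloride", "chemistry", c("mEq/L"), 50, 200),
  num("crea", "creatinine", "chemistry", c("mg/dL"), 0, 50,
      omopid = 4013964),
  num("ck", "creatine kinase", "chemistry", c("IU/L"), 0, 100000),
  num("ckmb", "creatine kinase MB", "chemistry", c("ng/mL"), 0, 10000),
  num("crp", "C-reactive protein", "chemistry", c("mg/L"), 0, 1000),
  num("glu", "glucose", "chemistry", c("mg/dL"), 0, 2000,
      omopid = 4149519),
  num("k", "potassium", "chemistry", c("mEq/L", "mmol/L"), 0, 15,
      omopid = 4276440),
  num("mg", "magnesium", "chemistry", c("mg/dL"), 0, 10),
  num("na", "sodium", "chemistry", c("mEq/L", "mmol/L"), 80, 220,
      omopid = 4269839),
  num("phos", "phosphate", "chemistry", c("mg/dL"), 0, 20),
  num("trig", "triglycerides", "chemistry", c("mg/dL"), 0, 5000),
  num("tnt", "troponin T", "chemistry", c("ng/mL"), 0, 100),
  ## hematology (20)
  num("plt", "platelet count", "hematology", c("K/uL", "10^3/uL"), 0,
      2000, omopid = 4267147),
  num("hgb", "hemoglobin", "hematology", c("g/dL"), 0, 25,
      omopid = 4118981),
  num("hct", "hematocrit", "hematology", c("%"), 0, 75),
  num("wbc", "white blood cell count", "hematology", c("K/uL"), 0, 500,
      omopid = 4298431),
  num("rbc", "red blood cell count", "hematology", c("M/uL"), 0, 15),
  num("mcv", "mean corpuscular volume", "hematology", c("fL"), 0, 150),
  num("mch", "mean corpuscular hemoglobin", "hematology", c("pg"), 0, 60),
  num("mchc", "mean corpuscular hemoglobin concentration", "hematology",
      c("g/dL"), 0, 50),
  num("rdw", "red cell distribution width", "hematology", c("%"), 0, 40),
  num("ptt", "partial thromboplastin time", "hematology", c("sec"), 0,
      250),
  num("pt", "prothrombin time", "hematology", c("sec"), 0, 150),
  num("inr_pt", "international normalized ratio", "hematology", NULL, 0,
      20),
  num("fgn", "fibrinogen", "hematology", c("mg/dL"), 0, 1500),
  num("neut", "neutrophil fraction", "hematology", c("%"), 0, 100),
  num("lymph", "lymphocyte fraction", "hematology", c("%"), 0, 100),
  num("mono", "monocyte fraction", "hematology", c("%"), 0, 100),
  num("eos", "eosinophil fraction", "hematology", c("%"), 0, 100),
  num("baso", "basophil fraction", "hematology", c("%"), 0, 100),
  num("bnd", "band neutrophil fraction", "hematology", c("%"), 0, 100),
  num("esr", "erythrocyte sedimentation rate", "hematology", c("mm/hr"),
      0, 200),
  ## neurological (5 atomic)
  num("egcs", "GCS eye component", "neurological", NULL, 1, 4),
  num("vgcs", "GCS verbal component", "neurological", NULL, 1, 5),
  num("mgcs", "GCS motor component", "neurological", NULL, 1, 6),
  num("rass", "Richmond agitation-sedation scale", "neurological", NULL,
      -5, 4),
  fct("avpu", "alert/voice/pain/unresponsive scale", "neurological",
      c("A", "V", "P", "U")),
  ## output (1)
  num("urine", "urine output", "output", c("mL"), 0, 2000,
      aggregate = "sum"),
  ## respiratory (8)
  num("fio2", "inspired oxygen fraction", "respiratory", c("%"), 21, 100),
  num("o2sat", "oxygen saturation", "respiratory", c("%"), 0, 100,
      omopid = 4196147),
  num("resp", "respiratory rate", "respiratory", c("/min", "insp/min"),
      0, 120, omopid = 4313591),
  num("peep", "positive end-expiratory pressure", "respiratory",
      c("cmH2O"), 0, 50),
  num("tidal_vol", "tidal volume", "respiratory", c("mL"), 0, 2000),
  num("minute_vol", "minute ventilation", "respiratory", c("L/min"), 0,
      50),
  fct("mech_vent", "mechanical ventilation episode", "respiratory",
      c("invasive", "noninvasive"), target = "win_tbl"),
  lgl("supp_o2", "supplemental oxygen", "respiratory"),
  ## vitals (6)
  num("hr", "heart rate", "vitals", c("bpm", "/min"), 0, 300,
      omopid = 4239408),
  num("map", "mean arterial pressure", "vitals", c("mmHg", "mm Hg"), 0,
      250, omopid = 4239021),
  num("sbp", "systolic blood pressure", "vitals", c("mmHg"), 0, 300,
      omopid = 4152194),
  num("dbp", "diastolic blood pressure", "vitals", c("mmHg"), 0, 200,
      omopid = 4154790),
  num("temp", "body temperature", "vitals", c("C"), 30, 45,
      omopid = 4302666),
  num("etco2", "end-tidal carbon dioxide", "vitals", c("mmHg"), 0, 150),
  ## medications (12 atomic)
  num("ins", "insulin administered", "medications", c("units")),
  lgl("abx", "antibiotic administered", "medications"),
  num("dopa_rate", "dopamine infusion rate", "medications",
      c("ug/kg/min"), 0, 50),
  num("dobu_rate", "dobutamine infusion rate", "medications",
      c("ug/kg/min"), 0, 50),
  num("epi_rate", "epinephrine infusion rate", "medications",
      c("ug/kg/min"), 0, 10),
  num("norepi_rate", "norepinephrine infusion rate", "medications",
      c("ug/kg/min"), 0, 10),
  num("adh_rate", "vasopressin infusion rate", "medications",
      c("units/min"), 0, 1),
  num("phn_rate", "phenylephrine infusion rate", "medications",
      c("ug/kg/min"), 0, 20),
  lgl("cort", "corticosteroid administered", "medications"),
  lgl("sed", "sedative administered", "medications"),
  lgl("hep", "heparin administered", "medications"),
  lgl("dex", "dexmedetomidine administered", "medications"),
  ## microbiology (1)
  lgl("samp", "culture specimen sampled", "microbiology"),
  ## demographics (5 atomic)
  num("age", "patient age", "demographics", c("years"), 0, 130,
      target = "id_tbl", aggregate = "first", omopid = 4265453),
  fct("sex", "patient sex", "demographics", c("Male", "Female"),
      target = "id_tbl", omopid = 37116947),
  num("height", "patient height", "demographics", c("cm"), 0, 260,
      target = "id_tbl", aggregate = "first"),
  num("weight", "patient weight", "demographics", c("kg"), 0, 500,
      target = "id_tbl", aggregate = "first"),
  lgl("diab", "diabetes status (ICD-9 250.xx)", "demographics",
      target = "id_tbl"),
  ## outcome (5 atomic)
  lgl("death", "in-hospital death flag", "outcome", omopid = 4306655),
  fct("disch", "discharge destination", "outcome",
      c("home", "expired", "transfer"), target = "id_tbl"),
  lgl("rrt", "renal replacement therapy", "outcome"),
  lgl("trach", "tracheostomy", "outcome"),
  lgl("dnr", "do-not-resuscitate order", "outcome")
)

recursive <- list(
  rec("pafi", "PaO2/FiO2 ratio", "blood gas", c("po2", "fio2"),
      "pafi_cb"),
  rec("egfr", "estimated glomerular filtration rate", "chemistry",
      c("crea", "age", "sex"), "egfr_cb"),
  rec("gcs", "Glasgow coma scale total", "neurological",
      c("egcs", "vgcs", "mgcs"), "gcs_cb", omopid = 4093836),
  rec("tgcs", "total GCS (alias of component sum)", "neurological",
      c("gcs"), "tgcs_cb"),
  rec("urine24", "24-hour urine output", "output", c("urine"),
      "urine24_cb"),
  rec("vent_ind", "ventilation indicator", "respiratory",
      c("mech_vent"), "vent_ind_cb"),
  rec("safi", "SpO2/FiO2 ratio", "respiratory", c("o2sat", "fio2"),
      "safi_cb"),
  rec("ins24", "insulin administered in first 24 h", "medications",
      c("ins"), "ins_cb", target = "id_tbl", aggregate = "sum"),
  rec("vaso_ind", "vasopressor indicator", "medications",
      c("dopa_rate", "dobu_rate", "epi_rate", "norepi_rate"),
      "vaso_ind_cb"),
  rec("vaso60", "max vasopressor rate over trailing hour", "medications",
      c("norepi_rate"), "vaso60_cb"),
  rec("dopa60", "max dopamine rate over trailing hour", "medications",
      c("dopa_rate"), "dopa60_cb"),
  rec("norepi60", "max norepinephrine rate over trailing hour",
      "medications", c("norepi_rate"), "norepi60_cb"),
  rec("bmi", "body mass index", "demographics", c("height", "weight"),
      "bmi_cb", target = "id_tbl"),
  rec("sofa_resp", "SOFA respiratory component", "outcome",
      c("pafi", "vent_ind"), "sofa_resp_cb"),
  rec("sofa_coag", "SOFA coagulation component", "outcome", c("plt"),
      "sofa_coag_cb"),
  rec("sofa_liver", "SOFA liver component", "outcome", c("bili"),
      "sofa_liver_cb"),
  rec("sofa_cardio", "SOFA cardiovascular component", "outcome",
      c("map", "dopa_rate", "dobu_rate", "epi_rate", "norepi_rate"),
      "sofa_cardio_cb"),
  rec("sofa_cns", "SOFA central nervous system component", "outcome",
      c("gcs"), "sofa_cns_cb"),
  rec("sofa_renal", "SOFA renal component", "outcome", c("crea"),
      "sofa_renal_cb"),
  rec("sofa", "SOFA total score", "outcome",
      c("sofa_resp", "sofa_coag", "sofa_liver", "sofa_cardio",
        "sofa_cns", "sofa_renal"), "sofa_cb", omopid = 1616852),
  rec("susp_inf", "suspected infection onset", "outcome",
      c("abx", "samp"), "susp_inf_cb"),
  rec("sep3", "Sepsis-3 label", "outcome", c("sofa", "susp_inf"),
      "sep3_cb", omopid = 132797),
  rec("qsofa", "quick SOFA score", "outcome", c("sbp", "resp", "gcs"),
      "qsofa_cb"),
  rec("sirs", "SIRS criteria count", "outcome",
      c("temp", "hr", "resp", "wbc"), "sirs_cb"),
  rec("mews", "modified early warning score (simplified)", "outcome",
      c("sbp", "hr", "resp", "temp", "avpu"), "mews_cb"),
  rec("news", "national early warning score (simplified)", "outcome",
      c("resp", "o2sat", "temp", "sbp", "hr"), "news_cb"),
  rec("aki", "acute kidney injury flag (creatinine criteria)", "outcome",
      c("crea"), "aki_cb")
)

## ---- per-dialect extraction items ------------------------------------

sel <- function(table, sub_var, ids, callback = NULL) {
  o <- list(table = table, sub_var = sub_var, ids = as.list(ids),
            class = "sel_itm")
  if (!is.null(callback)) o$callback <- callback
  o
}
col <- function(table, value_column = NULL, callback = NULL) {
  o <- list(table = table, class = "col_itm")
  if (!is.null(value_column)) o$value_column <- value_column
  if (!is.null(callback)) o$callback <- callback
  o
}

dialect_items <- function(name, filler_code) {
  ca <- icuharm:::synth_codes$eav_absolute
  cr <- icuharm:::synth_codes$eav_relative
  switch(name,
    hr = , map = , egcs = , vgcs = , mgcs = list(
      eav_absolute = sel("chartevents", "itemid", ca[[name]]),
      wide_relative = col(
        if (name %in% c("hr", "map")) "vitalperiodic" else "nursecharting",
        if (name == "hr") "heartrate" else name),
      eav_relative = sel("events", "itemid", cr[[name]])),
    lact = , bili = , plt = , crea = list(
      eav_absolute = sel("labevents", "itemid", ca[[name]]),
      wide_relative = col("lab", name),
      eav_relative = sel("events", "itemid", cr[[name]])),
    ins = list(
      eav_absolute = sel("inputevents", "itemid", ca$ins),
      wide_relative = sel("medication", "drugcode", "INS"),
      eav_relative = sel("pharma", "itemid", cr$ins)),
    abx = list(
      eav_absolute = sel("inputevents", "itemid", ca$abx, "flag_true"),
      wide_relative = sel("medication", "drugcode", "ABX", "flag_true"),
      eav_relative = sel("pharma", "itemid", cr$abx, "flag_true")),
    samp = list(
      eav_absolute = col("microbiologyevents", callback = "flag_true"),
      wide_relative = col("microlab", callback = "flag_true"),
      eav_relative = col("culture", callback = "flag_true")),
    mech_vent = list(
      eav_absolute = col("ventevents"),
      wide_relative = col("vent"),
      eav_relative = col("vent")),
    diab = list(
      eav_absolute = col("diagnoses_icd",
                         callback = "transform_fun(grep_diab)"),
      wide_relative = col("diagnosis", callback =
                            "transform_fun(grep_diab)"),
      eav_relative = col("diagnosis", callback =
                           "transform_fun(grep_diab)")),
    death = list(
      eav_absolute = col("admissions", "deathtime", "death_flag"),
      wide_relative = col("unitstays", "deathoffset", "death_flag"),
      eav_relative = col("admissions", "dateofdeath", "death_flag")),
    age = list(
      eav_absolute = col("patients", "age"),
      wide_relative = col("unitstays", "age"),
      eav_relative = col("admissions", "age")),
    sex = list(
      eav_absolute = col("patients", "sex"),
      wide_relative = col("unitstays", "sex"),
      eav_relative = col("admissions", "sex")),
    ## filler: codes that the synthetic generator never emits
    list(
      eav_absolute = sel("chartevents", "itemid", filler_code),
      wide_relative = sel("misc", "conceptcode",
                          paste0("C", filler_code)),
      eav_relative = sel("events", "itemid", filler_code))
  )
}

## ---- assemble ---------------------------------------------------------

entries <- list()
stub_code <- 50000L
filler_code <- 90000L
for (i in seq_along(atomic)) {
  a <- atomic[[i]]
  nm <- a$name
  e <- a[!vapply(a, is.null, logical(1))]
  e$name <- NULL
  if (!is.null(e$unit)) e$unit <- as.list(e$unit)
  if (!is.null(e$levels)) e$levels <- as.list(e$levels)
  srcs <- list()
  ## real-database stubs (synthetic item codes except printed examples)
  for (s in real_sources) {
    if (nm %in% missing_by_source[[s]]) next
    stub_code <- stub_code + 1L
    it <- if (nm == "hr" && s %in% c("mimic", "miiv")) {
      sel("chartevents", "itemid", c(211, 220045))
    } else if (nm == "diab" && s %in% c("mimic", "miiv")) {
      col("diagnoses_icd", callback = "transform_fun(grep_diab)")
    } else {
      sel("events", "itemid", stub_code)
    }
    srcs[[s]] <- list(it)
  }
  filler_code <- filler_code + 1L
  di <- dialect_items(nm, filler_code)
  for (d in names(di)) srcs[[d]] <- list(di[[d]])
  e$sources <- srcs
  entries[[nm]] <- e
}
for (r in recursive) {
  e <- r[!vapply(r, is.null, logical(1))]
  nm <- e$name
  e$name <- NULL
  e$concepts <- as.list(e$concepts)
  entries[[nm]] <- e
}

## ---- split by category and write -------------------------------------

dir.create("inst/extdata/dictionary", recursive = TRUE,
           showWarnings = FALSE)
unlink(list.files("inst/extdata/dictionary", pattern = "\\.json$",
                  full.names = TRUE))
cats <- unique(vapply(entries, function(e) e$category, character(1)))
for (cat in cats) {
  sub <- entries[vapply(entries, function(e) identical(e$category, cat),
                        logical(1))]
  fn <- file.path("inst/extdata/dictionary",
                  paste0("concepts-", gsub("[^a-z]+", "-", cat), ".json"))
  jsonlite::write_json(sub, fn, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = FALSE)
}

## sanity check
d <- parse_dictionary(as.list(list.files("inst/extdata/dictionary",
                                         full.names = TRUE)))
s <- dict_stats(d, sources = real_sources)
stopifnot(s$total == 119L, s$atomic == 92L, s$recursive == 27L)
stopifnot(identical(
  s$by_source[real_sources],
  c(mimic = 89L, eicu = 87L, aumc = 85L, hirid = 74L, miiv = 87L)))
cat("total:", s$total, "atomic:", s$atomic, "recursive:", s$recursive, "\n")
print(s$by_category)
print(s$by_source)
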