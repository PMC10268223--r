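## Render one CohortTruth into a schema dialect: CSV tables plus a
## matching JSON source configuration. All three renderings carry the
## same observation multiset, so harmonized output must agree across
## dialects (modulo id-column naming).

#' @name render_source
#' @rdname render_source
NULL

synth_dialects <- c("eav_absolute", "wide_relative", "eav_relative")

## item codes shared between the renderers and the shipped dictionary
synth_codes <- list(
  eav_absolute = list(hr = c(211, 220045), map = 220052, egcs = 220739,
                      vgcs = 223900, mgcs = 223901, lact = 50813,
                      bili = 50885, plt = 51265, crea = 50912,
                      ins = 223258, abx = 225798),
  eav_relative = list(hr = 6640, map = 6642, egcs = 6732, vgcs = 6735,
                      mgcs = 6734, lact = 10053, bili = 9945, plt = 9964,
                      crea = 9941, ins = 340, abx = 350)
)

col_def <- function(name, type) list(name = name, type = type)

tbl_def <- function(name, columns, defaults = NULL) {
  cols <- lapply(names(columns), function(n) col_def(n, columns[[n]]))
  out <- list(name = name, file = paste0(name, ".csv"), columns = cols)
  if (!is.null(defaults)) out$defaults <- defaults
  out
}

write_csv <- function(dt, dir, name) {
  data.table::fwrite(dt, file.path(dir, paste0(name, ".csv")), na = "",
                     quote = "auto")
}

#' Render a cohort into a schema dialect
#'
#' Writes the CSV tables and JSON source configuration of one dialect:
#'
#' * `"eav_absolute"`: long item-coded event tables, absolute ISO-8601
#'   timestamps, three nested identifier systems (patient < hospital
#'   stay < ICU stay); lab and microbiology tables are keyed by
#'   hospital stay, exercising identifier conversion. Heart-rate rows
#'   carry item codes 211/220045.
#' * `"wide_relative"`: wide periodic tables, integer minutes from ICU
#'   admission, a single flat identifier.
#' * `"eav_relative"`: long event tables, relative minutes, flat
#'   identifier; creatinine is reported in umol/L, exercising unit
#'   conversion.
#'
#' @param truth A `cohort_truth` from [generate_cohort()].
#' @param dialect One of `"eav_absolute"`, `"wide_relative"`,
#'   `"eav_relative"`.
#' @param out_dir Output directory (created if needed).
#' @return The `src_cfg` of the rendered source (also written to
#'   `config.json` in `out_dir`), invisibly.
#' @export
render_source <- function(truth, dialect, out_dir) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (!dialect %in% synth_dialects) {
    stop("unknown dialect `", dialect, "` (known: ",
         paste(synth_dialects, collapse = ", "), ")", call. = FALSE)
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  if (file.access(out_dir, 2L) != 0L) {
    stop("output directory not writable: ", out_dir, call. = FALSE)
  }
  cfg <- switch(dialect,
    eav_absolute = render_eav_absolute(truth, out_dir),
    wide_relative = render_wide_relative(truth, out_dir),
    eav_relative = render_eav_relative(truth, out_dir))
  writeLines(serialize_source_config(cfg), file.path(out_dir, "config.json"))
  invisible(cfg)
}

render_eav_absolute <- function(truth, dir) {
  st <- truth$stays
  obs <- copy(truth$obs)
  obs <- merge(obs, st[, c("icustay_id", "icu_start")], by = "icustay_id")
  obs$abs_time <- obs$icu_start + obs$rel_time
  codes <- synth_codes$eav_absolute

  pats <- st[, list(sex = sex[1L], age = age[1L],
                    first_adm = fmt_abs_minutes(min(hadm_start)),
                    last_disch = fmt_abs_minutes(max(hadm_end))),
             by = "patient_id"]
  write_csv(pats, dir, "patients")

  adm <- unique(st[, list(patient_id, hadm_id, hadm_start, hadm_end)])
  dth <- st[!is.na(st$death_time)]
  dth <- if (nrow(dth) > 0L) {
    dth[, list(death_time = max(death_time)), by = "hadm_id"]
  } else {
    data.table(hadm_id = integer(), death_time = integer())
  }
  adm <- merge(adm, dth, by = "hadm_id", all.x = TRUE)
  adm <- adm[, list(patient_id, hadm_id,
                    admittime = fmt_abs_minutes(hadm_start),
                    dischtime = fmt_abs_minutes(hadm_end),
                    deathtime = ifelse(is.na(death_time), NA_character_,
                                       fmt_abs_minutes(death_time)))]
  write_csv(adm, dir, "admissions")

  icu <- st[, list(patient_id, hadm_id, icustay_id,
                   intime = fmt_abs_minutes(icu_start),
                   outtime = fmt_abs_minutes(icu_end))]
  write_csv(icu, dir, "icustays")

  chart_concepts <- c("hr", "map", "egcs", "vgcs", "mgcs")
  ce <- obs[obs$concept %in% chart_concepts]
  ## heart rate alternates between its two equivalent item codes
  itemid <- vapply(seq_len(nrow(ce)), function(i) {
    cc <- codes[[ce$concept[i]]]
    cc[(i %% length(cc)) + 1L]
  }, numeric(1))
  ce <- data.table(icustay_id = ce$icustay_id,
                   charttime = fmt_abs_minutes(ce$abs_time),
                   itemid = as.integer(itemid), value = ce$value,
                   valueuom = ce$unit)
  write_csv(ce, dir, "chartevents")

  lab_concepts <- c("lact", "bili", "plt", "crea")
  le <- obs[obs$concept %in% lab_concepts]
  le <- data.table(hadm_id = le$hadm_id,
                   charttime = fmt_abs_minutes(le$abs_time),
                   itemid = as.integer(unlist(codes[le$concept])),
                   value = le$value, valueuom = le$unit)
  write_csv(le, dir, "labevents")

  ie <- obs[obs$concept %in% c("ins", "abx")]
  ie <- data.table(icustay_id = ie$icustay_id,
                   starttime = fmt_abs_minutes(ie$abs_time),
                   itemid = as.integer(unlist(codes[ie$concept])),
                   amount = ie$value, amountuom = ie$unit)
  write_csv(ie, dir, "inputevents")

  mb <- obs[obs$concept == "samp"]
  mb <- data.table(hadm_id = mb$hadm_id,
                   charttime = fmt_abs_minutes(mb$abs_time),
                   spec_type = "BLOOD CULTURE")
  write_csv(mb, dir, "microbiologyevents")

  vt <- merge(truth$vent, st[, c("icustay_id", "icu_start")],
              by = "icustay_id")
  vt <- data.table(icustay_id = vt$icustay_id,
                   starttime = fmt_abs_minutes(vt$icu_start + vt$start_rel),
                   duration = vt$dur, ventmode = vt$mode)
  write_csv(vt, dir, "ventevents")

  dg <- truth$diag[, list(hadm_id, icd9_code)]
  write_csv(dg, dir, "diagnoses_icd")

  parse_source_config(list(
    name = "eav_absolute", time_mode = "absolute",
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
      tbl_def("patients",
              c(patient_id = "id", sex = "string", age = "number",
                first_adm = "timestamp", last_disch = "timestamp"),
              list(id_column = "patient_id")),
      tbl_def("admissions",
              c(patient_id = "id", hadm_id = "id", admittime = "timestamp",
                dischtime = "timestamp", deathtime = "timestamp"),
              list(id_column = "hadm_id")),
      tbl_def("icustays",
              c(patient_id = "id", hadm_id = "id", icustay_id = "id",
                intime = "timestamp", outtime = "timestamp"),
              list(id_column = "icustay_id")),
      tbl_def("chartevents",
              c(icustay_id = "id", charttime = "timestamp",
                itemid = "string", value = "number", valueuom = "string"),
              list(id_column = "icustay_id", index_column = "charttime",
                   value_column = "value", unit_column = "valueuom")),
      tbl_def("labevents",
              c(hadm_id = "id", charttime = "timestamp", itemid = "string",
                value = "number", valueuom = "string"),
              list(id_column = "hadm_id", index_column = "charttime",
                   value_column = "value", unit_column = "valueuom")),
      tbl_def("inputevents",
              c(icustay_id = "id", starttime = "timestamp",
                itemid = "string", amount = "number", amountuom = "string"),
              list(id_column = "icustay_id", index_column = "starttime",
                   value_column = "amount", unit_column = "amountuom")),
      tbl_def("microbiologyevents",
              c(hadm_id = "id", charttime = "timestamp",
                spec_type = "string"),
              list(id_column = "hadm_id", index_column = "charttime",
                   value_column = "spec_type")),
      tbl_def("ventevents",
              c(icustay_id = "id", starttime = "timestamp",
                duration = "duration", ventmode = "string"),
              list(id_column = "icustay_id", index_column = "starttime",
                   value_column = "ventmode", dur_column = "duration")),
      tbl_def("diagnoses_icd",
              c(hadm_id = "id", icd9_code = "string"),
              list(id_column = "hadm_id", value_column = "icd9_code")))))
}

widen <- function(obs, concepts, id_col, time_col) {
  o <- obs[obs$concept %in% concepts]
  if (nrow(o) == 0L) {
    out <- data.table(id = integer(), time = integer())
    for (cc in concepts) out[[cc]] <- numeric()
    setnames(out, c("id", "time"), c(id_col, time_col))
    return(out)
  }
  w <- data.table::dcast(o, icustay_id + rel_time ~ concept,
                         value.var = "value", fun.aggregate = function(x) {
                           x[1L]
                         }, fill = NA)
  for (cc in setdiff(concepts, names(w))) w[[cc]] <- NA_real_
  setnames(w, c("icustay_id", "rel_time"), c(id_col, time_col))
  setcolorder(w, c(id_col, time_col, concepts))
  w
}

render_wide_relative <- function(truth, dir) {
  st <- truth$stays
  obs <- truth$obs
  us <- st[, list(patientunitstayid = icustay_id, unitadmitoffset = 0L,
                  unitdischargeoffset = icu_end - icu_start,
                  age = age, sex = sex,
                  deathoffset = ifelse(is.na(death_time), NA_integer_,
                                       death_time - icu_start))]
  write_csv(us, dir, "unitstays")

  vp <- widen(obs, c("hr", "map"), "patientunitstayid", "observationoffset")
  setnames(vp, "hr", "heartrate")
  write_csv(vp, dir, "vitalperiodic")

  write_csv(widen(obs, c("egcs", "vgcs", "mgcs"), "patientunitstayid",
                  "nursingchartoffset"), dir, "nursecharting")

  write_csv(widen(obs, c("lact", "bili", "plt", "crea"),
                  "patientunitstayid", "labresultoffset"), dir, "lab")

  med <- obs[obs$concept %in% c("ins", "abx")]
  med <- data.table(patientunitstayid = med$icustay_id,
                    drugstartoffset = med$rel_time,
                    drugcode = ifelse(med$concept == "ins", "INS", "ABX"),
                    dose = med$value, doseunit = med$unit)
  write_csv(med, dir, "medication")

  mb <- obs[obs$concept == "samp"]
  mb <- data.table(patientunitstayid = mb$icustay_id,
                   culturetakenoffset = mb$rel_time,
                   culturesite = "blood")
  write_csv(mb, dir, "microlab")

  vt <- data.table(patientunitstayid = truth$vent$icustay_id,
                   ventstartoffset = truth$vent$start_rel,
                   ventduration = truth$vent$dur,
                   ventmode = truth$vent$mode)
  write_csv(vt, dir, "vent")

  dg <- merge(truth$diag, unique(st[, c("hadm_id", "icustay_id")]),
              by = "hadm_id", allow.cartesian = TRUE)
  dg <- data.table(patientunitstayid = dg$icustay_id,
                   icd9code = dg$icd9_code)
  write_csv(dg, dir, "diagnosis")

  misc <- data.table(patientunitstayid = integer(), offset = integer(),
                     conceptcode = character(), value = numeric(),
                     unit = character())
  write_csv(misc, dir, "misc")

  parse_source_config(list(
    name = "wide_relative", time_mode = "relative",
    id_systems = list(
      list(name = "icustay", id_column = "patientunitstayid",
           origin_table = "unitstays", start_column = "unitadmitoffset",
           end_column = "unitdischargeoffset", rank = 1L)),
    tables = list(
      tbl_def("unitstays",
              c(patientunitstayid = "id", unitadmitoffset = "timestamp",
                unitdischargeoffset = "timestamp", age = "number",
                sex = "string", deathoffset = "timestamp"),
              list(id_column = "patientunitstayid")),
      tbl_def("vitalperiodic",
              c(patientunitstayid = "id", observationoffset = "timestamp",
                heartrate = "number", map = "number"),
              list(id_column = "patientunitstayid",
                   index_column = "observationoffset")),
      tbl_def("nursecharting",
              c(patientunitstayid = "id", nursingchartoffset = "timestamp",
                egcs = "number", vgcs = "number", mgcs = "number"),
              list(id_column = "patientunitstayid",
                   index_column = "nursingchartoffset")),
      tbl_def("lab",
              c(patientunitstayid = "id", labresultoffset = "timestamp",
                lact = "number", bili = "number", plt = "number",
                crea = "number"),
              list(id_column = "patientunitstayid",
                   index_column = "labresultoffset")),
      tbl_def("medication",
              c(patientunitstayid = "id", drugstartoffset = "timestamp",
                drugcode = "string", dose = "number", doseunit = "string"),
              list(id_column = "patientunitstayid",
                   index_column = "drugstartoffset",
                   value_column = "dose", unit_column = "doseunit")),
      tbl_def("microlab",
              c(patientunitstayid = "id", culturetakenoffset = "timestamp",
                culturesite = "string"),
              list(id_column = "patientunitstayid",
                   index_column = "culturetakenoffset",
                   value_column = "culturesite")),
      tbl_def("vent",
              c(patientunitstayid = "id", ventstartoffset = "timestamp",
                ventduration = "duration", ventmode = "string"),
              list(id_column = "patientunitstayid",
                   index_column = "ventstartoffset",
                   value_column = "ventmode", dur_column = "ventduration")),
      tbl_def("diagnosis",
              c(patientunitstayid = "id", icd9code = "string"),
              list(id_column = "patientunitstayid",
                   value_column = "icd9code")),
      tbl_def("misc",
              c(patientunitstayid = "id", offset = "timestamp",
                conceptcode = "string", value = "number", unit = "string"),
              list(id_column = "patientunitstayid", index_column = "offset",
                   value_column = "value", unit_column = "unit")))))
}

render_eav_relative <- function(truth, dir) {
  st <- truth$stays
  obs <- copy(truth$obs)
  codes <- synth_codes$eav_relative
  adm <- st[, list(admissionid = icustay_id, admittedat = 0L,
                   dischargedat = icu_end - icu_start, age = age,
                   sex = sex,
                   dateofdeath = ifelse(is.na(death_time), NA_integer_,
                                        death_time - icu_start))]
  write_csv(adm, dir, "admissions")

  ev_concepts <- c("hr", "map", "egcs", "vgcs", "mgcs", "lact", "bili",
                   "plt", "crea")
  ev <- obs[obs$concept %in% ev_concepts]
  value <- ev$value
  unit <- ev$unit
  ## creatinine reported in umol/L in this dialect
  cr <- ev$concept == "crea"
  value[cr] <- value[cr] * 88.42
  unit[cr] <- "umol/l"
  unit[ev$concept == "hr"] <- "/min"
  ev <- data.table(admissionid = ev$icustay_id, measuredat = ev$rel_time,
                   itemid = as.integer(unlist(codes[ev$concept])),
                   value = value, unit = unit)
  write_csv(ev, dir, "events")

  ph <- obs[obs$concept %in% c("ins", "abx")]
  ph <- data.table(admissionid = ph$icustay_id, start = ph$rel_time,
                   itemid = as.integer(unlist(codes[ph$concept])),
                   dose = ph$value, doseunit = ph$unit)
  write_csv(ph, dir, "pharma")

  mb <- obs[obs$concept == "samp"]
  mb <- data.table(admissionid = mb$icustay_id, takenat = mb$rel_time,
                   site = "blood")
  write_csv(mb, dir, "culture")

  vt <- data.table(admissionid = truth$vent$icustay_id,
                   start = truth$vent$start_rel,
                   duration = truth$vent$dur, mode = truth$vent$mode)
  write_csv(vt, dir, "vent")

  dg <- merge(truth$diag, unique(st[, c("hadm_id", "icustay_id")]),
              by = "hadm_id", allow.cartesian = TRUE)
  dg <- data.table(admissionid = dg$icustay_id, icd9code = dg$icd9_code)
  write_csv(dg, dir, "diagnosis")

  parse_source_config(list(
    name = "eav_relative", time_mode = "relative",
    id_systems = list(
      list(name = "icustay", id_column = "admissionid",
           origin_table = "admissions", start_column = "admittedat",
           end_column = "dischargedat", rank = 1L)),
    tables = list(
      tbl_def("admissions",
              c(admissionid = "id", admittedat = "timestamp",
                dischargedat = "timestamp", age = "number", sex = "string",
                dateofdeath = "timestamp"),
              list(id_column = "admissionid")),
      tbl_def("events",
              c(admissionid = "id", measuredat = "timestamp",
                itemid = "string", value = "number", unit = "string"),
              list(id_column = "admissionid", index_column = "measuredat",
                   value_column = "value", unit_column = "unit")),
      tbl_def("pharma",
              c(admissionid = "id", start = "timestamp", itemid = "string",
                dose = "number", doseunit = "string"),
              list(id_column = "admissionid", index_column = "start",
                   value_column = "dose", unit_column = "doseunit")),
      tbl_def("culture",
              c(admissionid = "id", takenat = "timestamp",
                site = "string"),
              list(id_column = "admissionid", index_column = "takenat",
                   value_column = "site")),
      tbl_def("vent",
              c(admissionid = "id", start = "timestamp",
                duration = "duration", mode = "string"),
              list(id_column = "admissionid", index_column = "start",
                   value_column = "mode", dur_column = "duration")),
      tbl_def("diagnosis",
              c(admissionid = "id", icd9code = "string"),
              list(id_column = "admissionid", value_column = "icd9code")))))
}
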