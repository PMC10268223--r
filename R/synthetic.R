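## Synthetic ICU cohort: a ground-truth generator plus renderers that
## write the same cohort into three schema dialects, emulating the
## structural heterogeneity of real ICU databases (nested vs. flat
## identifier systems, absolute vs. admission-relative timestamps, long
## entity-attribute-value vs. wide periodic layouts). Not a physiology
## simulator: signals are simple noise processes with planted features
## (out-of-bounds artifacts, measurement gaps, a sustained platelet
## drop at sepsis onset) whose exact values are recorded so they serve
## as a test oracle.

synth_epoch <- 21024000L  # minutes: 2010-01-01T00:00:00 UTC

## plausibility bounds mirrored by the oracle (kept in the generator so
## truth_lookup() stays independent of the dictionary / load pipeline)
truth_bounds <- list(
  hr = c(0, 300), map = c(0, 250), lact = c(0, 50), bili = c(0, 100),
  plt = c(0, 2000), crea = c(0, 50), egcs = c(1, 4), vgcs = c(1, 5),
  mgcs = c(1, 6), ins = c(0, 1000))

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a ground-truth ICU cohort
#'
#' Produces a deterministic synthetic cohort: patients with nested
#' hospital and ICU stays (at least one patient has two ICU stays
#' within one hospital stay, to exercise identifier-conversion
#' ambiguity), and per-stay planted signals: hourly heart rate with
#' ~1% out-of-bounds artifacts (350 bpm), hourly mean arterial
#' pressure, 6-hourly lactate with random gaps, daily bilirubin /
#' platelets / creatinine, 4-hourly GCS components, insulin
#' administrations in the first 36 h, antibiotic + culture-sampling
#' events and a sustained platelet drop at a planted sepsis onset for
#' septic patients, mechanical-ventilation windows, ICD-9 diagnosis
#' codes, and an in-ICU death time for non-survivors. Every planted
#' value is recorded exactly, so [truth_lookup()] can serve as an
#' oracle for the harmonization pipeline.
#'
#' All observation times fall inside ICU stay windows; deaths occur
#' within the final ICU stay.
#'
#' @param seed Integer RNG seed; the result is a pure function of
#'   `(seed, n_patients)` and the rate parameters.
#' @param n_patients Number of patients (`>= 1`).
#' @param p_death,p_septic,p_diab,p_ins,p_vent Event probabilities.
#' @param artifact_rate Fraction of heart-rate rows replaced by an
#'   out-of-bounds artifact.
#' @return A `cohort_truth` list: `stays`, `obs`, `vent`, `diag`,
#'   `sep3_truth` tables plus the parameters.
#' @export
generate_cohort <- function(seed, n_patients, p_death = 0.2,
                            p_septic = 0.25, p_diab = 0.25, p_ins = 0.5,
                            p_vent = 0.3, artifact_rate = 0.01) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop("`n_patients` must be at least 1", call. = FALSE)
  }
  n_patients <- as.integer(n_patients)
  with_local_seed(as.integer(seed), {
    stays <- list(); obs <- list(); vent <- list(); diag <- list()
    sep3_truth <- list()
    hadm_ct <- 0L; icu_ct <- 0L
    for (p in seq_len(n_patients)) {
      pid <- 1000L + p
      age <- round(runif(1, 18, 95))
      sex <- sample(c("Male", "Female"), 1L)
      dies <- runif(1) < p_death
      septic <- runif(1) < p_septic
      diabetic <- runif(1) < p_diab
      ## patient 1 always has one hospital stay with two ICU stays
      n_hosp <- if (p == 1L) 1L else if (runif(1) < 0.1) 2L else 1L
      t0 <- synth_epoch + as.integer(round(runif(1, 0, 3 * 365))) * 1440L
      for (h in seq_len(n_hosp)) {
        hadm_ct <- hadm_ct + 1L
        hid <- 200000L + hadm_ct
        hs <- t0
        two_icu <- (p == 1L && h == 1L) ||
          (p > 1L && runif(1) < 0.15)
        n_icu <- if (two_icu) 2L else 1L
        icu_prev_end <- hs + as.integer(round(runif(1, 2, 20))) * 60L
        hstays <- list()
        for (k in seq_len(n_icu)) {
          icu_ct <- icu_ct + 1L
          iid <- 300000L + icu_ct
          is_last <- h == n_hosp && k == n_icu
          st_septic <- septic && is_last
          los <- if (st_septic) {
            as.integer(round(runif(1, 96, 144))) * 60L  # 4-6 days
          } else {
            as.integer(round(runif(1, 24, 96))) * 60L   # 1-4 days
          }
          icu_s <- icu_prev_end + if (k == 1L) 0L else
            as.integer(round(runif(1, 12, 48))) * 60L
          icu_e <- icu_s + los
          death_t <- NA_integer_
          if (dies && is_last) {
            death_t <- icu_s + as.integer(floor(los * runif(1, 0.6, 0.9) /
                                                  60)) * 60L
            icu_e <- death_t + 120L
            los <- icu_e - icu_s
          }
          icu_prev_end <- icu_e
          onset <- NA_integer_
          if (st_septic) onset <- 48L * 60L
          sig <- gen_stay_signals(iid, hid, pid, icu_s, los, st_septic,
                                  onset, artifact_rate)
          obs[[length(obs) + 1L]] <- sig
          if (st_septic) {
            obs[[length(obs) + 1L]] <- data.table(
              concept = c("abx", "samp"), icustay_id = iid, hadm_id = hid,
              patient_id = pid, rel_time = c(onset, onset + 180L),
              value = 1, unit = NA_character_, artifact = FALSE)
            sep3_truth[[length(sep3_truth) + 1L]] <- data.table(
              icustay_id = iid, onset_rel = onset, label_rel = onset)
          }
          if (runif(1) < p_ins) {
            n_ev <- sample(1:5, 1L)
            tt <- sort(sample(seq_len(min(36L * 60L, los) - 1L), n_ev))
            obs[[length(obs) + 1L]] <- data.table(
              concept = "ins", icustay_id = iid, hadm_id = hid,
              patient_id = pid, rel_time = as.integer(tt),
              value = sample(1:12, n_ev, replace = TRUE),
              unit = "units", artifact = FALSE)
          }
          if (runif(1) < p_vent) {
            vs <- as.integer(round(runif(1, 0, los / 2)))
            vd <- as.integer(round(runif(1, 300, min(3000, los - vs))))
            vent[[length(vent) + 1L]] <- data.table(
              icustay_id = iid, start_rel = vs, dur = max(vd, 0L),
              mode = "invasive")
          }
          hstays[[length(hstays) + 1L]] <- data.table(
            patient_id = pid, hadm_id = hid, icustay_id = iid,
            icu_start = icu_s, icu_end = icu_e, death_time = death_t,
            age = age, sex = sex, septic = st_septic)
        }
        he <- icu_prev_end + as.integer(round(runif(1, 12, 72))) * 60L
        codes <- sample(c("4019", "41401", "5849", "2501", "V250"),
                        sample(1:3, 1L))
        if (diabetic) {
          codes <- c(codes, sample(c("25012", "250.01", "25002"), 1L))
        }
        diag[[length(diag) + 1L]] <- data.table(
          patient_id = pid, hadm_id = hid, icd9_code = codes)
        hh <- rbindlist(hstays)
        hh$hadm_start <- min(hh$icu_start) - 6L * 60L
        hh$hadm_end <- he
        stays[[length(stays) + 1L]] <- hh
        t0 <- he + as.integer(round(runif(1, 30, 200))) * 1440L
      }
    }
    structure(list(
      seed = as.integer(seed), n_patients = n_patients,
      stays = rbindlist(stays, fill = TRUE),
      obs = rbindlist(obs, fill = TRUE),
      vent = if (length(vent)) rbindlist(vent) else
        data.table(icustay_id = integer(), start_rel = integer(),
                   dur = integer(), mode = character()),
      diag = rbindlist(diag),
      sep3_truth = if (length(sep3_truth)) rbindlist(sep3_truth) else
        data.table(icustay_id = integer(), onset_rel = integer(),
                   label_rel = integer()),
      params = list(p_death = p_death, p_septic = p_septic,
                    p_diab = p_diab, p_ins = p_ins, p_vent = p_vent,
                    artifact_rate = artifact_rate)),
      class = "cohort_truth")
  })
}

## per-stay signal battery; septic stays get benign flat baselines so
## the planted platelet drop is the only SOFA movement in the Sepsis-3
## window, making the expected label hour exact
gen_stay_signals <- function(iid, hid, pid, icu_s, los, septic, onset,
                             artifact_rate) {
  out <- list()
  emit <- function(concept, rel, value, unit, artifact = FALSE) {
    if (length(rel) == 0L) return(invisible(NULL))
    out[[length(out) + 1L]] <<- data.table(
      concept = concept, icustay_id = iid, hadm_id = hid, patient_id = pid,
      rel_time = as.integer(rel), value = as.numeric(value), unit = unit,
      artifact = artifact)
  }
  vt <- seq(0L, los - 1L, by = 60L)
  hr <- round(rnorm(length(vt), 85, 10))
  art <- runif(length(vt)) < artifact_rate
  hr[art] <- 350
  emit("hr", vt, hr, "bpm", art)
  map <- if (septic) round(rnorm(length(vt), 85, 3), 1) else
    round(rnorm(length(vt), 78, 12), 1)
  emit("map", vt, pmax(map, 20), "mmHg")
  lt <- seq(0L, los - 1L, by = 360L)
  lt <- lt[runif(length(lt)) < 0.7]
  emit("lact", lt, round(pmax(0.4, rnorm(length(lt), 1.8, 0.8)), 1),
       "mmol/L")
  dt <- seq(60L, los - 1L, by = 1440L)
  emit("bili", dt, if (septic) rep(0.5, length(dt)) else
    round(pmax(0.2, rnorm(length(dt), 0.9, 0.5)), 1), "mg/dL")
  emit("crea", dt, if (septic) rep(0.8, length(dt)) else
    round(pmax(0.3, rnorm(length(dt), 1.0, 0.4)), 2), "mg/dL")
  if (septic) {
    pre <- dt[dt < onset]
    post <- dt[dt >= onset]
    emit("plt", pre, rep(250, length(pre)), "K/uL")
    emit("plt", onset, 45, "K/uL")
    emit("plt", post, pmax(20, round(rnorm(length(post), 42, 3))), "K/uL")
  } else {
    emit("plt", dt, round(pmax(60, rnorm(length(dt), 240, 60))), "K/uL")
  }
  gt <- seq(0L, los - 1L, by = 240L)
  if (septic) {
    emit("egcs", gt, rep(4, length(gt)), NA_character_)
    emit("vgcs", gt, rep(5, length(gt)), NA_character_)
    emit("mgcs", gt, rep(6, length(gt)), NA_character_)
  } else {
    emit("egcs", gt, sample(3:4, length(gt), TRUE, prob = c(0.2, 0.8)),
         NA_character_)
    emit("vgcs", gt, sample(4:5, length(gt), TRUE, prob = c(0.2, 0.8)),
         NA_character_)
    emit("mgcs", gt, sample(5:6, length(gt), TRUE, prob = c(0.2, 0.8)),
         NA_character_)
  }
  rbindlist(out)
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf(paste0("<cohort_truth> seed %d: %d patients, %d ICU stays, ",
                     "%d observations\n"),
              x$seed, x$n_patients, nrow(x$stays), nrow(x$obs)))
  invisible(x)
}

#' Oracle: expected harmonized series for a planted concept
#'
#' Computes, independently of the loading pipeline, the series that
#' harmonization is expected to produce for one ICU stay: plausibility
#' bounds applied to the planted raw values, times binned onto the
#' grid by floor division, and the concept's declared aggregation
#' applied per bin (median for numerics, sum-then-bin for `ins24`,
#' any-code-match for `diab`).
#'
#' @param truth A `cohort_truth`.
#' @param concept_name One of the planted concepts: `"hr"`, `"map"`,
#'   `"lact"`, `"bili"`, `"plt"`, `"crea"`, `"egcs"`, `"vgcs"`,
#'   `"mgcs"`, `"ins"`, `"death"`, `"ins24"`, `"diab"`, `"age"`,
#'   `"sex"`.
#' @param id_value An `icustay_id` of the cohort.
#' @param interval Grid step in minutes.
#' @return For time-stamped concepts a `data.table(time, value)`
#'   ordered by time; for static concepts a single value (`ins24`: the
#'   bin label; `diab`: logical; `death` of a survivor: empty table).
#' @export
truth_lookup <- function(truth, concept_name, id_value, interval = 60L) {
  stopifnot(inherits(truth, "cohort_truth"))
  st <- truth$stays[truth$stays$icustay_id == id_value]
  if (nrow(st) == 0L) {
    stop("unknown icustay id ", id_value, call. = FALSE)
  }
  bin <- function(t) as.integer(floor(t / interval) * interval)
  if (concept_name %in% names(truth_bounds)) {
    o <- truth$obs[truth$obs$concept == concept_name &
                     truth$obs$icustay_id == id_value]
    b <- truth_bounds[[concept_name]]
    o <- o[o$value >= b[1] & o$value <= b[2]]
    if (nrow(o) == 0L) {
      return(data.table(time = integer(), value = numeric()))
    }
    agg <- if (concept_name == "ins") sum else median
    grp <- split(o$value, bin(o$rel_time))
    res <- data.table(time = as.integer(names(grp)),
                      value = vapply(grp, agg, numeric(1)))
    return(res[order(res$time)])
  }
  switch(concept_name,
    death = {
      if (is.na(st$death_time)) {
        data.table(time = integer(), value = logical())
      } else {
        data.table(time = bin(st$death_time - st$icu_start), value = TRUE)
      }
    },
    ins24 = {
      o <- truth$obs[truth$obs$concept == "ins" &
                       truth$obs$icustay_id == id_value]
      tb <- bin(o$rel_time)
      keep <- tb >= 0L & tb <= 24L * 60L
      if (!any(keep)) return(NA_character_)
      total <- sum(o$value[keep])
      as.character(cut(total, breaks = c(0, 1, 10, 20, 40, Inf),
                       right = FALSE))
    },
    diab = {
      codes <- truth$diag[truth$diag$hadm_id == st$hadm_id]$icd9_code
      any(grepl("^250\\.?[0-9]{2}$", codes))
    },
    mech_vent = {
      v <- truth$vent[truth$vent$icustay_id == id_value]
      data.table(time = bin(v$start_rel), dur = as.numeric(v$dur),
                 value = v$mode)
    },
    age = st$age,
    sex = st$sex,
    stop("concept `", concept_name, "` was not planted by the generator",
         call. = FALSE)
  )
}
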