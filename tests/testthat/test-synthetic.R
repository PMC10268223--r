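test_that("cohort generation is deterministic and validates its invariants", {
  expect_error(generate_cohort(1, 0), "at least 1")

  t1 <- generate_cohort(1, 1)
  expect_gte(nrow(t1$stays), 1L)

  a <- generate_cohort(1, 50)
  b <- generate_cohort(1, 50)
  expect_equal(a, b)

  st <- a$stays
  ## ICU stays nested within their hospital stay
  expect_true(all(st$icu_start >= st$hadm_start &
                    st$icu_end <= st$hadm_end))
  ## stays of one patient do not overlap
  by_pat <- split(st, st$patient_id)
  for (s in by_pat) {
    s <- s[order(s$icu_start)]
    if (nrow(s) > 1L) {
      expect_true(all(s$icu_start[-1] >= s$icu_end[-nrow(s)]))
    }
  }
  ## at least one patient with two ICU stays in one hospital stay
  multi <- st[, .N, by = c("patient_id", "hadm_id")]
  expect_gte(max(multi$N), 2L)
  ## death, when present, within the stay window
  d <- st[!is.na(st$death_time)]
  expect_true(all(d$death_time >= d$icu_start &
                    d$death_time < d$icu_end))
})

test_that("out-of-bounds heart-rate artifacts are planted", {
  truth <- generate_cohort(2, 50)
  hr <- truth$obs[truth$obs$concept == "hr"]
  expect_gte(sum(hr$value > 300), 1L)
  expect_true(all(hr$artifact[hr$value > 300]))
})

test_that("all observations fall inside their ICU stay windows", {
  truth <- generate_cohort(3, 20)
  m <- merge(truth$obs, truth$stays[, c("icustay_id", "icu_start",
                                        "icu_end")],
             by = "icustay_id")
  expect_true(all(m$rel_time >= 0 &
                    m$rel_time < m$icu_end - m$icu_start))
})

test_that("renderings carry the same observation multiset", {
  fx <- get_fixture()
  truth <- fx$truth
  ## heart rate in the EAV-absolute rendering: codes 211/220045 only,
  ## values recoverable as the planted multiset
  ce <- src_table(fx$handles$eav_absolute, "chartevents")
  hr_rows <- ce[ce$itemid %in% c("211", "220045")]
  expect_setequal(unique(hr_rows$itemid), c("211", "220045"))
  planted <- truth$obs[truth$obs$concept == "hr"]
  expect_identical(nrow(hr_rows), nrow(planted))
  expect_equal(sort(hr_rows$value), sort(planted$value))

  ## same multiset in the wide rendering
  vp <- src_table(fx$handles$wide_relative, "vitalperiodic")
  expect_equal(sort(vp$heartrate[!is.na(vp$heartrate)]),
               sort(planted$value))

  ## deaths appear as timestamp rows in the absolute rendering
  adm <- src_table(fx$handles$eav_absolute, "admissions")
  expect_identical(sum(!is.na(adm$deathtime)),
                   length(unique(truth$stays[
                     !is.na(truth$stays$death_time)]$hadm_id)))
})

test_that("truth_lookup applies bounds, binning and aggregation", {
  truth <- generate_cohort(2, 50)
  hr <- truth$obs[truth$obs$concept == "hr"]
  art_stay <- hr$icustay_id[hr$value > 300][1L]
  series <- truth_lookup(truth, "hr", art_stay)
  expect_true(all(series$value <= 300))

  ## a survivor has an empty death series
  surv <- truth$stays$icustay_id[is.na(truth$stays$death_time)][1L]
  expect_identical(nrow(truth_lookup(truth, "death", surv)), 0L)

  expect_error(truth_lookup(truth, "xyz", surv), "not planted")
  expect_error(truth_lookup(truth, "hr", -1), "unknown icustay")
})

test_that("first-day insulin totals bin per the left-closed breaks", {
  ## 3 units + 9 units within the first day: total 12 -> [10,20)
  truth <- generate_cohort(4, 30)
  ins <- truth$obs[truth$obs$concept == "ins"]
  ## the first-day filter acts on the hourly-binned index, as in the
  ## harmonized output (a raw time of 1470 min bins to hour 24)
  binned <- floor(ins$rel_time / 60) * 60
  keep <- binned >= 0 & binned <= 24 * 60
  tot <- tapply(ins$value[keep], ins$icustay_id[keep], sum)
  for (sid in names(tot)) {
    expected <- as.character(cut(tot[[sid]],
                                 breaks = c(0, 1, 10, 20, 40, Inf),
                                 right = FALSE))
    expect_identical(truth_lookup(truth, "ins24", as.integer(sid)),
                     expected)
  }
  ## the documented example: sums of 3 and 9 fall in [10,20)
  expect_identical(
    as.character(cut(3 + 9, c(0, 1, 10, 20, 40, Inf), right = FALSE)),
    "[10,20)")
})

test_that("unknown dialects and unwritable directories are rejected", {
  truth <- generate_cohort(5, 2)
  expect_error(render_source(truth, "parquet", tempdir()),
               "unknown dialect")
  ro <- file.path(tempdir(), "ro_dir")
  dir.create(ro, showWarnings = FALSE)
  Sys.chmod(ro, "0555")
  on.exit(Sys.chmod(ro, "0755"))
  if (file.access(ro, 2L) != 0L) {
    expect_error(render_source(truth, "eav_absolute", ro),
                 "not writable|cannot create")
  }
})
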