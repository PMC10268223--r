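mk_series <- function(times, values, var, id = 1L) {
  if (length(times) == 0L) id <- integer()
  d <- data.frame(id = id, t = as.integer(times), v = values)
  names(d)[3] <- var
  ts_tbl(d, id_vars = "id", index_var = "t", interval = 60)
}

test_that("SOFA component thresholds follow the shipped rule table", {
  rules <- list(
    coagulation = list(c(45, 3), c(19, 4), c(20, 3), c(99, 2), c(149, 1),
                       c(150, 0), c(400, 0)),
    liver = list(c(1.0, 0), c(1.2, 1), c(1.9, 1), c(2.0, 2), c(5.9, 2),
                 c(6.0, 3), c(11.9, 3), c(12, 4)),
    renal = list(c(1.0, 0), c(1.2, 1), c(2.2, 2), c(3.5, 3), c(5, 4)),
    cns = list(c(15, 0), c(14, 1), c(13, 1), c(12, 2), c(10, 2), c(9, 3),
               c(6, 3), c(5, 4), c(3, 4)))
  for (comp in names(rules)) {
    r <- sofa_rule(comp)
    for (case in rules[[comp]]) {
      expect_identical(as.integer(r$score(case[1])), as.integer(case[2]),
                       info = paste(comp, case[1]))
    }
  }
  ## respiratory: unventilated scores cap at 2
  rr <- sofa_rule("respiratory")
  expect_identical(as.integer(rr$score(420)), 0L)
  expect_identical(as.integer(rr$score(350)), 1L)
  expect_identical(as.integer(rr$score(250)), 2L)
  expect_identical(as.integer(rr$score(150)), 2L)
  expect_identical(as.integer(rr$score(150, vent = TRUE)), 3L)
  expect_identical(as.integer(rr$score(80, vent = TRUE)), 4L)
  ## cardiovascular: MAP and vasopressor tiers
  rc <- sofa_rule("cardiovascular")
  expect_identical(as.integer(rc$score(75)), 0L)
  expect_identical(as.integer(rc$score(60)), 1L)
  expect_identical(as.integer(rc$score(60, dopa = 3)), 2L)
  expect_identical(as.integer(rc$score(60, dobu = 5)), 2L)
  expect_identical(as.integer(rc$score(60, dopa = 7)), 3L)
  expect_identical(as.integer(rc$score(60, norepi = 0.05)), 3L)
  expect_identical(as.integer(rc$score(60, norepi = 0.2)), 4L)
  expect_identical(as.integer(rc$score(60, dopa = 20)), 4L)
})

test_that("component scoring uses the trailing 24-hour worst value", {
  ## platelets recover after hour 10, but the 24 h window still sees 45
  s <- mk_series(c(0, 600, 1800) , c(250, 45, 200), "plt")
  out <- sofa_component(s, sofa_rule("coagulation"))
  expect_identical(out$plt, c(0L, 3L, 3L))
})

test_that("the hand-built patient scores the hand-computed component sum", {
  t24 <- 24 * 60
  comps <- list(
    sofa_coag = sofa_component(mk_series(t24, 45, "plt"),
                               sofa_rule("coagulation")),
    sofa_liver = sofa_component(mk_series(t24, 3.0, "bili"),
                                sofa_rule("liver")),
    sofa_cardio = sofa_component(mk_series(t24, 60, "map"),
                                 sofa_rule("cardiovascular")),
    sofa_cns = sofa_component(mk_series(t24, 14, "gcs"),
                              sofa_rule("cns")),
    sofa_renal = sofa_component(mk_series(t24, 2.2, "crea"),
                                sofa_rule("renal")),
    sofa_resp = sofa_component(mk_series(t24, 350, "pafi"),
                               sofa_rule("respiratory")))
  ## platelets 45 -> 3, bilirubin 3.0 -> 2, MAP 60 (no vasopressors)
  ## -> 1, GCS 14 -> 1, creatinine 2.2 -> 2, PaO2/FiO2 350 -> 1
  expect_identical(vapply(comps, function(x) as.integer(x[[3]][1]),
                          integer(1)),
                   c(sofa_coag = 3L, sofa_liver = 2L, sofa_cardio = 1L,
                     sofa_cns = 1L, sofa_renal = 2L, sofa_resp = 1L))
  total <- sofa(comps)
  expect_identical(total$sofa, 3L + 2L + 1L + 1L + 2L + 1L)
  ## a normal patient scores zero
  normal <- list(
    sofa_coag = sofa_component(mk_series(0, 250, "plt"),
                               sofa_rule("coagulation")),
    sofa_liver = sofa_component(mk_series(0, 0.5, "bili"),
                                sofa_rule("liver")))
  expect_identical(sofa(normal)$sofa, 0L)
})

test_that("missing components contribute zero to the total", {
  comps <- list(
    sofa_coag = sofa_component(mk_series(0, 45, "plt"),
                               sofa_rule("coagulation")),
    sofa_liver = mk_series(integer(), numeric(), "bili"))
  expect_identical(sofa(comps)$sofa, 3L)
})

test_that("worsening one component never decreases the total", {
  set.seed(9)
  for (rep in 1:20) {
    plt1 <- runif(1, 10, 400)
    plt2 <- max(plt1 - runif(1, 0, 100), 1)
    base <- list(
      sofa_liver = sofa_component(mk_series(0, runif(1, 0.2, 15), "bili"),
                                  sofa_rule("liver")),
      sofa_renal = sofa_component(mk_series(0, runif(1, 0.4, 6), "crea"),
                                  sofa_rule("renal")))
    t1 <- sofa(c(base, list(sofa_coag = sofa_component(
      mk_series(0, plt1, "plt"), sofa_rule("coagulation")))))
    t2 <- sofa(c(base, list(sofa_coag = sofa_component(
      mk_series(0, plt2, "plt"), sofa_rule("coagulation")))))
    expect_gte(t2$sofa, t1$sofa)
  }
})

test_that("suspected-infection pairing windows behave as specified", {
  abx <- mk_series(10 * 60, TRUE, "abx")
  samp <- mk_series(20 * 60, TRUE, "samp")
  on1 <- susp_inf(abx, samp)
  expect_identical(on1$t, 600L)

  ## culture first, antibiotic 80 h later: outside the 72 h window
  abx2 <- mk_series(80 * 60, TRUE, "abx")
  samp2 <- mk_series(0, TRUE, "samp")
  expect_identical(nrow(susp_inf(abx2, samp2)), 0L)
  ## culture first, antibiotic 48 h later: onset at the culture
  abx3 <- mk_series(48 * 60, TRUE, "abx")
  expect_identical(susp_inf(abx3, samp2)$t, 0L)
  ## no antibiotics: empty
  expect_identical(nrow(susp_inf(mk_series(integer(), logical(), "abx"),
                                 samp)), 0L)
})

test_that("the Sepsis-3 label fires on a >= 2 point SOFA rise near onset", {
  sofa_tbl <- mk_series(c(0, 60, 120, 180), c(2, 2, 5, 5), "sofa")
  susp <- mk_series(60, TRUE, "susp_inf")
  lab <- sep3(sofa_tbl, susp)
  expect_identical(lab$t, 120L)
  expect_true(lab$sep3)

  flat <- mk_series(c(0, 60, 120), c(2, 2, 2), "sofa")
  expect_identical(nrow(sep3(flat, susp)), 0L)
})

test_that("planted septic patients are labelled at their planted onset", {
  fx <- get_fixture()
  truth <- fx$truth
  skip_if(nrow(truth$sep3_truth) == 0L)
  lab <- quiet_load("sep3", fx$handles$eav_absolute)
  got <- as.data.frame(lab)
  for (k in seq_len(nrow(truth$sep3_truth))) {
    sid <- truth$sep3_truth$icustay_id[k]
    expect_identical(got$time[got$icustay_id == sid],
                     truth$sep3_truth$label_rel[k])
  }
  ## no labels outside the planted set
  expect_setequal(got$icustay_id, truth$sep3_truth$icustay_id)
})

test_that("GCS is the sum of its components", {
  fx <- get_fixture()
  g <- quiet_load("gcs", fx$handles$eav_relative)
  parts <- quiet_load(c("egcs", "vgcs", "mgcs"), fx$handles$eav_relative)
  m <- merge(as.data.frame(g), as.data.frame(parts),
             by = c("admissionid", "time"))
  expect_equal(m$gcs, m$egcs + m$vgcs + m$mgcs)
})

test_that("ins24 sums the first day and bins left-closed", {
  ins <- mk_series(c(120, 300), c(3, 9), "ins")
  ctx <- list(name = "ins24", interval = 60L)
  out <- icuharm:::cb_ins24(list(ins = ins), ctx)
  expect_s3_class(out, "id_tbl")
  expect_identical(out$ins24, "[10,20)")

  edge <- icuharm:::cb_ins24(list(ins = mk_series(c(0, 25 * 60),
                                                  c(0.5, 100), "ins")),
                             ctx)
  expect_identical(edge$ins24, "[0,1)")
  hi <- icuharm:::cb_ins24(list(ins = mk_series(60, 45, "ins")), ctx)
  expect_identical(hi$ins24, "[40,Inf)")
})

test_that("diab equals direct regex evaluation over the diagnosis table", {
  fx <- get_fixture()
  h <- fx$handles$eav_relative
  got <- quiet_load("diab", h)
  dg <- src_table(h, "diagnosis")
  exp <- tapply(grepl("^250\\.?[0-9]{2}$", dg$icd9code),
                dg$admissionid, any)
  exp <- setNames(as.logical(exp), names(exp))
  got_v <- setNames(got$diab, got$admissionid)
  expect_identical(got_v[names(exp)], exp)
})
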