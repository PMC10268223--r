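## Recursive-concept callbacks: SOFA and its six organ components,
## suspected infection and the Sepsis-3 label, GCS, PaO2/FiO2, the
## first-24h insulin concept, and assorted derived scores. Callbacks
## receive a named list of dependency tables plus a context list
## (handle, id_type, interval, concept name, target).

ctx_id_col <- function(ctx) id_system(ctx$handle, ctx$id_type)$id_column

empty_result <- function(ctx, type = numeric(), kind = "ts_tbl") {
  idc <- ctx_id_col(ctx)
  dt <- data.table(id = integer(), time = integer(), value = type)
  setnames(dt, c("id", "value"), c(idc, ctx$name))
  if (identical(kind, "id_tbl")) {
    dt$time <- NULL
    return(id_tbl(dt, id_vars = idc))
  }
  ts_tbl(dt, id_vars = idc, index_var = "time", interval = ctx$interval)
}

## full outer merge of dependency tables followed by per-id LOCF, so a
## value measured at 08:00 still informs a score at 09:00
merge_locf <- function(deps, locf = TRUE) {
  out <- merge_concepts(unname(deps))
  if (locf && is_ts_tbl(out) && nrow(out) > 0L) {
    out <- replace_na(out, NA, type = "locf", vars = data_vars(out))
  }
  out
}

rename_value <- function(tb, from, to) {
  setnames(tb, from, to)
  tb
}

## ---- SOFA -------------------------------------------------------------

#' SOFA component scoring rules
#'
#' The standard Sequential Organ Failure Assessment thresholds, fixed
#' here: each organ system maps its canonical measurement to a score in
#' 0--4, monotone in severity. Scoring is applied to the worst value
#' over a trailing 24-hour window ([slide()]).
#'
#' @param component One of `"respiratory"`, `"coagulation"`, `"liver"`,
#'   `"cardiovascular"`, `"cns"`, `"renal"`.
#' @return A rule list with the component name, the direction of
#'   "worst" (`"min"` or `"max"`), and the elementwise scoring function.
#' @export
sofa_rule <- function(component) {
  switch(component,
    coagulation = list(component = component, worst = "min",
      score = function(plt) 4L - findInterval(plt, c(20, 50, 100, 150))),
    liver = list(component = component, worst = "max",
      score = function(bili) findInterval(bili, c(1.2, 2, 6, 12))),
    renal = list(component = component, worst = "max",
      score = function(crea) findInterval(crea, c(1.2, 2, 3.5, 5))),
    cns = list(component = component, worst = "min",
      score = function(gcs) 4L - findInterval(gcs, c(6, 10, 13, 15))),
    respiratory = list(component = component, worst = "min",
      score = function(pafi, vent = FALSE) {
        raw <- 4L - findInterval(pafi, c(100, 200, 300, 400))
        ifelse(raw >= 3L & !vent, 2L, raw)
      }),
    cardiovascular = list(component = component, worst = "min",
      score = function(map, dopa = 0, dobu = 0, epi = 0, norepi = 0) {
        s <- ifelse(map < 70, 1L, 0L)
        s <- pmax(s, ifelse((dopa > 0 & dopa <= 5) | dobu > 0, 2L, 0L))
        s <- pmax(s, ifelse(dopa > 5 | (epi > 0 & epi <= 0.1) |
                              (norepi > 0 & norepi <= 0.1), 3L, 0L))
        pmax(s, ifelse(dopa > 15 | epi > 0.1 | norepi > 0.1, 4L, 0L))
      }),
    stop("unknown SOFA component `", component, "`", call. = FALSE)
  )
}

#' Score one SOFA component series
#'
#' Applies the component's trailing 24-hour worst-value window and then
#' its threshold scoring, yielding a 0--4 score series. Inputs must be
#' in the component's canonical unit (platelets 10^3/uL, bilirubin and
#' creatinine mg/dL, MAP mmHg, vasopressor rates ug/kg/min).
#'
#' @param series A `ts_tbl` with a single value column.
#' @param rule A rule from [sofa_rule()] (only single-input components).
#' @param worst_win Window width in minutes (default 24 h).
#' @return A `ts_tbl` of integer scores.
#' @export
sofa_component <- function(series, rule, worst_win = 24L * 60L) {
  if (!is.null(attr(series, "unit_flags"))) {
    warning("SOFA ", rule$component,
            ": input carries unrecognized units", call. = FALSE)
  }
  if (nrow(series) == 0L) return(series)
  worst <- slide(series, before = worst_win, after = 0L, fun = rule$worst)
  v <- data_vars(worst)[1L]
  dt <- unwrap(worst)
  dt[[v]] <- as.integer(rule$score(dt[[v]]))
  rebuild(dt, tbl_meta(worst))
}

single_component_cb <- function(dep_name, component) {
  function(deps, ctx) {
    dep <- deps[[dep_name]]
    if (is.null(dep) || nrow(dep) == 0L) {
      return(empty_result(ctx, numeric()))
    }
    out <- sofa_component(dep, sofa_rule(component))
    rename_value(out, data_vars(out)[1L], ctx$name)
  }
}

cb_sofa_resp <- function(deps, ctx) {
  pafi <- deps[["pafi"]]
  if (is.null(pafi) || nrow(pafi) == 0L) return(empty_result(ctx))
  rule <- sofa_rule("respiratory")
  worst <- slide(pafi, before = 24L * 60L, after = 0L, fun = "min")
  vent <- deps[["vent_ind"]]
  dt <- unwrap(worst)
  v <- data_vars(worst)[1L]
  ventilated <- rep(FALSE, nrow(dt))
  if (!is.null(vent) && nrow(vent) > 0L) {
    key <- c(id_vars(worst), index_var(worst))
    vdt <- unwrap(vent)
    setnames(vdt, c(id_vars(vent), index_var(vent)), key)
    hit <- merge(dt[, key, with = FALSE], vdt, by = key, all.x = TRUE)
    ventilated <- !is.na(hit[[data_vars(vent)[1L]]]) &
      hit[[data_vars(vent)[1L]]] %in% TRUE
  }
  dt[[v]] <- as.integer(rule$score(dt[[v]], ventilated))
  rename_value(rebuild(dt, tbl_meta(worst)), v, ctx$name)
}

cb_sofa_cardio <- function(deps, ctx) {
  rule <- sofa_rule("cardiovascular")
  have <- Filter(function(d) !is.null(d) && nrow(d) > 0L, deps)
  if (length(have) == 0L) return(empty_result(ctx))
  worst <- lapply(names(deps), function(nm) {
    d <- deps[[nm]]
    if (is.null(d) || nrow(d) == 0L) return(NULL)
    slide(d, before = 24L * 60L, after = 0L,
          fun = if (nm == "map") "min" else "max")
  })
  names(worst) <- names(deps)
  m <- merge_locf(Filter(Negate(is.null), worst))
  dt <- unwrap(m)
  g <- function(nm, default) {
    if (nm %in% names(dt)) {
      v <- dt[[nm]]
      ifelse(is.na(v), default, v)
    } else {
      rep(default, nrow(dt))
    }
  }
  score <- rule$score(map = g("map", Inf), dopa = g("dopa_rate", 0),
                      dobu = g("dobu_rate", 0), epi = g("epi_rate", 0),
                      norepi = g("norepi_rate", 0))
  out <- dt[, c(id_vars(m), index_var(m)), with = FALSE]
  out[[ctx$name]] <- as.integer(score)
  ts_tbl(out, id_vars = id_vars(m), index_var = index_var(m),
         interval = interval(m))
}

#' Total SOFA score
#'
#' Sums the six organ-component scores on the common grid. At any time
#' point where a component has no score (no measurement in its trailing
#' 24-hour window), that component contributes 0 -- an explicit,
#' documented choice, since silent assumptions here are a known driver
#' of Sepsis-3 prevalence heterogeneity between implementations.
#'
#' @param components Named list of six component `ts_tbl`s.
#' @param name Output column name (default `"sofa"`).
#' @return A `ts_tbl` with the total score (0--24).
#' @export
sofa <- function(components, name = "sofa") {
  have <- Filter(function(d) !is.null(d) && nrow(d) > 0L, components)
  if (length(have) == 0L) {
    stop("sofa(): no component scores available", call. = FALSE)
  }
  m <- merge_concepts(unname(have))
  dt <- unwrap(m)
  comp_cols <- data_vars(m)
  total <- rowSums(as.matrix(dt[, comp_cols, with = FALSE]), na.rm = TRUE)
  out <- dt[, c(id_vars(m), index_var(m)), with = FALSE]
  out[[name]] <- as.integer(total)
  ts_tbl(out, id_vars = id_vars(m), index_var = index_var(m),
         interval = interval(m))
}

cb_sofa <- function(deps, ctx) {
  res <- tryCatch(sofa(deps, name = ctx$name), error = function(e) NULL)
  if (is.null(res)) return(empty_result(ctx)) else res
}

## ---- suspected infection and Sepsis-3 ---------------------------------

#' Suspected-infection onset
#'
#' Pairs antibiotic administrations with culture sampling: a pair
#' qualifies when the culture follows the antibiotic within
#' `samp_after` (default 24 h) or the antibiotic follows the culture
#' within `abx_after` (default 72 h). The onset is the earlier event of
#' the earliest qualifying pair per identifier.
#'
#' @param abx A `ts_tbl` of antibiotic administration flags.
#' @param sampling A `ts_tbl` of culture-sampling flags.
#' @param samp_after,abx_after Pairing windows in minutes.
#' @param name Output column name.
#' @return A `ts_tbl` with one `TRUE` row per identifier at its onset
#'   time (empty when nothing qualifies).
#' @export
susp_inf <- function(abx, sampling, samp_after = 24L * 60L,
                     abx_after = 72L * 60L, name = "susp_inf") {
  iv <- id_vars(abx)
  ix <- index_var(abx)
  adt <- unwrap(abx)
  sdt <- unwrap(sampling)
  if (nrow(sdt) > 0L) {
    setnames(sdt, c(id_vars(sampling), index_var(sampling)), c(iv, ix))
  }
  res <- data.table(id = integer(), time = integer(), value = logical())
  if (nrow(adt) > 0L && nrow(sdt) > 0L) {
    pairs <- merge(adt[, c(iv, ix), with = FALSE],
                   sdt[, c(iv, ix), with = FALSE],
                   by = iv, allow.cartesian = TRUE, suffixes = c(".a", ".s"))
    ta <- pairs[[paste0(ix, ".a")]]
    tsamp <- pairs[[paste0(ix, ".s")]]
    ok <- (tsamp >= ta & tsamp - ta <= samp_after) |
      (ta >= tsamp & ta - tsamp <= abx_after)
    pairs <- pairs[ok]
    if (nrow(pairs) > 0L) {
      pairs[, onset := pmin(get(paste0(ix, ".a")), get(paste0(ix, ".s")))]
      res <- pairs[, list(time = min(onset)), by = iv]
      res$value <- TRUE
    }
  }
  if (!iv %in% names(res)) setnames(res, "id", iv)
  setnames(res, c("time", "value"), c(ix, name))
  ts_tbl(res, id_vars = iv, index_var = ix, interval = interval(abx))
}

cb_susp_inf <- function(deps, ctx) {
  abx <- deps[["abx"]]
  samp <- deps[["samp"]]
  if (is.null(abx) || is.null(samp) || nrow(abx) == 0L) {
    return(empty_result(ctx, logical()))
  }
  susp_inf(abx, samp, name = ctx$name)
}

#' Sepsis-3 label
#'
#' A patient is labelled at the first time `t` in
#' `[onset - before, onset + after]` (default -48 h / +24 h around the
#' suspected-infection onset) at which the SOFA total has increased by
#' at least `delta` (default 2) over the minimum SOFA observed earlier
#' within the window.
#'
#' @param sofa_tbl A `ts_tbl` of SOFA totals.
#' @param susp A `ts_tbl` of suspected-infection onsets ([susp_inf()]).
#' @param delta Required SOFA increase.
#' @param before,after Window extent around the onset, minutes.
#' @param name Output column name.
#' @return A `ts_tbl` with one `TRUE` row per labelled identifier at
#'   the label time.
#' @export
sep3 <- function(sofa_tbl, susp, delta = 2L, before = 48L * 60L,
                 after = 24L * 60L, name = "sep3") {
  iv <- id_vars(sofa_tbl)
  ix <- index_var(sofa_tbl)
  sdt <- unwrap(sofa_tbl)
  setorderv(sdt, c(iv, ix))
  odt <- unwrap(susp)
  setnames(odt, c(id_vars(susp), index_var(susp)), c(iv, ix))
  sofa_col <- data_vars(sofa_tbl)[1L]
  rows <- list()
  for (k in seq_len(nrow(odt))) {
    pid <- odt[[iv]][k]
    onset <- odt[[ix]][k]
    s <- sdt[sdt[[iv]] == pid]
    s <- s[s[[ix]] >= onset - before & s[[ix]] <= onset + after]
    if (nrow(s) < 2L) next
    tt <- s[[ix]]
    vv <- s[[sofa_col]]
    for (j in 2L:length(tt)) {
      if (vv[j] - min(vv[1:(j - 1L)]) >= delta) {
        rows[[length(rows) + 1L]] <- data.table(id = pid, time = tt[j])
        break
      }
    }
  }
  res <- if (length(rows) > 0L) rbindlist(rows) else
    data.table(id = integer(), time = integer())
  res$value <- rep(TRUE, nrow(res))
  setnames(res, c("id", "time", "value"), c(iv, ix, name))
  ts_tbl(res, id_vars = iv, index_var = ix, interval = interval(sofa_tbl))
}

cb_sep3 <- function(deps, ctx) {
  sofa_tbl <- deps[["sofa"]]
  susp <- deps[["susp_inf"]]
  if (is.null(sofa_tbl) || nrow(sofa_tbl) == 0L || is.null(susp) ||
      nrow(susp) == 0L) {
    return(empty_result(ctx, logical()))
  }
  sep3(sofa_tbl, susp, name = ctx$name)
}

## ---- insulin in the first 24 h ----------------------------------------

ins_breaks <- c(0, 1, 10, 20, 40, Inf)

cb_ins24 <- function(deps, ctx) {
  ins <- deps[["ins"]]
  if (is.null(ins) || nrow(ins) == 0L) {
    return(empty_result(ctx, character(), kind = "id_tbl"))
  }
  idx <- index_var(ins)
  ids <- id_vars(ins)
  v <- data_vars(ins)[1L]
  dt <- unwrap(ins)
  day_one <- dt[[idx]] >= 0L & dt[[idx]] <= 24L * 60L
  dt <- dt[day_one, list(total = sum(.SD[[1L]], na.rm = TRUE)),
           by = ids, .SDcols = v]
  dt[[ctx$name]] <- as.character(cut(dt$total, breaks = ins_breaks,
                                     right = FALSE))
  dt$total <- NULL
  id_tbl(dt, id_vars = ids)
}

## ---- other recursive concepts -----------------------------------------

single_transform_cb <- function(dep_name, f) {
  function(deps, ctx) {
    d <- deps[[dep_name]]
    if (is.null(d) || nrow(d) == 0L) return(empty_result(ctx))
    dt <- unwrap(d)
    v <- data_vars(d)[1L]
    dt[[v]] <- f(dt[[v]])
    rename_value(rebuild(dt, tbl_meta(d)), v, ctx$name)
  }
}

ratio_cb <- function(num, den, scale = 100) {
  function(deps, ctx) {
    if (is.null(deps[[num]]) || is.null(deps[[den]]) ||
        nrow(deps[[num]]) == 0L || nrow(deps[[den]]) == 0L) {
      return(empty_result(ctx))
    }
    m <- merge_locf(deps[c(num, den)])
    dt <- unwrap(m)
    dt[[ctx$name]] <- dt[[num]] / (dt[[den]] / scale)
    dt[, c(num, den) := NULL]
    dt <- dt[!is.na(dt[[ctx$name]])]
    ts_tbl(dt, id_vars = id_vars(m), index_var = index_var(m),
           interval = interval(m))
  }
}

cb_gcs <- function(deps, ctx) {
  have <- Filter(function(d) !is.null(d) && nrow(d) > 0L, deps)
  if (length(have) == 0L) return(empty_result(ctx))
  m <- merge_locf(have)
  dt <- unwrap(m)
  comp <- data_vars(m)
  total <- rowSums(as.matrix(dt[, comp, with = FALSE]))
  out <- dt[, c(id_vars(m), index_var(m)), with = FALSE]
  out[[ctx$name]] <- as.numeric(total)
  out <- out[!is.na(out[[ctx$name]])]
  ts_tbl(out, id_vars = id_vars(m), index_var = index_var(m),
         interval = interval(m))
}

cb_bmi <- function(deps, ctx) {
  h <- deps[["height"]]
  w <- deps[["weight"]]
  if (is.null(h) || is.null(w) || nrow(h) == 0L || nrow(w) == 0L) {
    return(empty_result(ctx, numeric(), kind = "id_tbl"))
  }
  m <- merge_concepts(list(h, w))
  dt <- unwrap(m)
  dt[[ctx$name]] <- dt$weight / (dt$height / 100)^2
  dt[, c("height", "weight") := NULL]
  id_tbl(dt[!is.na(dt[[ctx$name]])], id_vars = id_vars(m))
}

cb_egfr <- function(deps, ctx) {
  crea <- deps[["crea"]]
  if (is.null(crea) || nrow(crea) == 0L) return(empty_result(ctx))
  m <- merge_concepts(unname(Filter(function(d) nrow(d) > 0L, deps)))
  dt <- unwrap(m)
  if (!"age" %in% names(dt)) dt$age <- NA_real_
  if (!"sex" %in% names(dt)) dt$sex <- NA_character_
  dt[[ctx$name]] <- 186 * dt$crea^-1.154 *
    ifelse(is.na(dt$age), 1, dt$age^-0.203) *
    ifelse(!is.na(dt$sex) & dt$sex == "Female", 0.742, 1)
  keep <- c(id_vars(m), index_var(m), ctx$name)
  out <- dt[!is.na(dt[[ctx$name]]), keep, with = FALSE]
  ts_tbl(out, id_vars = id_vars(m), index_var = index_var(m),
         interval = interval(m))
}

cb_urine24 <- function(deps, ctx) {
  u <- deps[["urine"]]
  if (is.null(u) || nrow(u) == 0L) return(empty_result(ctx))
  out <- slide(u, before = 24L * 60L, after = 0L, fun = "sum")
  rename_value(out, data_vars(out)[1L], ctx$name)
}

cb_vent_ind <- function(deps, ctx) {
  mv <- deps[["mech_vent"]]
  if (is.null(mv) || nrow(mv) == 0L) {
    return(empty_result(ctx, logical()))
  }
  x <- if (is_win_tbl(mv)) expand(mv) else mv
  dt <- unwrap(x)
  v <- data_vars(x)[1L]
  dt[[ctx$name]] <- !is.na(dt[[v]])
  dt[[v]] <- NULL
  dt <- unique(dt)
  ts_tbl(dt, id_vars = id_vars(x), index_var = index_var(x),
         interval = interval(x))
}

cb_vaso_ind <- function(deps, ctx) {
  have <- Filter(function(d) !is.null(d) && nrow(d) > 0L, deps)
  if (length(have) == 0L) return(empty_result(ctx, logical()))
  m <- merge_concepts(unname(have))
  dt <- unwrap(m)
  rates <- as.matrix(dt[, data_vars(m), with = FALSE])
  out <- dt[, c(id_vars(m), index_var(m)), with = FALSE]
  out[[ctx$name]] <- rowSums(rates > 0, na.rm = TRUE) > 0
  ts_tbl(out, id_vars = id_vars(m), index_var = index_var(m),
         interval = interval(m))
}

count_criteria_cb <- function(crit) {
  ## crit: named list dep -> function(value) logical
  function(deps, ctx) {
    have <- Filter(function(d) !is.null(d) && nrow(d) > 0L,
                   deps[names(crit)])
    if (length(have) == 0L) return(empty_result(ctx))
    m <- merge_locf(have)
    dt <- unwrap(m)
    score <- rep(0L, nrow(dt))
    for (nm in names(crit)) {
      if (nm %in% names(dt)) {
        hit <- crit[[nm]](dt[[nm]])
        score <- score + ifelse(is.na(hit), 0L, as.integer(hit))
      }
    }
    out <- dt[, c(id_vars(m), index_var(m)), with = FALSE]
    out[[ctx$name]] <- score
    ts_tbl(out, id_vars = id_vars(m), index_var = index_var(m),
           interval = interval(m))
  }
}

cb_qsofa <- count_criteria_cb(list(
  sbp = function(x) x <= 100,
  resp = function(x) x >= 22,
  gcs = function(x) x < 15))

cb_sirs <- count_criteria_cb(list(
  temp = function(x) x > 38 | x < 36,
  hr = function(x) x > 90,
  resp = function(x) x > 20,
  wbc = function(x) x > 12 | x < 4))

cb_mews <- count_criteria_cb(list(
  sbp = function(x) x <= 100 | x >= 200,
  hr = function(x) x <= 50 | x >= 100,
  resp = function(x) x < 9 | x >= 21,
  temp = function(x) x < 35 | x >= 38.5,
  avpu = function(x) !x %in% "A"))

cb_news <- count_criteria_cb(list(
  resp = function(x) x <= 11 | x >= 21,
  o2sat = function(x) x <= 95,
  temp = function(x) x <= 36 | x >= 38.1,
  sbp = function(x) x <= 110 | x >= 220,
  hr = function(x) x <= 50 | x >= 91))

cb_aki <- function(deps, ctx) {
  crea <- deps[["crea"]]
  if (is.null(crea) || nrow(crea) == 0L) {
    return(empty_result(ctx, logical()))
  }
  dt <- unwrap(crea)
  iv <- id_vars(crea)
  setorderv(dt, c(iv, index_var(crea)))
  v <- data_vars(crea)[1L]
  dt[, .base__ := cummin(ifelse(is.na(.SD[[1L]]), Inf, .SD[[1L]])),
     by = iv, .SDcols = v]
  dt[[ctx$name]] <- dt[[v]] >= 4 | dt[[v]] >= 1.5 * dt$.base__
  dt[, c(v, ".base__") := NULL]
  ts_tbl(dt, id_vars = iv, index_var = index_var(crea),
         interval = interval(crea))
}

windowed_rate_cb <- function(dep_name) {
  function(deps, ctx) {
    d <- deps[[dep_name]]
    if (is.null(d) || nrow(d) == 0L) return(empty_result(ctx))
    out <- slide(d, before = 60L, after = 0L, fun = "max")
    rename_value(out, data_vars(out)[1L], ctx$name)
  }
}

register_clinical_callbacks <- function() {
  reg <- function(nm, f) register_callback(nm, f, overwrite = TRUE)
  reg("ins_cb", cb_ins24)
  reg("gcs_cb", cb_gcs)
  reg("tgcs_cb", single_transform_cb("gcs", identity))
  reg("pafi_cb", ratio_cb("po2", "fio2", scale = 100))
  reg("safi_cb", ratio_cb("o2sat", "fio2", scale = 100))
  reg("egfr_cb", cb_egfr)
  reg("bmi_cb", cb_bmi)
  reg("urine24_cb", cb_urine24)
  reg("vent_ind_cb", cb_vent_ind)
  reg("vaso_ind_cb", cb_vaso_ind)
  reg("qsofa_cb", cb_qsofa)
  reg("sirs_cb", cb_sirs)
  reg("mews_cb", cb_mews)
  reg("news_cb", cb_news)
  reg("aki_cb", cb_aki)
  reg("sofa_coag_cb", single_component_cb("plt", "coagulation"))
  reg("sofa_liver_cb", single_component_cb("bili", "liver"))
  reg("sofa_renal_cb", single_component_cb("crea", "renal"))
  reg("sofa_cns_cb", single_component_cb("gcs", "cns"))
  reg("sofa_resp_cb", cb_sofa_resp)
  reg("sofa_cardio_cb", cb_sofa_cardio)
  reg("sofa_cb", cb_sofa)
  reg("susp_inf_cb", cb_susp_inf)
  reg("sep3_cb", cb_sep3)
  reg("vaso60_cb", windowed_rate_cb("norepi_rate"))
  reg("dopa60_cb", windowed_rate_cb("dopa_rate"))
  reg("norepi60_cb", windowed_rate_cb("norepi_rate"))
  invisible(NULL)
}
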