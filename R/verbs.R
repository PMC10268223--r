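#' Bin raw event times onto a regular grid
#'
#' Maps every time value onto the largest multiple of `interval` not
#' exceeding it (floor division, toward negative infinity), so that an
#' event 61 minutes after admission bins to 60 and an event 61 minutes
#' before admission bins to -120. Flooring toward negative infinity is
#' applied uniformly; pre-admission events therefore land on the grid
#' point at or before their true time.
#'
#' @param x A `ts_tbl`-like object (or a table plus `time_var`) whose
#'   index holds raw, un-binned minutes.
#' @param interval Positive grid step in minutes.
#' @param time_var Column holding raw times; defaults to the index.
#' @return A `ts_tbl` on the new grid (values are not aggregated; use
#'   [aggregate_by()] afterwards).
#' @examples
#' x <- ts_tbl(data.frame(id = 1, t = c(0, 61, -61), v = 1:3),
#'             id_vars = "id", index_var = "t", interval = 1)
#' bin_index(x, 60)
#' @export
bin_index <- function(x, interval, time_var = index_var(x)) {
  if (length(interval) != 1L || is.na(interval) || interval <= 0) {
    stop("`interval` must be a single positive number of minutes",
         call. = FALSE)
  }
  interval <- as.integer(interval)
  dt <- unwrap(x)
  tv <- dt[[time_var]]
  if (any(!is.finite(tv))) {
    stop("raw times must be finite", call. = FALSE)
  }
  dt[[time_var]] <- as.integer(floor(tv / interval) * interval)
  rebuild(dt, tbl_meta(x), interval = interval, kind =
            if (is_win_tbl(x)) "win_tbl" else "ts_tbl")
}

## aggregation primitives: missing values are ignored unless the whole
## group is missing, in which case the result is missing
agg_fun <- function(name) {
  switch(name,
    median = function(x) if (all(is.na(x))) x[1L] else median(x, na.rm = TRUE),
    sum    = function(x) if (all(is.na(x))) x[1L] else sum(x, na.rm = TRUE),
    min    = function(x) if (all(is.na(x))) x[1L] else min(x, na.rm = TRUE),
    max    = function(x) if (all(is.na(x))) x[1L] else max(x, na.rm = TRUE),
    any    = function(x) if (all(is.na(x))) x[1L] else any(x, na.rm = TRUE),
    first  = function(x) if (all(is.na(x))) x[1L] else x[!is.na(x)][1L],
    count  = function(x) sum(!is.na(x)),
    stop("unknown aggregation function `", name, "`", call. = FALSE)
  )
}

#' Default aggregation by value type
#'
#' Numeric columns aggregate with the median, logical columns with any,
#' everything else takes the first non-missing value (stable in input
#' order). Concepts may override this per column.
#'
#' @param x A vector.
#' @return The name of the default aggregation function.
#' @export
default_aggregate <- function(x) {
  if (is.logical(x)) "any" else if (is.numeric(x)) "median" else "first"
}

#' Aggregate to one row per identifier (and time step)
#'
#' Collapses duplicate `(id, index)` combinations, applying a (possibly
#' per-column) aggregation. Missing values are ignored unless a group is
#' entirely missing.
#'
#' @param x A table object.
#' @param funs Either a single aggregation name applied to all value
#'   columns, a named list/vector mapping columns to names, a function,
#'   or `NULL` for type-based defaults ([default_aggregate()]).
#' @return A table of the same kind with unique keys.
#' @examples
#' x <- ts_tbl(data.frame(id = 1, t = c(0, 0), hr = c(80, 90)),
#'             id_vars = "id", index_var = "t", interval = 60)
#' aggregate_by(x, "median")  # 85
#' @export
aggregate_by <- function(x, funs = NULL) {
  dt <- unwrap(x)
  key <- c(id_vars(x), index_var(x))
  vals <- setdiff(names(dt), c(key, dur_var(x)))
  if (is_win_tbl(x)) vals <- c(dur_var(x), vals)
  pick <- function(v) {
    f <- if (is.null(funs)) {
      default_aggregate(dt[[v]])
    } else if (is.function(funs)) {
      funs
    } else if (length(funs) == 1L && is.null(names(funs))) {
      funs[[1L]]
    } else if (v %in% names(funs)) {
      funs[[v]]
    } else {
      default_aggregate(dt[[v]])
    }
    if (is.character(f)) agg_fun(f) else if (is.function(f)) f else
      stop("invalid aggregation for `", v, "`", call. = FALSE)
  }
  fn <- lapply(setNames(vals, vals), pick)
  out <- dt[, lapply(setNames(vals, vals), function(v) fn[[v]](.SD[[v]])),
            by = key, .SDcols = vals]
  res <- rebuild(out, tbl_meta(x))
  validate_tbl(res, dups = TRUE)
  res
}

#' Re-bin a time series to a new grid step
#'
#' Bins the existing index onto the new grid and re-aggregates so keys
#' stay unique. Equivalent to the composition of [bin_index()] and
#' [aggregate_by()].
#'
#' @param x A `ts_tbl`.
#' @param new_interval Positive grid step in minutes.
#' @param funs Aggregation specification as in [aggregate_by()].
#' @return A `ts_tbl` on the new grid.
#' @export
change_interval <- function(x, new_interval, funs = NULL) {
  aggregate_by(bin_index(x, new_interval), funs)
}

#' Make a time series regular by inserting missing grid rows
#'
#' Per identifier, ensures that every multiple of the interval between
#' the first and last observed index (or explicit limits) is present;
#' inserted rows carry missing values. Idempotent.
#'
#' @param x A `ts_tbl`.
#' @param limits Optional table (or data.frame) with the table's id
#'   columns plus `start` and `end` columns (minutes) giving the span to
#'   fill per identifier.
#' @return A dense `ts_tbl`.
#' @export
fill_gaps <- function(x, limits = NULL) {
  iv <- id_vars(x)
  ix <- index_var(x)
  step <- interval(x)
  dt <- unwrap(x)
  if (nrow(dt) == 0L && is.null(limits)) {
    return(x)
  }
  if (is.null(limits)) {
    lim <- dt[, list(start = min(.SD[[1L]]), end = max(.SD[[1L]])),
              by = iv, .SDcols = ix]
  } else {
    lim <- as.data.table(limits)
    if (!all(c(iv, "start", "end") %in% names(lim))) {
      stop("`limits` must contain columns ",
           paste(c(iv, "start", "end"), collapse = ", "), call. = FALSE)
    }
  }
  grid <- lim[, list(idx = seq(floor(start / step) * step,
                               floor(end / step) * step, by = step)),
              by = iv]
  setnames(grid, "idx", ix)
  grid[[ix]] <- as.integer(grid[[ix]])
  out <- merge(grid, dt, by = c(iv, ix), all.x = TRUE, all.y = TRUE)
  setorderv(out, c(iv, ix))
  rebuild(out, tbl_meta(x))
}

locf_vec <- function(x) {
  i <- cummax(seq_along(x) * (!is.na(x)))
  out <- x[pmax(i, 1L)]
  out[i == 0L] <- x[NA_integer_]
  out
}

#' Impute missing values
#'
#' Two schemes, selectable per variable: `"locf"` (last observation
#' carried forward within each group, ordered by the time index; leading
#' missing values remain missing) and `"const"` (replace every missing
#' value by a constant, e.g. missing death flags become `FALSE`).
#'
#' @param x A table object.
#' @param values For each variable: the constant to use for `"const"`
#'   (ignored, conventionally `NA`, for `"locf"`).
#' @param type Character vector of schemes, one per variable (recycled).
#' @param vars Variables to impute; default all value columns.
#' @param by Grouping columns; default the id columns.
#' @return The table with imputed values.
#' @examples
#' x <- ts_tbl(data.frame(id = 1, t = c(0, 60, 120, 180) ,
#'                        lact = c(1.7, NA, NA, 2.2)),
#'             id_vars = "id", index_var = "t", interval = 60)
#' replace_na(x, NA, type = "locf", vars = "lact")
#' @export
replace_na <- function(x, values, type = "const", vars = data_vars(x),
                       by = id_vars(x)) {
  if (!all(vars %in% names(x))) {
    stop("unknown variable(s): ",
         paste(setdiff(vars, names(x)), collapse = ", "), call. = FALSE)
  }
  if (!all(type %in% c("locf", "const"))) {
    stop("`type` entries must be \"locf\" or \"const\"", call. = FALSE)
  }
  type <- rep_len(type, length(vars))
  values <- rep_len(as.list(values), length(vars))
  for (k in seq_along(vars)) {
    if (type[k] == "const" && is.na(values[[k]])) {
      stop("a fill value is required for type \"const\" (`",
           vars[k], "`)", call. = FALSE)
    }
  }
  dt <- unwrap(x)
  if (!is.null(index_var(x))) setorderv(dt, c(by, index_var(x)))
  for (k in seq_along(vars)) {
    v <- vars[k]
    if (type[k] == "locf") {
      dt[, (v) := locf_vec(.SD[[1L]]), by = by, .SDcols = v]
    } else {
      fill <- values[[k]]
      dt[is.na(dt[[v]]), (v) := fill]
    }
  }
  rebuild(dt, tbl_meta(x))
}

#' Expand a windowed table onto the time grid
#'
#' Each `(start, duration)` row becomes grid rows at
#' `start, start + interval, ..., start + floor(duration/interval) *
#' interval`, all carrying the row's value, so a 159-minute episode at
#' hour 0 on an hourly grid yields rows at 0, 60 and 120 minutes.
#'
#' @param x A `win_tbl` with a grid-aligned start index.
#' @return A `ts_tbl`.
#' @export
expand <- function(x) {
  stopifnot(is_win_tbl(x))
  dt <- unwrap(x)
  ix <- index_var(x)
  dv <- dur_var(x)
  step <- interval(x)
  meta <- tbl_meta(x)
  if (nrow(dt) == 0L) {
    dt[[dv]] <- NULL
    return(rebuild(dt, meta, kind = "ts_tbl", dur_var = NULL))
  }
  dt[, .row__ := .I]
  out <- dt[, list(.off__ = seq(0L, floor(.SD[[dv]] / step) * step,
                                by = step)),
            by = ".row__", .SDcols = dv]
  out <- merge(out, dt, by = ".row__")
  out[[ix]] <- as.integer(out[[ix]] + out$.off__)
  out[, c(".row__", ".off__", dv) := NULL]
  setorderv(out, c(id_vars(x), ix))
  rebuild(out, meta, kind = "ts_tbl", dur_var = NULL)
}

#' Sliding-window summaries
#'
#' For every observed grid time `t` of each identifier, applies `fun` to
#' all observations of that identifier with index in
#' `[t - before, t + after]`. With an empty window the result is
#' missing. Used, e.g., for the 24-hour worst-value windows of SOFA
#' scoring.
#'
#' @param x A `ts_tbl` with a single value column (or `var` named).
#' @param before,after Window extent in minutes (non-negative).
#' @param fun Aggregation name (see [aggregate_by()]) or a function.
#' @param var Value column; defaults to the single data column.
#' @return A `ts_tbl` with the windowed values.
#' @export
slide <- function(x, before, after = 0L, fun = "max", var = NULL) {
  if (before < 0 || after < 0) {
    stop("`before` and `after` must be non-negative", call. = FALSE)
  }
  f <- if (is.character(fun)) agg_fun(fun) else fun
  if (!is.function(f)) stop("invalid `fun`", call. = FALSE)
  iv <- id_vars(x)
  ix <- index_var(x)
  if (is.null(var)) {
    var <- data_vars(x)
    if (length(var) != 1L) {
      stop("`var` must name the value column", call. = FALSE)
    }
  }
  dt <- unwrap(x)
  if (nrow(dt) == 0L) return(x)
  res <- dt[, {
    t0 <- .SD[[ix]]
    v <- .SD[[var]]
    out <- vapply(t0, function(tt) {
      w <- v[t0 >= tt - before & t0 <= tt + after & !is.na(v)]
      if (length(w) == 0L) {
        if (is.logical(v)) NA else NA_real_
      } else {
        as.numeric(f(w))
      }
    }, numeric(1))
    c(setNames(list(t0), ix), setNames(list(out), var))
  }, by = iv, .SDcols = c(ix, var)]
  rebuild(res, tbl_meta(x))
}

#' Truncate each series at its first raised flag
#'
#' Per identifier (ordered by time), keeps rows up to and including the
#' first row where `flag_var` is `TRUE`; if the flag never raises, all
#' rows are kept. This is the death-truncation step of survival-style
#' preprocessing: data up to and including the hour in which the death
#' flag switches on are retained.
#'
#' @param x A `ts_tbl`.
#' @param flag_var Name of a logical column (`NA` treated as not-true).
#' @return The truncated `ts_tbl`.
#' @export
truncate_at_first <- function(x, flag_var) {
  if (!flag_var %in% names(x)) {
    stop("flag column `", flag_var, "` not present", call. = FALSE)
  }
  dt <- unwrap(x)
  setorderv(dt, c(id_vars(x), index_var(x)))
  grp <- id_vars(x)
  out <- dt[, head(.SD, n = match(TRUE, .SD[[flag_var]], .N)), by = grp]
  rebuild(out, tbl_meta(x))
}

#' Merge several harmonized concept tables into one
#'
#' Performs a full outer join on the identifier columns (plus the time
#' index where present). `win_tbl` inputs are [expand()]ed onto the grid
#' first; `id_tbl` inputs (static data such as sex) are broadcast per
#' identifier against time-stamped inputs. All `ts_tbl` inputs must
#' share one interval; convert with [change_interval()] first otherwise.
#'
#' @param tables A list of table objects with compatible id columns.
#' @return A single table: `ts_tbl` if any input has a time index,
#'   otherwise `id_tbl`. Unit metadata is merged.
#' @export
merge_concepts <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  if (length(tables) == 1L) return(tables[[1L]])
  tables <- lapply(tables, function(t) if (is_win_tbl(t)) expand(t) else t)
  ivs <- unique(lapply(tables, id_vars))
  if (length(ivs) != 1L) {
    stop("id columns differ between tables; cannot merge", call. = FALSE)
  }
  iv <- ivs[[1L]]
  ts <- Filter(is_ts_tbl, tables)
  if (length(ts) > 0L) {
    ints <- unique(vapply(ts, interval, integer(1)))
    if (length(ints) != 1L) {
      stop("interval mismatch (", paste(ints, collapse = ", "),
           " minutes); align tables with change_interval() first",
           call. = FALSE)
    }
    ix <- unique(vapply(ts, index_var, character(1)))[1L]
    step <- ints[1L]
  } else {
    ix <- NULL
  }
  units <- do.call(c, lapply(tables, units_of))
  out <- NULL
  for (t in tables) {
    dt <- unwrap(t)
    if (!is.null(ix) && is_ts_tbl(t) && index_var(t) != ix) {
      setnames(dt, index_var(t), ix)
    }
    key <- c(iv, if (is_ts_tbl(t)) ix)
    if (is.null(out)) {
      out <- dt
      okey <- key
    } else {
      by <- intersect(okey, key)
      out <- merge(out, dt, by = by, all = TRUE, allow.cartesian = TRUE)
      okey <- union(okey, key)
    }
  }
  setcolorder(out, c(iv, intersect(ix, names(out))))
  setorderv(out, c(iv, intersect(ix, names(out))))
  if (!is.null(ix) && ix %in% names(out)) {
    ts_tbl(out, id_vars = iv, index_var = ix, interval = step, units = units)
  } else {
    id_tbl(out, id_vars = iv, units = units)
  }
}
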