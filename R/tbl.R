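#' @importFrom data.table as.data.table data.table is.data.table setattr
#'   copy setorderv setnames setcolorder rbindlist fifelse CJ :=
#'   setDT .SD .N .I %chin%
#' @importFrom stats median setNames
#' @importFrom utils head tail
NULL

#' Tables keyed by patient identifiers
#'
#' The harmonization engine represents all clinical data as one of three
#' table kinds, each a thin layer of metadata on top of a `data.table`:
#'
#' * `id_tbl`: rows keyed by one or more identifier columns (`id_vars`),
#'   e.g. static demographics (one row per ICU stay).
#' * `ts_tbl`: additionally carries a regular time index (`index_var`)
#'   whose values are integer minutes, each an integer multiple of the
#'   table's `interval` (also minutes). Index values may be negative:
#'   events before ICU admission are real (hospital labs drawn on the
#'   ward, for instance).
#' * `win_tbl`: additionally carries a duration column (`dur_var`,
#'   non-negative minutes) so that each row describes a time window,
#'   e.g. a mechanical-ventilation episode.
#'
#' All times and durations are integer minutes; display layers may render
#' hours but the canonical representation never changes.
#'
#' @param x A `data.frame`/`data.table` of rows.
#' @param id_vars Character vector of identifier column names.
#' @param index_var Name of the time-index column (minutes).
#' @param interval Positive integer time-grid step in minutes.
#' @param dur_var Name of the duration column (minutes, `>= 0`).
#' @param units Optional named character vector mapping value columns to
#'   unit strings.
#'
#' @return An object of class `id_tbl`, `ts_tbl` or `win_tbl` (each also
#'   a `data.table`).
#'
#' @examples
#' id_tbl(data.frame(icustay_id = 1:2, sex = c("Male", "Female")),
#'        id_vars = "icustay_id")
#' ts_tbl(data.frame(icustay_id = 1, charttime = c(0, 60), hr = c(80, 85)),
#'        id_vars = "icustay_id", index_var = "charttime", interval = 60)
#' @export
id_tbl <- function(x, id_vars, units = NULL) {
  new_tbl(x, id_vars = id_vars, units = units, kind = "id_tbl")
}

#' @rdname id_tbl
#' @export
ts_tbl <- function(x, id_vars, index_var, interval = 60L, units = NULL) {
  new_tbl(x, id_vars = id_vars, index_var = index_var,
          interval = as.integer(interval), units = units, kind = "ts_tbl")
}

#' @rdname id_tbl
#' @export
win_tbl <- function(x, id_vars, index_var, dur_var, interval = 60L,
                    units = NULL) {
  new_tbl(x, id_vars = id_vars, index_var = index_var,
          interval = as.integer(interval), dur_var = dur_var,
          units = units, kind = "win_tbl")
}

tbl_kinds <- c("id_tbl", "ts_tbl", "win_tbl")

new_tbl <- function(x, id_vars, index_var = NULL, interval = NULL,
                    dur_var = NULL, units = NULL, kind) {
  dt <- as.data.table(x)
  cls <- switch(kind,
    id_tbl  = c("id_tbl", class(data.table())),
    ts_tbl  = c("ts_tbl", "id_tbl", class(data.table())),
    win_tbl = c("win_tbl", "ts_tbl", "id_tbl", class(data.table()))
  )
  setattr(dt, "class", cls)
  setattr(dt, "id_vars", as.character(id_vars))
  setattr(dt, "index_var", if (is.null(index_var)) NULL else as.character(index_var))
  setattr(dt, "interval", if (is.null(interval)) NULL else as.integer(interval))
  setattr(dt, "dur_var", if (is.null(dur_var)) NULL else as.character(dur_var))
  setattr(dt, "units", units)
  validate_tbl(dt)
  dt
}

#' Validate table invariants
#'
#' Checks that identifier columns exist and are non-missing, that a
#' `ts_tbl` index is an integer multiple of its (positive) interval, and
#' that `win_tbl` durations are non-negative. Duplicate
#' `(id_vars, index)` combinations are only forbidden after aggregation;
#' pass `dups = TRUE` to additionally enforce uniqueness.
#'
#' @param x A table object.
#' @param dups Also check for duplicate key combinations.
#' @return `x`, invisibly; errors describe the violated invariant.
#' @export
validate_tbl <- function(x, dups = FALSE) {
  stopifnot(is.data.table(x))
  iv <- id_vars(x)
  miss <- setdiff(iv, names(x))
  if (length(miss) > 0L) {
    stop("id column(s) not present: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (v in iv) {
    if (anyNA(x[[v]])) {
      stop("id column `", v, "` contains missing values", call. = FALSE)
    }
  }
  if (is_ts_tbl(x)) {
    ix <- index_var(x)
    iv_step <- interval(x)
    if (!ix %in% names(x)) {
      stop("index column `", ix, "` not present", call. = FALSE)
    }
    if (is.null(iv_step) || is.na(iv_step) || iv_step <= 0L) {
      stop("interval must be a positive number of minutes", call. = FALSE)
    }
    idx <- x[[ix]]
    if (length(idx) > 0L) {
      ok <- is.na(idx) | (idx %% iv_step == 0)
      if (!all(ok)) {
        stop("index values must be integer multiples of the ", iv_step,
             "-minute interval", call. = FALSE)
      }
    }
  }
  if (is_win_tbl(x)) {
    dv <- dur_var(x)
    if (!dv %in% names(x)) {
      stop("duration column `", dv, "` not present", call. = FALSE)
    }
    if (length(x[[dv]]) > 0L && any(x[[dv]] < 0, na.rm = TRUE)) {
      stop("durations must be non-negative", call. = FALSE)
    }
  }
  if (dups) {
    key <- c(iv, if (is_ts_tbl(x)) index_var(x))
    if (anyDuplicated(x, by = key) > 0L) {
      stop("duplicate (id, index) combinations present", call. = FALSE)
    }
  }
  invisible(x)
}

#' Table metadata accessors
#'
#' @param x A table object.
#' @return `id_vars()`: character vector of identifier columns;
#'   `index_var()`, `dur_var()`: column name or `NULL`; `interval()`:
#'   integer minutes or `NULL`; `data_vars()`: the value columns (all
#'   columns that are not identifier, index or duration columns);
#'   `units_of()`: named character vector of unit strings.
#' @export
id_vars <- function(x) attr(x, "id_vars")

#' @rdname id_vars
#' @export
index_var <- function(x) attr(x, "index_var")

#' @rdname id_vars
#' @export
interval <- function(x) attr(x, "interval")

#' @rdname id_vars
#' @export
dur_var <- function(x) attr(x, "dur_var")

#' @rdname id_vars
#' @export
data_vars <- function(x) {
  setdiff(names(x), c(id_vars(x), index_var(x), dur_var(x)))
}

#' @rdname id_vars
#' @export
units_of <- function(x) attr(x, "units")

#' @rdname id_vars
#' @export
is_id_tbl <- function(x) inherits(x, "id_tbl")

#' @rdname id_vars
#' @export
is_ts_tbl <- function(x) inherits(x, "ts_tbl")

#' @rdname id_vars
#' @export
is_win_tbl <- function(x) inherits(x, "win_tbl")

tbl_kind <- function(x) {
  if (is_win_tbl(x)) "win_tbl" else if (is_ts_tbl(x)) "ts_tbl"
  else if (is_id_tbl(x)) "id_tbl" else "data.table"
}

tbl_meta <- function(x) {
  list(id_vars = id_vars(x), index_var = index_var(x),
       interval = interval(x), dur_var = dur_var(x),
       units = units_of(x), kind = tbl_kind(x))
}

## rebuild a table of the same kind around new rows, optionally
## overriding individual metadata fields
rebuild <- function(rows, meta, ...) {
  over <- list(...)
  for (nm in names(over)) meta[[nm]] <- over[[nm]]
  switch(meta$kind,
    id_tbl  = id_tbl(rows, id_vars = meta$id_vars, units = meta$units),
    ts_tbl  = ts_tbl(rows, id_vars = meta$id_vars, index_var = meta$index_var,
                     interval = meta$interval, units = meta$units),
    win_tbl = win_tbl(rows, id_vars = meta$id_vars, index_var = meta$index_var,
                      dur_var = meta$dur_var, interval = meta$interval,
                      units = meta$units),
    as.data.table(rows)
  )
}

## plain data.table copy (drops the id_tbl classes and metadata)
unwrap <- function(x) {
  dt <- copy(x)
  setattr(dt, "class", class(data.table()))
  setattr(dt, "id_vars", NULL)
  setattr(dt, "index_var", NULL)
  setattr(dt, "interval", NULL)
  setattr(dt, "dur_var", NULL)
  setattr(dt, "units", NULL)
  dt
}

fmt_hours <- function(mins) {
  ifelse(mins %% 60 == 0, paste0(mins %/% 60, " hours"),
         paste0(mins, " mins"))
}

#' @export
print.id_tbl <- function(x, n = 10L, ...) {
  cat(sprintf("# %s `%s`: %d x %d\n",
              if (grepl("^[aeiou]", tbl_kind(x))) "An" else "A",
              tbl_kind(x), nrow(x), ncol(x)))
  cat(sprintf("# Id var%s:   %s\n", if (length(id_vars(x)) > 1) "s" else "",
              paste0("`", id_vars(x), "`", collapse = ", ")))
  un <- units_of(x)
  if (length(un) > 0) {
    cat(sprintf("# Units:     %s\n",
                paste0("`", names(un), "` [", un, "]", collapse = ", ")))
  }
  if (is_ts_tbl(x)) {
    cat(sprintf("# Index var: `%s` (%g hours)\n", index_var(x),
                interval(x) / 60))
  }
  if (is_win_tbl(x)) {
    cat(sprintf("# Duration var: `%s`\n", dur_var(x)))
  }
  print(as.data.table(head(unwrap(x), n)))
  if (nrow(x) > n) cat(sprintf("# ... with %d more rows\n", nrow(x) - n))
  invisible(x)
}

#' Serialize a table to CSV with a JSON metadata sidecar
#'
#' The CSV carries the rows; the sidecar (`<path>.meta.json`) records the
#' table kind, identifier columns, index/interval/duration metadata and
#' per-column units, so a round trip preserves the object.
#'
#' @param x A table object.
#' @param path CSV output path.
#' @return `write_tbl()`: `path`, invisibly. `read_tbl()`: the restored
#'   table.
#' @export
write_tbl <- function(x, path) {
  data.table::fwrite(unwrap(x), path)
  meta <- tbl_meta(x)
  meta$units <- as.list(meta$units)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_tbl
#' @export
read_tbl <- function(path) {
  rows <- data.table::fread(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  units <- if (length(meta$units) > 0) unlist(meta$units) else NULL
  meta_l <- list(id_vars = meta$id_vars, index_var = meta$index_var,
                 interval = meta$interval, dur_var = meta$dur_var,
                 units = units, kind = meta$kind)
  rebuild(rows, meta_l)
}
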