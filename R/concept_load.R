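## The load_concepts() engine: per-source item extraction, callbacks,
## unit harmonization, plausibility-bound filtering, identifier-system
## conversion, time binning, aggregation, recursive-concept resolution
## and multi-concept merging.

#' Extract the raw rows of one item
#'
#' Runs one extraction rule against a registered source: `sel_itm`
#' selects the rows of its table whose `sub_var` value is one of `ids`;
#' `col_itm` takes all rows, reading the value from the declared value
#' column. Rows with a missing value are dropped (wide layouts encode
#' absence as empty cells), then the item's callback, if any, is applied.
#'
#' @param handle A `src_handle`.
#' @param it A `cncpt_item`.
#' @param concept_name For error messages.
#' @return A `data.table` with the item's id column plus `time`
#'   (canonical minutes, when the table has a time index), `value`,
#'   and optionally `unit` and `dur` columns. The id column name is
#'   recorded in attribute `"id_col"`.
#' @export
load_item <- function(handle, it, concept_name = "?") {
  tdef <- handle$cfg$tables[[it$table]]
  if (is.null(tdef)) {
    stop("extraction error for concept `", concept_name, "`: table `",
         it$table, "` not present in source `", handle$cfg$name, "`",
         call. = FALSE)
  }
  dt <- src_table(handle, it$table)
  pick_col <- function(override, default_name, required = FALSE,
                       what = default_name) {
    col <- if (!is.null(override)) override else
      table_default(handle, it$table, default_name)
    if (is.null(col)) {
      if (required) {
        stop("extraction error for concept `", concept_name,
             "`: no ", what, " declared for table `", it$table, "`",
             call. = FALSE)
      }
      return(NULL)
    }
    if (!col %in% names(dt)) {
      stop("extraction error for concept `", concept_name, "`: column `",
           col, "` missing from table `", it$table, "`", call. = FALSE)
    }
    col
  }
  id_col <- pick_col(NULL, "id_column", required = TRUE, what = "id column")
  idx_col <- pick_col(it$index_column, "index_column")
  val_col <- pick_col(it$value_column, "value_column",
                      required = identical(it$kind, "col_itm") &&
                        is.null(it$value_column),
                      what = "value column")
  unit_col <- pick_col(it$unit_column, "unit_column")
  dur_col <- pick_col(it$dur_column, "dur_column")

  if (identical(it$kind, "sel_itm")) {
    if (!it$sub_var %in% names(dt)) {
      stop("extraction error for concept `", concept_name, "`: sub_var `",
           it$sub_var, "` missing from table `", it$table, "`",
           call. = FALSE)
    }
    keep <- as.character(dt[[it$sub_var]]) %in% as.character(it$ids)
    if (!any(keep)) {
      warning("concept `", concept_name, "`: no rows match ids for table `",
              it$table, "` in source `", handle$cfg$name, "`",
              call. = FALSE)
    }
    dt <- dt[keep]
  }

  out <- data.table(id = dt[[id_col]])
  setnames(out, "id", id_col)
  if (!is.null(idx_col)) out$time <- dt[[idx_col]]
  out$value <- if (is.null(val_col)) rep(TRUE, nrow(dt)) else dt[[val_col]]
  if (!is.null(unit_col)) out$unit <- dt[[unit_col]]
  if (!is.null(dur_col)) out$dur <- as.numeric(dt[[dur_col]])
  out <- out[!is.na(out$value)]
  if (!is.null(it$callback)) {
    cb <- resolve_callback(it$callback)
    out <- cb(out, list(handle = handle, id_col = id_col))
  }
  setattr(out, "id_col", id_col)
  out
}

#' Harmonize measurement units
#'
#' Rows whose unit string is one of the concept's accepted units (or
#' whose unit is unknown/absent because the table declares none) pass
#' unchanged; convertible units (see [register_unit_conversion()]) are
#' rescaled to the concept's canonical unit; unrecognized units are kept
#' with a warning and recorded in the `"unit_flags"` attribute.
#'
#' @param rows Item rows (with or without a `unit` column).
#' @param concept The `cncpt`.
#' @return The harmonized rows.
#' @export
harmonize_units <- function(rows, concept) {
  if (is.null(concept$unit) || !"unit" %in% names(rows) ||
      nrow(rows) == 0L) {
    return(rows)
  }
  accepted <- tolower(concept$unit)
  u <- tolower(rows$unit)
  ok <- is.na(u) | u %in% accepted
  flags <- character()
  for (bad in unique(u[!ok])) {
    conv <- find_unit_conversion(bad, concept$unit)
    sel <- !ok & u == bad
    if (!is.null(conv)) {
      rows$value[sel] <- rows$value[sel] * conv$factor
      rows$unit[sel] <- concept$unit[match(conv$to, accepted)]
    } else {
      flags <- c(flags, bad)
    }
  }
  if (length(flags) > 0) {
    warning("concept `", concept$name, "`: unrecognized unit(s) kept: ",
            paste(flags, collapse = ", "), call. = FALSE)
    setattr(rows, "unit_flags", flags)
  }
  rows
}

#' Remove implausible values
#'
#' Numeric concepts may declare plausibility bounds; values outside the
#' closed interval `[min, max]` are removed and the removal count is
#' reported via `message()`. Concepts without bounds pass through
#' unchanged. Filtering happens before aggregation, so an artifactual
#' 350-bpm reading can never contaminate an hourly median.
#'
#' @param rows Item rows.
#' @param concept The `cncpt`.
#' @return The filtered rows.
#' @export
enforce_bounds <- function(rows, concept) {
  if (is.null(concept$min) && is.null(concept$max)) return(rows)
  v <- as.numeric(rows$value)
  bad <- rep(FALSE, length(v))
  if (!is.null(concept$min)) bad <- bad | v < concept$min
  if (!is.null(concept$max)) bad <- bad | v > concept$max
  bad[is.na(bad)] <- FALSE
  if (any(bad)) {
    message(sprintf("concept `%s`: removed %d value(s) outside [%s, %s]",
                    concept$name, sum(bad),
                    format(concept$min %||% -Inf),
                    format(concept$max %||% Inf)))
    rows <- rows[!bad]
  }
  rows
}

`%||%` <- function(a, b) if (is.null(a)) b else a

coerce_concept_value <- function(rows, concept) {
  if (nrow(rows) == 0L) {
    rows$value <- switch(concept$kind, lgl_cncpt = logical(),
                         fct_cncpt = character(), as.numeric(rows$value))
    return(rows)
  }
  if (identical(concept$kind, "num_cncpt")) {
    rows$value <- as.numeric(rows$value)
  } else if (identical(concept$kind, "lgl_cncpt")) {
    rows$value <- as.logical(rows$value)
  } else if (identical(concept$kind, "fct_cncpt") &&
             !is.null(concept$levels)) {
    rows$value <- as.character(rows$value)
    bad <- !rows$value %in% concept$levels
    if (any(bad)) {
      message(sprintf(
        "concept `%s`: dropped %d value(s) outside the level set",
        concept$name, sum(bad)))
      rows <- rows[!bad]
    }
  }
  rows
}

## package one extracted+converted item into the concept's target kind,
## keyed by the request id system, on the request grid
package_item <- function(rows, handle, concept, id_type, step) {
  id_col <- attr(rows, "id_col")
  origin <- if (identical(handle$cfg$time_mode, "absolute")) "absolute"
            else NULL
  tgt_col <- id_system(handle, id_type)$id_column
  if (identical(concept$target, "id_tbl") || !"time" %in% names(rows)) {
    keep <- c(id_col, "value")
    tb <- id_tbl(rows[, keep, with = FALSE], id_vars = id_col)
    tb <- change_id(tb, handle, id_type, origin = origin)
    return(unwrap(tb)[, c(tgt_col, "value"), with = FALSE])
  }
  has_dur <- "dur" %in% names(rows) && identical(concept$target, "win_tbl")
  keep <- c(id_col, "time", if (has_dur) "dur", "value")
  rows <- rows[!is.na(rows$time), keep, with = FALSE]
  rows$time <- as.integer(round(rows$time))
  tb <- if (has_dur) {
    win_tbl(rows, id_vars = id_col, index_var = "time", dur_var = "dur",
            interval = 1L)
  } else {
    ts_tbl(rows, id_vars = id_col, index_var = "time", interval = 1L)
  }
  tb <- change_id(tb, handle, id_type, origin = origin)
  tb <- bin_index(tb, step)
  unwrap(tb)[, c(tgt_col, "time", if (has_dur) "dur", "value"),
             with = FALSE]
}

#' Load one atomic concept from a source
#'
#' Runs the full extraction pipeline for an atomic (non-recursive)
#' concept: item extraction and callbacks, unit harmonization,
#' plausibility-bound filtering, conversion to the requested identifier
#' system, binning onto the requested grid, and aggregation to unique
#' keys. A source with declared items but no matching rows yields an
#' empty table; a source with no declared items raises an availability
#' error.
#'
#' @param handle A `src_handle`.
#' @param concept A `cncpt` (atomic).
#' @param id_type Target identifier system name.
#' @param interval Grid step in minutes.
#' @param aggregate Optional aggregation override.
#' @return An `id_tbl`/`ts_tbl`/`win_tbl` with the concept's value
#'   column named after the concept.
#' @export
load_atomic_concept <- function(handle, concept, id_type = NULL,
                                interval = 60L, aggregate = NULL) {
  stopifnot(!identical(concept$kind, "rec_cncpt"))
  src <- handle$cfg$name
  if (is.null(id_type)) id_type <- tail(id_hierarchy(handle), 1L)
  items <- concept$sources[[src]]
  if (length(items) == 0L) {
    stop("concept `", concept$name, "` is not available for source `",
         src, "`", call. = FALSE)
  }
  parts <- lapply(items, function(it) {
    rows <- load_item(handle, it, concept_name = concept$name)
    rows <- harmonize_units(rows, concept)
    rows <- coerce_concept_value(rows, concept)
    rows <- enforce_bounds(rows, concept)
    package_item(rows, handle, concept, id_type, as.integer(interval))
  })
  all <- rbindlist(parts, fill = TRUE)
  tgt_col <- id_system(handle, id_type)$id_column
  units <- if (!is.null(concept$unit)) {
    setNames(concept$unit[1L], concept$name)
  }
  has_time <- "time" %in% names(all) && !identical(concept$target, "id_tbl")
  has_dur <- "dur" %in% names(all) && identical(concept$target, "win_tbl")
  if (nrow(all) == 0L) {
    all <- data.table(id = integer(), time = integer(), dur = numeric(),
                      value = switch(concept$kind, lgl_cncpt = logical(),
                                     fct_cncpt = character(), numeric()))
    setnames(all, "id", tgt_col)
    has_time <- !identical(concept$target, "id_tbl")
    has_dur <- identical(concept$target, "win_tbl")
    if (!has_time) all$time <- NULL
    if (!has_dur) all$dur <- NULL
  }
  agg <- aggregate %||% concept$aggregate %||% default_aggregate(all$value)
  tb <- if (has_dur) {
    win_tbl(all, id_vars = tgt_col, index_var = "time", dur_var = "dur",
            interval = as.integer(interval), units = units)
  } else if (has_time) {
    ts_tbl(all, id_vars = tgt_col, index_var = "time",
           interval = as.integer(interval), units = units)
  } else {
    if ("time" %in% names(all)) all$time <- NULL
    id_tbl(all, id_vars = tgt_col, units = units)
  }
  tb <- aggregate_by(tb, setNames(list(agg), "value"))
  setnames(tb, "value", concept$name)
  tb
}

#' Resolve a recursive concept
#'
#' Loads the concept's dependencies (topologically, propagating the
#' requested identifier system and interval), then hands the named list
#' of dependency tables to the concept's callback, which computes and
#' returns the concept table.
#'
#' @inheritParams load_atomic_concept
#' @param dict The `concept_dict` (dependencies are looked up here).
#' @param cache Internal per-request memo environment.
#' @return The concept table.
#' @export
resolve_recursive <- function(dict, handle, concept, id_type = NULL,
                              interval = 60L, aggregate = NULL,
                              cache = new.env(parent = emptyenv())) {
  ## a recursive concept's aggregate field applies to loading its
  ## dependencies (e.g. ins24 loads ins with sum instead of median)
  deps <- lapply(setNames(concept$depends, concept$depends), function(d) {
    load_concept_one(dict, handle, d, id_type = id_type,
                     interval = interval, aggregate = concept$aggregate,
                     cache = cache)
  })
  cb <- resolve_callback(concept$callback)
  ctx <- list(handle = handle, id_type = id_type,
              interval = as.integer(interval), name = concept$name,
              target = concept$target, aggregate = aggregate,
              dict = dict, cache = cache)
  res <- cb(deps, ctx)
  validate_tbl(res)
  res
}

load_concept_one <- function(dict, handle, name, id_type = NULL,
                             interval = 60L, aggregate = NULL,
                             cache = new.env(parent = emptyenv())) {
  key <- paste0(name, "\r", aggregate %||% "")
  if (!is.null(cache[[key]])) return(cache[[key]])
  concept <- find_concept(dict, name)
  res <- if (identical(concept$kind, "rec_cncpt")) {
    resolve_recursive(dict, handle, concept, id_type = id_type,
                      interval = interval, aggregate = aggregate,
                      cache = cache)
  } else {
    load_atomic_concept(handle, concept, id_type = id_type,
                        interval = interval, aggregate = aggregate)
  }
  cache[[key]] <- res
  res
}

#' Load clinical concepts from a registered source
#'
#' The main workhorse: loads one or more concepts (by abbreviated name
#' or integer OMOP concept id) from a registered source, harmonized to
#' the requested identifier system and time grid, and merges them into
#' a single table (full outer join; no implicit imputation -- call
#' [replace_na()] / [fill_gaps()] explicitly).
#'
#' Concepts queried by name yield columns named by the abbreviation;
#' concepts queried by OMOP id yield columns named `omop_<id>`.
#'
#' @param x Character/numeric vector of concept names and/or OMOP ids.
#' @param handle A `src_handle` (see [register_source()]).
#' @param dict A `concept_dict`; defaults to the shipped dictionary
#'   plus user extensions.
#' @param id_type Identifier system of the result (default: the finest
#'   declared system, typically the ICU stay).
#' @param interval Time-grid step in minutes.
#' @param patient_ids Optional identifier filter: a vector of id
#'   values, or a table whose first id column is used.
#' @param aggregate Optional named list/vector of per-concept
#'   aggregation overrides.
#' @return A single `id_tbl`/`ts_tbl` with one value column per
#'   concept (`win_tbl` inputs are expanded onto the grid when merged
#'   with others).
#' @examples \dontrun{
#' load_concepts(c("lact", "death", "sofa"), handle)
#' load_concepts(4191725, handle)   # same data, column "omop_4191725"
#' }
#' @export
load_concepts <- function(x, handle, dict = NULL, id_type = NULL,
                          interval = 60L, patient_ids = NULL,
                          aggregate = NULL) {
  if (is.null(dict)) dict <- load_dictionary()
  if (is.null(id_type)) id_type <- tail(id_hierarchy(handle), 1L)
  keys <- as.list(x)
  misses <- character()
  concepts <- list()
  for (k in keys) {
    key <- k
    cn <- tryCatch(find_concept(dict, key), error = function(e) NULL)
    if (is.null(cn)) misses <- c(misses, as.character(k)) else
      concepts <- c(concepts, list(list(key = key, concept = cn)))
  }
  if (length(misses) > 0) {
    stop("unknown concept(s): ", paste(misses, collapse = ", "),
         call. = FALSE)
  }
  cache <- new.env(parent = emptyenv())
  tabs <- lapply(concepts, function(ci) {
    agg <- if (!is.null(aggregate)) aggregate[[ci$concept$name]]
    tb <- load_concept_one(dict, handle, ci$concept$name,
                           id_type = id_type, interval = interval,
                           aggregate = agg, cache = cache)
    if (is.numeric(ci$key)) {
      newname <- paste0("omop_", format(ci$concept$omopid, scientific = FALSE))
      un <- units_of(tb)
      setnames(tb, ci$concept$name, newname)
      if (!is.null(un) && ci$concept$name %in% names(un)) {
        names(un)[names(un) == ci$concept$name] <- newname
        setattr(tb, "units", un)
      }
    }
    tb
  })
  out <- merge_concepts(tabs)
  if (!is.null(patient_ids)) {
    ids <- if (is.data.frame(patient_ids)) {
      iv <- if (is_id_tbl(patient_ids)) id_vars(patient_ids)[1L] else
        names(patient_ids)[1L]
      unique(patient_ids[[iv]])
    } else {
      unique(patient_ids)
    }
    keep <- out[[id_vars(out)[1L]]] %in% ids
    out <- rebuild(unwrap(out)[keep], tbl_meta(out))
  }
  out
}
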