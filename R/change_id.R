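#' Convert a table between identifier systems
#'
#' Moves a table from one identifier system of a source (e.g. hospital
#' stay) to another (e.g. ICU stay), using the admission/discharge
#' windows declared in the source configuration.
#'
#' * fine to coarse (e.g. ICU stay to hospital stay): identifiers are
#'   mapped through the origin tables and the time index is shifted by
#'   the difference of the two admission times.
#' * coarse to fine: each time-stamped row is assigned to the finer stay
#'   whose half-open window `[admission, discharge)` contains the row's
#'   absolute time; rows falling outside every window are dropped and
#'   their count is reported via `message()`. Rows without a time index
#'   (static `id_tbl` data such as a hospital-stay diagnosis) are
#'   broadcast to every contained finer stay instead.
#'
#' The result's index is expressed in minutes relative to the target
#' system's admission time.
#'
#' @param x An `id_tbl`/`ts_tbl`/`win_tbl` whose single id column is the
#'   id column of some identifier system of `handle`.
#' @param handle A `src_handle`.
#' @param target Name of the target identifier system.
#' @param origin Time origin of `x`'s index: `"absolute"` (canonical
#'   minutes, as read from an absolute-time source) or the name of the
#'   identifier system the index is relative to. Defaults to the
#'   system `x` is currently keyed by.
#' @return The converted table, keyed by the target system's id column.
#' @export
change_id <- function(x, handle, target, origin = NULL) {
  stopifnot(inherits(handle, "src_handle"))
  cfg <- handle$cfg
  tgt <- id_system(cfg, target)
  iv <- id_vars(x)
  if (length(iv) != 1L) {
    stop("change_id() requires a single id column", call. = FALSE)
  }
  from <- NULL
  for (s in cfg$id_systems) if (s$id_column == iv) from <- s
  if (is.null(from)) {
    stop("id column `", iv, "` does not match any id system of source `",
         cfg$name, "`", call. = FALSE)
  }
  if (is.null(origin)) origin <- from$name
  has_time <- is_ts_tbl(x)
  map <- id_map(handle)
  dt <- unwrap(x)
  meta <- tbl_meta(x)

  if (identical(from$name, tgt$name) && !has_time) {
    return(x)
  }

  if (has_time) {
    ix <- index_var(x)
    ## absolute time per row
    if (identical(origin, "absolute")) {
      dt[, .abs__ := as.numeric(.SD[[1L]]), .SDcols = ix]
    } else {
      osys <- id_system(cfg, origin)
      ostart <- paste0(osys$name, "__start")
      om <- unique(map[, c(osys$id_column, ostart), with = FALSE])
      if (!osys$id_column %in% names(dt)) {
        stop("cannot anchor relative times: column `", osys$id_column,
             "` absent", call. = FALSE)
      }
      dt <- merge(dt, om, by = osys$id_column, all.x = TRUE)
      dt[, .abs__ := as.numeric(.SD[[ix]]) + as.numeric(.SD[[ostart]]),
         .SDcols = c(ix, ostart)]
      dt[[ostart]] <- NULL
    }
  }

  tcol <- tgt$id_column
  tstart <- paste0(tgt$name, "__start")
  tend <- paste0(tgt$name, "__end")

  if (tgt$rank <= from$rank) {
    ## fine -> coarse (or same system): unique mapping
    mcols <- unique(c(iv, tcol, if (has_time) tstart))
    m <- unique(map[, mcols, with = FALSE])
    if (identical(from$name, tgt$name)) {
      out <- if (has_time) merge(dt, m[, c(iv, tstart), with = FALSE],
                                 by = iv, all.x = TRUE) else dt
    } else {
      out <- merge(dt, m, by = iv, all.x = FALSE)
      out[[iv]] <- NULL
    }
  } else {
    ## coarse -> fine: containment (time-stamped) or broadcast (static)
    mcols <- unique(c(iv, tcol, tstart, tend))
    m <- map[, mcols, with = FALSE]
    n0 <- nrow(dt)
    out <- merge(dt, m, by = iv, all.x = FALSE, allow.cartesian = TRUE)
    if (has_time) {
      keep <- !is.na(out[[tstart]]) &
        out$.abs__ >= as.numeric(out[[tstart]]) &
        out$.abs__ < as.numeric(out[[tend]])
      out <- out[keep]
      if (nrow(out) < n0) {
        message(sprintf(
          "change_id: %d row(s) outside every `%s` window dropped",
          n0 - nrow(out), tgt$name))
      }
    }
    out[[tend]] <- NULL
    if (!has_time) out[[tstart]] <- NULL
    out[[iv]] <- NULL
  }

  if (has_time) {
    ix <- index_var(x)
    out[[ix]] <- as.integer(round(out$.abs__ - as.numeric(out[[tstart]])))
    out[, c(".abs__", tstart) := NULL]
  }
  out <- out[!is.na(out[[tcol]])]
  setcolorder(out, c(tcol, if (has_time) index_var(x)))
  rebuild(out, meta, id_vars = tcol)
}
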