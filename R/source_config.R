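## Declarative description of one ICU database: identifier systems
## (coarse -> fine, e.g. patient < hospital stay < ICU stay), tables and
## their column semantics, and whether timestamps are absolute
## (ISO-8601) or relative (integer minutes from the finest identifier
## system's admission).

col_types <- c("id", "timestamp", "duration", "number", "string")

cfg_err <- function(path, msg) {
  stop(sprintf("invalid source configuration at %s: %s", path, msg),
       call. = FALSE)
}

#' Parse a source configuration document
#'
#' A source configuration is a JSON document describing a database:
#' its name, time mode (`"absolute"` timestamps as ISO-8601 strings, or
#' `"relative"` integer minutes from the finest identifier system's
#' admission), its identifier systems (with rank 1 the coarsest, e.g.
#' `patient` < `hadm` < `icustay`), and its tables with per-column
#' semantic types (`id`, `timestamp`, `duration`, `number`, `string`)
#' and per-table defaults (`id_column`, `index_column`, `value_column`,
#' `unit_column`, `dur_column`).
#'
#' @param x JSON text, a path to a JSON file, or an already-parsed list.
#' @return A validated `src_cfg` object.
#' @examples
#' cfg <- parse_source_config('{
#'   "name": "tiny", "time_mode": "relative",
#'   "id_systems": [{"name": "icustay", "id_column": "stay_id",
#'     "origin_table": "stays", "start_column": "admit",
#'     "end_column": "disch", "rank": 1}],
#'   "tables": [{"name": "stays", "file": "stays.csv",
#'     "columns": [{"name": "stay_id", "type": "id"},
#'                 {"name": "admit", "type": "timestamp"},
#'                 {"name": "disch", "type": "timestamp"}],
#'     "defaults": {"id_column": "stay_id"}}]
#' }')
#' id_hierarchy(cfg)
#' @export
parse_source_config <- function(x) {
  doc <- coerce_json(x)
  for (f in c("name", "time_mode", "id_systems", "tables")) {
    if (is.null(doc[[f]])) cfg_err(paste0("$", f), "missing field")
  }
  if (!doc$time_mode %in% c("absolute", "relative")) {
    cfg_err("$time_mode", "must be \"absolute\" or \"relative\"")
  }
  ids <- lapply(seq_along(doc$id_systems), function(i) {
    s <- doc$id_systems[[i]]
    p <- sprintf("$id_systems[%d]", i)
    for (f in c("name", "id_column", "origin_table", "start_column", "rank")) {
      if (is.null(s[[f]])) cfg_err(paste0(p, ".", f), "missing field")
    }
    list(name = s$name, id_column = s$id_column,
         origin_table = s$origin_table, start_column = s$start_column,
         end_column = s$end_column, rank = as.integer(s$rank))
  })
  ranks <- sort(vapply(ids, `[[`, integer(1), "rank"))
  if (!identical(ranks, seq_along(ids))) {
    cfg_err("$id_systems", paste0(
      "ranks must be distinct, consecutive and start at 1 (got ",
      paste(ranks, collapse = ", "), ")"))
  }
  ids <- ids[order(vapply(ids, `[[`, integer(1), "rank"))]
  tbls <- lapply(seq_along(doc$tables), function(i) {
    t <- doc$tables[[i]]
    p <- sprintf("$tables[%d]", i)
    for (f in c("name", "file", "columns")) {
      if (is.null(t[[f]])) cfg_err(paste0(p, ".", f), "missing field")
    }
    cols <- lapply(seq_along(t$columns), function(j) {
      cc <- t$columns[[j]]
      if (is.null(cc$name) || is.null(cc$type)) {
        cfg_err(sprintf("%s.columns[%d]", p, j), "missing name/type")
      }
      if (!cc$type %in% col_types) {
        cfg_err(sprintf("%s.columns[%d].type", p, j),
                paste0("unknown semantic type \"", cc$type, "\""))
      }
      list(name = cc$name, type = cc$type)
    })
    cnames <- vapply(cols, `[[`, character(1), "name")
    if (anyDuplicated(cnames)) {
      cfg_err(paste0(p, ".columns"), "duplicate column names")
    }
    defs <- t$defaults
    if (is.null(defs)) defs <- list()
    defs <- defs[!vapply(defs, is.null, logical(1))]
    allowed <- c("id_column", "index_column", "value_column",
                 "unit_column", "dur_column")
    bad <- setdiff(names(defs), allowed)
    if (length(bad) > 0) {
      cfg_err(paste0(p, ".defaults"),
              paste0("unknown default(s): ", paste(bad, collapse = ", ")))
    }
    for (d in names(defs)) {
      if (!defs[[d]] %in% cnames) {
        cfg_err(paste0(p, ".defaults.", d),
                paste0("references undeclared column \"", defs[[d]], "\""))
      }
    }
    list(name = t$name, file = t$file, columns = cols, defaults = defs)
  })
  tnames <- vapply(tbls, `[[`, character(1), "name")
  if (anyDuplicated(tnames)) {
    stop("configuration error: duplicate table name(s): ",
         paste(unique(tnames[duplicated(tnames)]), collapse = ", "),
         call. = FALSE)
  }
  names(tbls) <- tnames
  for (i in seq_along(ids)) {
    s <- ids[[i]]
    p <- sprintf("$id_systems[%d]", i)
    if (!s$origin_table %in% tnames) {
      cfg_err(paste0(p, ".origin_table"),
              paste0("\"", s$origin_table, "\" is not a declared table"))
    }
    ocols <- vapply(tbls[[s$origin_table]]$columns, `[[`, character(1), "name")
    for (f in c("id_column", "start_column")) {
      if (!s[[f]] %in% ocols) {
        cfg_err(paste0(p, ".", f),
                paste0("column \"", s[[f]], "\" not in origin table"))
      }
    }
    if (!is.null(s$end_column) && !s$end_column %in% ocols) {
      cfg_err(paste0(p, ".end_column"),
              paste0("column \"", s$end_column, "\" not in origin table"))
    }
  }
  structure(list(name = doc$name, time_mode = doc$time_mode,
                 id_systems = ids, tables = tbls),
            class = "src_cfg")
}

coerce_json <- function(x) {
  if (is.list(x)) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  txt <- if (file.exists(x) && !grepl("^\\s*[{\\[]", x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else {
    x
  }
  jsonlite::fromJSON(txt, simplifyVector = FALSE)
}

#' @rdname parse_source_config
#' @param cfg A `src_cfg` object.
#' @return `serialize_source_config()`: the normalized JSON text; a
#'   parse/serialize/parse round trip is the identity.
#' @export
serialize_source_config <- function(cfg) {
  stopifnot(inherits(cfg, "src_cfg"))
  doc <- list(name = cfg$name, time_mode = cfg$time_mode,
              id_systems = cfg$id_systems,
              tables = unname(cfg$tables))
  jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, null = "null",
                   digits = NA)
}

#' @rdname parse_source_config
#' @return `id_hierarchy()`: identifier system names ordered coarse to
#'   fine (by rank).
#' @export
id_hierarchy <- function(cfg) {
  if (inherits(cfg, "src_handle")) cfg <- cfg$cfg
  vapply(cfg$id_systems, `[[`, character(1), "name")
}

id_system <- function(cfg, name) {
  if (inherits(cfg, "src_handle")) cfg <- cfg$cfg
  for (s in cfg$id_systems) if (s$name == name) return(s)
  stop("unknown id system `", name, "` (known: ",
       paste(id_hierarchy(cfg), collapse = ", "), ")", call. = FALSE)
}

#' @export
print.src_cfg <- function(x, ...) {
  cat(sprintf("<src_cfg> %s (%s time)\n", x$name, x$time_mode))
  cat("  id systems:", paste(id_hierarchy(x), collapse = " < "), "\n")
  cat("  tables:    ", paste(names(x$tables), collapse = ", "), "\n")
  invisible(x)
}

#' Register a data directory for a configured source
#'
#' Verifies that every configured table file exists under `data_dir` and
#' that each header contains all declared columns (extra, undeclared
#' columns are tolerated with a warning: real EHR extracts routinely
#' carry unused columns). Returns a handle giving lazy, cached access to
#' the tables with canonical types: timestamps become integer minutes
#' (absolute mode parses ISO-8601 to minutes since 1970-01-01 UTC;
#' relative mode reads integer minutes as-is).
#'
#' @param cfg A `src_cfg` (or JSON document accepted by
#'   [parse_source_config()]).
#' @param data_dir Directory holding the CSV files.
#' @return A `src_handle`.
#' @export
register_source <- function(cfg, data_dir) {
  if (!inherits(cfg, "src_cfg")) cfg <- parse_source_config(cfg)
  if (!dir.exists(data_dir)) {
    stop("data directory does not exist: ", data_dir, call. = FALSE)
  }
  missing <- character()
  for (t in cfg$tables) {
    if (!file.exists(file.path(data_dir, t$file))) {
      missing <- c(missing, t$name)
    }
  }
  if (length(missing) > 0) {
    stop("missing table file(s) for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (t in cfg$tables) {
    hdr <- names(data.table::fread(file.path(data_dir, t$file), nrows = 0L))
    declared <- vapply(t$columns, `[[`, character(1), "name")
    absent <- setdiff(declared, hdr)
    if (length(absent) > 0) {
      stop("table `", t$name, "`: declared column(s) missing from file: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    extra <- setdiff(hdr, declared)
    if (length(extra) > 0) {
      warning("table `", t$name, "`: undeclared column(s) ignored: ",
              paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(cfg = cfg, data_dir = normalizePath(data_dir),
                 cache = new.env(parent = emptyenv())),
            class = "src_handle")
}

#' @export
print.src_handle <- function(x, ...) {
  cat(sprintf("<src_handle> %s @ %s\n", x$cfg$name, x$data_dir))
  cat("  tables:", paste(names(x$cfg$tables), collapse = ", "), "\n")
  invisible(x)
}

## epoch for absolute timestamps; only differences ever matter
parse_abs_minutes <- function(x) {
  t <- as.POSIXct(x, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                 "%Y-%m-%d"))
  as.integer(round(as.numeric(t) / 60))
}

fmt_abs_minutes <- function(m) {
  format(as.POSIXct(as.numeric(m) * 60, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%S")
}

#' Read one table through a source handle
#'
#' Columns are coerced to their declared semantic types; timestamp
#' columns become canonical integer minutes. Results are cached on the
#' handle.
#'
#' @param handle A `src_handle`.
#' @param name Declared table name.
#' @return A `data.table` restricted to the declared columns.
#' @export
src_table <- function(handle, name) {
  stopifnot(inherits(handle, "src_handle"))
  tdef <- handle$cfg$tables[[name]]
  if (is.null(tdef)) {
    stop("table `", name, "` is not declared for source `",
         handle$cfg$name, "`", call. = FALSE)
  }
  if (!is.null(handle$cache[[name]])) return(handle$cache[[name]])
  declared <- vapply(tdef$columns, `[[`, character(1), "name")
  dt <- data.table::fread(file.path(handle$data_dir, tdef$file),
                          colClasses = "character", na.strings = "")
  dt <- dt[, intersect(declared, names(dt)), with = FALSE]
  for (cc in tdef$columns) {
    v <- dt[[cc$name]]
    dt[[cc$name]] <- switch(cc$type,
      id        = suppressWarnings({
                    n <- as.integer(v)
                    if (all(is.na(n) == is.na(v))) n else v
                  }),
      timestamp = local({
                    if (identical(handle$cfg$time_mode, "absolute")) {
                      out <- rep(NA_integer_, length(v))
                      ok <- !is.na(v)
                      if (any(ok)) out[ok] <- parse_abs_minutes(v[ok])
                      out
                    } else {
                      as.integer(round(as.numeric(v)))
                    }
                  }),
      duration  = as.numeric(v),
      number    = suppressWarnings(as.numeric(v)),
      string    = v
    )
  }
  handle$cache[[name]] <- dt
  dt
}

table_default <- function(handle, table, what) {
  handle$cfg$tables[[table]]$defaults[[what]]
}

## one row per finest-level stay, carrying every system's id column and
## the per-system admission/discharge times in canonical minutes
id_map <- function(handle) {
  cfg <- handle$cfg
  if (!is.null(handle$cache[[".id_map"]])) return(handle$cache[[".id_map"]])
  systems <- cfg$id_systems
  fine <- systems[[length(systems)]]
  map <- src_table(handle, fine$origin_table)
  keep <- unique(c(vapply(systems, `[[`, character(1), "id_column"),
                   fine$start_column, fine$end_column))
  keep <- intersect(keep, names(map))
  map <- unique(map[, keep, with = FALSE])
  setnames(map, fine$start_column, paste0(fine$name, "__start"))
  if (!is.null(fine$end_column) && fine$end_column %in% names(map)) {
    setnames(map, fine$end_column, paste0(fine$name, "__end"))
  } else {
    map[[paste0(fine$name, "__end")]] <- NA_integer_
  }
  if (length(systems) > 1L) {
    for (s in rev(systems[-length(systems)])) {
      ot <- src_table(handle, s$origin_table)
      cols <- unique(c(s$id_column, s$start_column, s$end_column))
      cols <- intersect(cols, names(ot))
      ot <- unique(ot[, cols, with = FALSE])
      setnames(ot, s$start_column, paste0(s$name, "__start"))
      if (!is.null(s$end_column) && s$end_column %in% names(ot)) {
        setnames(ot, s$end_column, paste0(s$name, "__end"))
      } else {
        ot[[paste0(s$name, "__end")]] <- NA_integer_
      }
      map <- merge(map, ot, by = s$id_column, all.x = TRUE)
    }
  }
  ## unknown discharge: stay window stays open until the next stay of
  ## the same coarser id, or +Inf
  fine_end <- paste0(fine$name, "__end")
  fine_start <- paste0(fine$name, "__start")
  if (anyNA(map[[fine_end]])) {
    grp <- if (length(systems) > 1L) {
      systems[[length(systems) - 1L]]$id_column
    } else {
      character()
    }
    setorderv(map, c(grp, fine_start))
    nxt <- if (length(grp) > 0) {
      map[, data.table::shift(.SD[[1L]], type = "lead"), by = grp,
          .SDcols = fine_start]$V1
    } else {
      data.table::shift(map[[fine_start]], type = "lead")
    }
    ends <- as.numeric(map[[fine_end]])
    na <- is.na(ends)
    ends[na] <- ifelse(is.na(nxt[na]), Inf, as.numeric(nxt[na]))
    map[[fine_end]] <- ends
  }
  handle$cache[[".id_map"]] <- map
  map
}
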