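## Clinical concept dictionary: named concepts (numeric / logical /
## factor / recursive) with units, plausibility bounds, an optional OMOP
## vocabulary id, and per-source extraction rules (items).

concept_kinds <- c("num_cncpt", "lgl_cncpt", "fct_cncpt", "rec_cncpt")
item_kinds <- c("sel_itm", "col_itm")
target_kinds <- c("id_tbl", "ts_tbl", "win_tbl")

#' Construct an extraction item
#'
#' An item is one extraction rule for a concept in one source: either a
#' row selection by code (`sel_itm`: rows of `table` where `sub_var`
#' takes one of `ids`) or a whole-column read (`col_itm`). A callback
#' (function or registry reference string, see [resolve_callback()])
#' may post-process the extracted rows.
#'
#' @param src Source name the item applies to.
#' @param table Table to extract from.
#' @param sub_var Code column for `sel_itm`.
#' @param ids Codes selecting rows for `sel_itm`.
#' @param class `"sel_itm"` or `"col_itm"`; inferred from `ids` when
#'   omitted.
#' @param callback Optional callback (function or reference string).
#' @param value_column,unit_column,index_column,dur_column Optional
#'   per-item column overrides of the table defaults.
#' @return An object of class `cncpt_item`.
#' @examples
#' item("mimic", table = "chartevents", sub_var = "itemid",
#'      ids = c(211, 220045))
#' @export
item <- function(src, table, sub_var = NULL, ids = NULL, class = NULL,
                 callback = NULL, value_column = NULL, unit_column = NULL,
                 index_column = NULL, dur_column = NULL) {
  if (is.null(class)) {
    class <- if (is.null(ids)) "col_itm" else "sel_itm"
  }
  it <- structure(
    list(src = src, kind = class, table = table, sub_var = sub_var,
         ids = ids, callback = callback, value_column = value_column,
         unit_column = unit_column, index_column = index_column,
         dur_column = dur_column),
    class = "cncpt_item")
  validate_item(it)
  it
}

validate_item <- function(it, where = it$table) {
  if (!it$kind %in% item_kinds) {
    stop("item (", where, "): unknown item class `", it$kind, "`",
         call. = FALSE)
  }
  if (identical(it$kind, "sel_itm")) {
    if (is.null(it$sub_var) || length(it$ids) == 0L) {
      stop("item (", where, "): sel_itm requires `sub_var` and non-empty ",
           "`ids`", call. = FALSE)
    }
  } else {
    if (!is.null(it$sub_var) || length(it$ids) > 0L) {
      stop("item (", where, "): col_itm takes neither `sub_var` nor `ids`",
           call. = FALSE)
    }
  }
  if (!is.null(it$callback) && !callback_exists(it$callback)) {
    stop("item (", where, "): callback reference `",
         if (is.character(it$callback)) it$callback else "<function>",
         "` does not resolve", call. = FALSE)
  }
  invisible(it)
}

#' Construct a clinical concept
#'
#' @param name Abbreviated concept name (the result's column name).
#' @param items For atomic concepts: a `cncpt_item`, or list of them
#'   (each carrying its source name).
#' @param description Free-text description.
#' @param class One of `"num_cncpt"` (numeric, with optional
#'   plausibility bounds), `"lgl_cncpt"` (logical), `"fct_cncpt"`
#'   (categorical with allowed `levels`), `"rec_cncpt"` (recursive:
#'   computed from other concepts by a callback).
#' @param category Dictionary category (e.g. `"vitals"`).
#' @param unit Accepted unit strings (first entry is canonical).
#' @param min,max Plausibility bounds; out-of-bounds values are removed.
#' @param levels Allowed values for `fct_cncpt`.
#' @param target Result kind: `"id_tbl"`, `"ts_tbl"` or `"win_tbl"`.
#' @param aggregate Aggregation name (see [aggregate_by()]); `NULL`
#'   selects a type-based default.
#' @param omopid Optional integer OMOP vocabulary concept id.
#' @param depends For `rec_cncpt`: names of the concepts it builds on.
#' @param callback For `rec_cncpt` (and optionally others): callback
#'   computing the concept from its dependencies.
#' @return An object of class `cncpt`.
#' @examples
#' hr_item <- item("mimic", table = "chartevents", sub_var = "itemid",
#'                 ids = c(211, 220045))
#' concept("hr", hr_item, "heart rate", unit = c("bpm", "/min"),
#'         min = 0, max = 300, omopid = 4239408,
#'         category = "routine vital signs")
#' @export
concept <- function(name, items = NULL, description = "",
                    class = "num_cncpt", category = "misc", unit = NULL,
                    min = NULL, max = NULL, levels = NULL,
                    target = "ts_tbl", aggregate = NULL, omopid = NULL,
                    depends = NULL, callback = NULL) {
  if (inherits(items, "cncpt_item")) items <- list(items)
  sources <- list()
  for (it in items) {
    sources[[it$src]] <- c(sources[[it$src]], list(it))
  }
  cn <- structure(
    list(name = name, kind = class, omopid = omopid,
         description = description, category = category,
         unit = unit, min = min, max = max, levels = levels,
         target = target, aggregate = aggregate, sources = sources,
         depends = depends, callback = callback),
    class = "cncpt")
  validate_concept(cn)
  cn
}

validate_concept <- function(cn) {
  nm <- cn$name
  if (!cn$kind %in% concept_kinds) {
    stop("concept `", nm, "`: unknown class `", cn$kind, "`", call. = FALSE)
  }
  if (!cn$target %in% target_kinds) {
    stop("concept `", nm, "`: unknown target `", cn$target, "`",
         call. = FALSE)
  }
  if (identical(cn$kind, "rec_cncpt")) {
    if (length(cn$depends) == 0L) {
      stop("concept `", nm, "`: rec_cncpt requires dependency concepts",
           call. = FALSE)
    }
    if (length(cn$sources) > 0L) {
      stop("concept `", nm, "`: rec_cncpt takes no sources", call. = FALSE)
    }
    if (is.null(cn$callback)) {
      stop("concept `", nm, "`: rec_cncpt requires a callback", call. = FALSE)
    }
  } else {
    if (length(cn$depends) > 0L) {
      stop("concept `", nm, "`: only rec_cncpt may declare dependencies",
           call. = FALSE)
    }
    if (is.null(cn$sources)) {
      stop("concept `", nm, "`: atomic concepts require a sources mapping",
           call. = FALSE)
    }
  }
  if (identical(cn$kind, "lgl_cncpt") &&
      (!is.null(cn$unit) || !is.null(cn$min) || !is.null(cn$max))) {
    stop("concept `", nm, "`: lgl_cncpt has no unit or bounds",
         call. = FALSE)
  }
  if (!is.null(cn$min) && !is.null(cn$max) && cn$min > cn$max) {
    stop("concept `", nm, "`: min exceeds max", call. = FALSE)
  }
  if (!is.null(cn$callback) && !callback_exists(cn$callback)) {
    stop("concept `", nm, "`: callback `", cn$callback,
         "` does not resolve", call. = FALSE)
  }
  for (src in names(cn$sources)) {
    for (it in cn$sources[[src]]) {
      validate_item(it, where = paste0(nm, "/", src))
    }
  }
  invisible(cn)
}

#' @export
print.cncpt <- function(x, ...) {
  cat(sprintf("<%s> %s%s: %s [%s]\n", x$kind, x$name,
              if (is.null(x$omopid)) "" else paste0(" (omop ", x$omopid, ")"),
              x$description, x$category))
  invisible(x)
}

parse_concept_entry <- function(name, e) {
  kind <- if (is.null(e$class)) "num_cncpt" else e$class
  items <- NULL
  if (!is.null(e$sources)) {
    items <- list()
    for (src in names(e$sources)) {
      for (raw in e$sources[[src]]) {
        items <- c(items, list(item(
          src = src, table = raw$table, sub_var = raw$sub_var,
          ids = if (is.null(raw$ids)) NULL else unlist(raw$ids),
          class = raw$class, callback = raw$callback,
          value_column = raw$value_column, unit_column = raw$unit_column,
          index_column = raw$index_column, dur_column = raw$dur_column)))
      }
    }
  }
  concept(
    name = name, items = items,
    description = if (is.null(e$description)) "" else e$description,
    class = kind,
    category = if (is.null(e$category)) "misc" else e$category,
    unit = if (is.null(e$unit)) NULL else unlist(e$unit),
    min = e$min, max = e$max,
    levels = if (is.null(e$levels)) NULL else unlist(e$levels),
    target = if (is.null(e$target)) "ts_tbl" else e$target,
    aggregate = e$aggregate, omopid = e$omopid,
    depends = if (is.null(e$concepts)) NULL else unlist(e$concepts),
    callback = e$callback)
}

#' Parse concept-dictionary documents
#'
#' Each document is a JSON object mapping concept names to definitions
#' (see the package vignette for the format; the `"hr"` example in
#' [concept()] shows the JSON fields). Later documents override earlier
#' ones per concept name, which is how user dictionaries extend or
#' modify the shipped one; provenance records each concept's origin and
#' any override.
#'
#' @param docs A character vector / list of JSON texts or file paths.
#' @param labels Optional provenance labels (defaults to file paths or
#'   positional labels).
#' @return A `concept_dict`.
#' @export
parse_dictionary <- function(docs, labels = NULL) {
  if (is.character(docs)) docs <- as.list(docs)
  if (is.null(labels)) {
    labels <- vapply(seq_along(docs), function(i) {
      d <- docs[[i]]
      if (is.character(d) && length(d) == 1L && file.exists(d) &&
          !grepl("^\\s*\\{", d)) d else sprintf("document %d", i)
    }, character(1))
  }
  concepts <- list()
  provenance <- character()
  for (i in seq_along(docs)) {
    doc <- coerce_json(docs[[i]])
    for (nm in names(doc)) {
      cn <- parse_concept_entry(nm, doc[[nm]])
      if (nm %in% names(concepts)) {
        provenance[[nm]] <- paste0(labels[[i]], " (overrides ",
                                   provenance[[nm]], ")")
      } else {
        provenance[[nm]] <- labels[[i]]
      }
      concepts[[nm]] <- cn
    }
  }
  dict <- structure(list(concepts = concepts, provenance = provenance),
                    class = "concept_dict")
  validate_dictionary(dict)
  dict
}

validate_dictionary <- function(dict) {
  omop <- vapply(dict$concepts, function(c) {
    if (is.null(c$omopid)) NA_integer_ else as.integer(c$omopid)
  }, integer(1))
  dup <- omop[!is.na(omop)][duplicated(omop[!is.na(omop)])]
  if (length(dup) > 0) {
    stop("duplicate omopid(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  topo_order(dict)  # errors on cycles
  invisible(dict)
}

## topological order of recursive concepts; errors listing any cycle
topo_order <- function(dict) {
  deps <- lapply(dict$concepts, function(c) {
    intersect(c$depends, names(dict$concepts))
  })
  order <- character()
  state <- setNames(rep(0L, length(deps)), names(deps))  # 0 new 1 open 2 done
  visit <- function(nm, path) {
    if (state[[nm]] == 2L) return(invisible(NULL))
    if (state[[nm]] == 1L) {
      cyc <- c(path[which(path == nm)[1L]:length(path)], nm)
      stop("dependency cycle among recursive concepts: ",
           paste(cyc, collapse = " -> "), call. = FALSE)
    }
    state[[nm]] <<- 1L
    for (d in deps[[nm]]) visit(d, c(path, nm))
    state[[nm]] <<- 2L
    order <<- c(order, nm)
  }
  for (nm in names(deps)) visit(nm, character())
  order
}

#' @export
print.concept_dict <- function(x, ...) {
  s <- dict_stats(x)
  cat(sprintf("<concept_dict> %d concepts (%d atomic, %d recursive)\n",
              s$total, s$atomic, s$recursive))
  invisible(x)
}

#' Look up a concept by name or OMOP id
#'
#' @param dict A `concept_dict`.
#' @param key Abbreviated name string or integer OMOP concept id.
#' @return The matching `cncpt`; unknown keys raise an error listing
#'   near matches.
#' @examples \dontrun{
#' find_concept(load_dictionary(), "lact")
#' find_concept(load_dictionary(), 4191725)
#' }
#' @export
find_concept <- function(dict, key) {
  stopifnot(inherits(dict, "concept_dict"))
  if (is.numeric(key)) {
    for (cn in dict$concepts) {
      if (!is.null(cn$omopid) && cn$omopid == key) return(cn)
    }
    stop("no concept with omopid ", key, call. = FALSE)
  }
  cn <- dict$concepts[[key]]
  if (!is.null(cn)) return(cn)
  near <- agrep(key, names(dict$concepts), max.distance = 0.3,
                value = TRUE)
  stop("unknown concept `", key, "`",
       if (length(near) > 0) paste0("; did you mean: ",
                                    paste(head(near, 5), collapse = ", "),
                                    "?"),
       call. = FALSE)
}

#' Dictionary composition report
#'
#' @param dict A `concept_dict`.
#' @param sources Sources to report availability for; defaults to every
#'   source referenced by any item.
#' @return A list with `total`, `atomic` and `recursive` counts,
#'   `by_category` (named integer vector) and `by_source` (atomic
#'   concepts with at least one item for that source).
#' @export
dict_stats <- function(dict, sources = NULL) {
  cs <- dict$concepts
  kinds <- vapply(cs, `[[`, character(1), "kind")
  cats <- vapply(cs, `[[`, character(1), "category")
  atomic <- cs[kinds != "rec_cncpt"]
  if (is.null(sources)) {
    sources <- sort(unique(unlist(lapply(atomic, function(c) {
      names(c$sources)
    }))))
  }
  by_source <- vapply(sources, function(s) {
    sum(vapply(atomic, function(c) length(c$sources[[s]]) > 0L, logical(1)))
  }, integer(1))
  list(total = length(cs),
       atomic = sum(kinds != "rec_cncpt"),
       recursive = sum(kinds == "rec_cncpt"),
       by_category = c(table(cats)),
       by_source = by_source)
}

#' Serialize a dictionary back to JSON
#'
#' Produces the normalized document form; parsing the output again
#' yields an equivalent dictionary (round-trip identity on the
#' normalized representation).
#'
#' @param dict A `concept_dict`.
#' @return JSON text.
#' @export
serialize_dictionary <- function(dict) {
  out <- lapply(dict$concepts, concept_to_entry)
  jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE, null = "null",
                   digits = NA)
}

concept_to_entry <- function(cn) {
  e <- list(class = cn$kind, description = cn$description,
            category = cn$category)
  if (!is.null(cn$unit)) e$unit <- as.list(cn$unit)
  if (!is.null(cn$min)) e$min <- cn$min
  if (!is.null(cn$max)) e$max <- cn$max
  if (!is.null(cn$levels)) e$levels <- as.list(cn$levels)
  if (!is.null(cn$omopid)) e$omopid <- cn$omopid
  e$target <- cn$target
  if (!is.null(cn$aggregate)) e$aggregate <- cn$aggregate
  if (identical(cn$kind, "rec_cncpt")) {
    e$concepts <- as.list(cn$depends)
    e$callback <- cn$callback
  } else {
    e$sources <- lapply(cn$sources, function(items) {
      lapply(items, function(it) {
        o <- list(table = it$table, class = it$kind)
        if (!is.null(it$sub_var)) o$sub_var <- it$sub_var
        if (length(it$ids) > 0) o$ids <- as.list(it$ids)
        for (f in c("callback", "value_column", "unit_column",
                    "index_column", "dur_column")) {
          if (!is.null(it[[f]]) && is.character(it[[f]])) o[[f]] <- it[[f]]
        }
        o
      })
    })
  }
  e
}

#' Build a dictionary from programmatically constructed concepts
#'
#' Companion to [concept()] / [item()]: wraps a list of concepts into a
#' validated `concept_dict`, the form [load_concepts()] expects.
#'
#' @param concepts A `cncpt` or list of them.
#' @param label Provenance label.
#' @return A `concept_dict`.
#' @export
as_concept_dict <- function(concepts, label = "programmatic") {
  if (inherits(concepts, "cncpt")) concepts <- list(concepts)
  names(concepts) <- vapply(concepts, `[[`, character(1), "name")
  dict <- structure(
    list(concepts = concepts,
         provenance = setNames(rep(label, length(concepts)),
                               names(concepts))),
    class = "concept_dict")
  validate_dictionary(dict)
  dict
}

#' Locate and load user dictionary documents
#'
#' Consults the `ICUHARM_CONFIG_PATH` environment variable (a
#' `.Platform$path.sep`-separated list of directories) and returns the
#' paths of every readable `*.json` file found, in stable order. These
#' are appended after the shipped dictionary by [load_dictionary()], so
#' user concepts extend or override shipped ones.
#'
#' @param env_var Name of the environment variable to consult.
#' @return Character vector of dictionary file paths (possibly empty).
#' @export
discover_user_dictionaries <- function(env_var = "ICUHARM_CONFIG_PATH") {
  val <- Sys.getenv(env_var, unset = "")
  if (!nzchar(val)) return(character())
  dirs <- strsplit(val, .Platform$path.sep, fixed = TRUE)[[1L]]
  out <- character()
  for (d in dirs) {
    if (!dir.exists(d)) {
      warning("dictionary path does not exist, skipped: ", d, call. = FALSE)
      next
    }
    files <- sort(list.files(d, pattern = "\\.json$", full.names = TRUE))
    for (f in files) {
      ok <- tryCatch({ jsonlite::fromJSON(f, simplifyVector = FALSE); TRUE },
                     error = function(e) FALSE)
      if (!ok) {
        warning("unreadable dictionary file, skipped: ", f, call. = FALSE)
      } else {
        out <- c(out, f)
      }
    }
  }
  out
}

shipped_dictionary_files <- function() {
  dir <- system.file("extdata", "dictionary", package = "icuharm")
  sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
}

#' Load the shipped dictionary (plus user extensions)
#'
#' Reads the dictionary files shipped with the package and, when
#' `include_user = TRUE`, appends any documents found through
#' [discover_user_dictionaries()], whose concepts override shipped ones
#' of the same name.
#'
#' @param include_user Also consult `ICUHARM_CONFIG_PATH`.
#' @param extra Additional documents (texts or paths) appended last.
#' @return A `concept_dict`.
#' @export
load_dictionary <- function(include_user = TRUE, extra = NULL) {
  docs <- shipped_dictionary_files()
  if (include_user) docs <- c(docs, discover_user_dictionaries())
  docs <- c(as.list(docs), as.list(extra))
  parse_dictionary(docs)
}
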