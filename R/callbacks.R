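## Callback references in dictionary JSON are strings resolved against a
## named registry: either a bare registered callback name ("ins_cb") or
## a one-argument factory application ("transform_fun(grep_diab)").
## No arbitrary code is ever evaluated out of JSON.

.registry <- new.env(parent = emptyenv())
.registry$callbacks <- list()   # name -> function(rows/deps, ctx)
.registry$factories <- list()   # name -> function(fun) -> callback
.registry$funs <- list()        # name -> pure elementwise function
.registry$units <- data.frame(from = character(), to = character(),
                              factor = numeric())

#' Register and resolve dictionary callbacks
#'
#' Dictionary documents refer to preprocessing callbacks by name. The
#' registry maps those strings to functions; a tiny reference grammar
#' supports bare names (`"ins_cb"`) and single-argument factory
#' applications (`"transform_fun(grep_diab)"`) -- nothing else, so no
#' arbitrary code can be smuggled in through JSON.
#'
#' @param name Registry name.
#' @param fun The function to register.
#' @param overwrite Allow replacing an existing entry.
#' @return `register_callback()` and friends: the name, invisibly.
#'   `resolve_callback()`: the callback function.
#' @export
register_callback <- function(name, fun, overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  if (!overwrite && !is.null(.registry$callbacks[[name]])) {
    stop("callback `", name, "` is already registered", call. = FALSE)
  }
  .registry$callbacks[[name]] <- fun
  invisible(name)
}

#' @rdname register_callback
#' @export
register_factory <- function(name, fun, overwrite = FALSE) {
  if (!overwrite && !is.null(.registry$factories[[name]])) {
    stop("factory `", name, "` is already registered", call. = FALSE)
  }
  .registry$factories[[name]] <- fun
  invisible(name)
}

#' @rdname register_callback
#' @export
resolve_callback <- function(name) {
  if (is.function(name)) return(name)
  stopifnot(is.character(name), length(name) == 1L)
  m <- regmatches(name, regexec("^([A-Za-z0-9_.]+)\\(([A-Za-z0-9_.]+)\\)$",
                                name))[[1L]]
  if (length(m) == 3L) {
    fac <- .registry$factories[[m[2L]]]
    if (is.null(fac)) {
      stop("unknown callback factory `", m[2L], "`", call. = FALSE)
    }
    f <- .registry$funs[[m[3L]]]
    if (is.null(f)) {
      stop("unknown function `", m[3L], "` in callback reference `",
           name, "`", call. = FALSE)
    }
    return(fac(f))
  }
  if (!grepl("^[A-Za-z0-9_.]+$", name)) {
    stop("malformed callback reference `", name, "`", call. = FALSE)
  }
  cb <- .registry$callbacks[[name]]
  if (is.null(cb)) {
    stop("unknown callback `", name, "`", call. = FALSE)
  }
  cb
}

#' @rdname register_callback
#' @export
callback_exists <- function(name) {
  if (is.function(name)) return(TRUE)
  ok <- tryCatch({ resolve_callback(name); TRUE },
                 error = function(e) FALSE)
  ok
}

#' Build a value-transforming item callback
#'
#' `transform_fun(f)` wraps a pure elementwise function `f` into an item
#' callback that applies it to the extracted value column -- e.g.
#' turning ICD-9 code strings into a logical diabetes indicator.
#' `make_transform_callback()` registers such a function under a name so
#' JSON dictionaries can reference it as `"transform_fun(<name>)"`.
#'
#' @param f A pure elementwise function.
#' @param name Name to register `f` under.
#' @param overwrite Allow replacing an existing entry.
#' @return `transform_fun()`: an item callback. `make_transform_callback()`:
#'   the reference string `"transform_fun(<name>)"`.
#' @examples
#' grep_diab <- function(x) grepl("^250\\.?[0-9]{2}$", x)
#' cb <- transform_fun(grep_diab)
#' @export
transform_fun <- function(f) {
  stopifnot(is.function(f))
  function(rows, ctx = NULL) {
    rows$value <- f(rows$value)
    rows
  }
}

#' @rdname transform_fun
#' @export
make_transform_callback <- function(name, f, overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, is.function(f))
  if (!overwrite && !is.null(.registry$funs[[name]])) {
    stop("function `", name, "` is already registered", call. = FALSE)
  }
  .registry$funs[[name]] <- f
  invisible(paste0("transform_fun(", name, ")"))
}

#' Register a measurement-unit conversion
#'
#' Conversions rescale values reported in a convertible unit into a
#' concept's accepted unit during harmonization (e.g. creatinine in
#' umol/L divided by 88.42 gives mg/dL). Unit strings are compared
#' case-insensitively.
#'
#' @param from,to Unit strings.
#' @param factor Multiplicative factor applied to values in `from`.
#' @return The conversion table, invisibly.
#' @export
register_unit_conversion <- function(from, to, factor) {
  .registry$units <- rbind(
    .registry$units,
    data.frame(from = tolower(from), to = tolower(to), factor = factor))
  invisible(.registry$units)
}

find_unit_conversion <- function(from, to_set) {
  u <- .registry$units
  hit <- u[u$from == tolower(from) & u$to %in% tolower(to_set), , drop = FALSE]
  if (nrow(hit) == 0L) return(NULL)
  hit[1L, ]
}

## ---- shipped item callbacks -------------------------------------------

## ICD-9 diabetes codes: 250 followed by exactly two digits (optionally
## dot-separated), e.g. "25012" or "250.01" but not "2501"
grep_diab <- function(x) grepl("^250\\.?[0-9]{2}$", x)

## a timestamp-valued column (e.g. death time) becomes a TRUE flag at
## that time; rows without a time are dropped
cb_death_flag <- function(rows, ctx = NULL) {
  rows <- rows[!is.na(rows$value)]
  rows$time <- as.integer(round(as.numeric(rows$value)))
  rows$value <- rep(TRUE, nrow(rows))
  rows
}

## presence rows (e.g. culture sampling events) become TRUE flags
cb_flag_true <- function(rows, ctx = NULL) {
  rows$value <- rep(TRUE, nrow(rows))
  rows
}

register_shipped_callbacks <- function() {
  make_transform_callback("grep_diab", grep_diab, overwrite = TRUE)
  make_transform_callback("identity", identity, overwrite = TRUE)
  register_factory("transform_fun", transform_fun, overwrite = TRUE)
  register_callback("death_flag", cb_death_flag, overwrite = TRUE)
  register_callback("flag_true", cb_flag_true, overwrite = TRUE)
  register_clinical_callbacks()
  register_unit_conversion("umol/l", "mg/dl", 1 / 88.42)
  register_unit_conversion("g/l", "g/dl", 1 / 10)
  register_unit_conversion("mmhg", "mm hg", 1)
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  register_shipped_callbacks()
}
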