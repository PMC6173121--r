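#' @title Typed cell coercion
#' @description
#' Cells in a Rearrangement TSV are parsed according to the value kind
#' of their column.  The empty string is the universal null encoding:
#' `""` maps to `NA` for every kind, and `NA` renders back to `""`.
#' Coordinates are integers constrained to be >= 1 (the format uses
#' 1-based closed intervals throughout).
#' @name coercion
NULL

typed_na <- function(kind) {
  switch(kind,
    integer = NA_integer_, coordinate = NA_integer_,
    number = NA_real_, boolean = NA,
    NA_character_)
}

BOOL_TRUE <- c("T", "TRUE", "true")
BOOL_FALSE <- c("F", "FALSE", "false")

#' Coerce a whole character column to its typed form.
#' Returns list(values, bad = integer indices of unparseable non-empty
#' cells, detail = short description of the expected form).
#' @noRd
coerce_column <- function(x, kind) {
  isnull <- !nzchar(x) | is.na(x)
  bad <- integer(0)
  detail <- ""
  values <- switch(kind,
    integer = {
      ok <- grepl("^[+-]?[0-9]+$", x)
      bad <- which(!isnull & !ok)
      detail <- "an integer"
      suppressWarnings(as.integer(ifelse(ok, x, NA)))
    },
    coordinate = {
      ok <- grepl("^[+-]?[0-9]+$", x)
      v <- suppressWarnings(as.integer(ifelse(ok, x, NA)))
      ok <- ok & !is.na(v) & v >= 1L
      bad <- which(!isnull & !ok)
      detail <- "a 1-based coordinate (integer >= 1)"
      ifelse(ok, v, NA_integer_)
    },
    number = {
      v <- suppressWarnings(as.numeric(x))
      bad <- which(!isnull & is.na(v))
      detail <- "a number"
      v
    },
    boolean = {
      v <- rep(NA, length(x))
      v[x %in% BOOL_TRUE] <- TRUE
      v[x %in% BOOL_FALSE] <- FALSE
      bad <- which(!isnull & is.na(v))
      detail <- "a boolean (T/TRUE/true or F/FALSE/false)"
      v
    },
    # text, sequences, cigar_text: kept verbatim
    ifelse(isnull, NA_character_, x)
  )
  values[isnull] <- typed_na(kind)
  list(values = values, bad = bad, detail = detail)
}

#' Coerce one raw cell string to a typed value
#'
#' @param raw a tab-free cell string as read from a TSV.
#' @param kind one of the schema value kinds (see [airr_schema]).
#' @return the typed value, or `NA` if `raw` is the empty string.
#' @examples
#' coerce_value("42", "coordinate")
#' coerce_value("", "integer")    # NA: empty string is null
#' @export
coerce_value <- function(raw, kind) {
  stopifnot(length(raw) == 1L, kind %in% VALUE_KINDS)
  res <- coerce_column(as.character(raw), kind)
  if (length(res$bad)) {
    abort_airr(sprintf("cannot parse %s as %s (expected %s)",
                       deparse(raw), kind, res$detail),
               "airr_coercion_error", kind = kind, text = raw)
  }
  res$values[[1L]]
}

#' Render a typed value back to its on-disk cell string
#'
#' The inverse of [coerce_value()]: `NA` renders as `""`, booleans as
#' the canonical `"T"`/`"F"`, and numbers with full precision so that
#' read/write round trips are value-exact.
#'
#' @inheritParams coerce_value
#' @param value a typed value (or `NA`).
#' @export
render_value <- function(value, kind) {
  stopifnot(length(value) == 1L)
  render_column(value, kind, "<value>")[[1L]]
}

render_column <- function(x, kind, field) {
  out <- switch(kind,
    boolean = ifelse(is.na(x), "", ifelse(x, "T", "F")),
    integer = ,
    coordinate = ,
    number = ifelse(is.na(x), "", as.character(x)),
    {
      x <- as.character(x)
      bad <- which(!is.na(x) & grepl("[\t\n\r]", x))
      if (length(bad)) {
        abort_airr(sprintf(
          "field '%s', record %d: values must not contain tabs or newlines",
          field, bad[1L]), "airr_render_error", field = field,
          record_index = bad[1L])
      }
      ifelse(is.na(x), "", x)
    })
  if (kind == "coordinate" && any(!is.na(x) & x < 1)) {
    abort_airr(sprintf("field '%s': coordinates must be >= 1", field),
               "airr_render_error", field = field)
  }
  out
}
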