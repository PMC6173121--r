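#' Write rearrangement records as a Rearrangement TSV
#'
#' The header is emitted in canonical order: declared schema fields
#' first (schema-document order), then custom columns in their current
#' order.  Nulls (`NA`) are rendered as empty strings, booleans as
#' `"T"`/`"F"`, and the line terminator is `"\n"`, so output is
#' byte-stable for identical input.  Values containing tabs or
#' newlines are rejected (the dialect has no quoting — that is what
#' keeps a newline an unambiguous record boundary).  The file is
#' written atomically (temp file + rename).
#'
#' @param x a data frame of typed records (as from
#'   [read_rearrangements()] or [simulate_dataset()]).
#' @param path destination file.
#' @param schema an `airr_schema`.
#' @return the number of data rows written, invisibly.
#' @export
write_rearrangements <- function(x, path, schema = default_schema()) {
  stopifnot(is.data.frame(x))
  declared <- intersect(schema$fields$name, names(x))
  custom <- setdiff(names(x), declared)
  cols <- c(declared, custom)

  rendered <- lapply(cols, function(nm) {
    kind <- if (nm %in% declared) field_kind(schema, nm) else "text"
    render_column(x[[nm]], kind, nm)
  })
  header <- paste(cols, collapse = "\t")
  body <- if (nrow(x) > 0L) do.call(paste, c(rendered, sep = "\t")) else character(0)
  write_atomic(path, function(tmp) {
    con <- file(tmp, "wb")
    on.exit(close(con))
    writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  })
  invisible(nrow(x))
}
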