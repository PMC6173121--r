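#' @title Reading Rearrangement TSV files
#' @description
#' Files are UTF-8, tab-delimited, with a mandatory header row of
#' unique column names and no quoting or escaping: tabs and newlines
#' are forbidden inside values, so a newline is always a record
#' boundary (this is what keeps the format splittable).  Readers accept
#' any column order; declared columns are typed per the schema and
#' unknown columns are carried through untyped as custom fields.
#' @name tsv-reading
NULL

new_issues <- function(rule_id = character(), severity = character(),
                       record_index = integer(), field = character(),
                       message = character()) {
  data.frame(rule_id = rule_id, severity = severity,
             record_index = record_index, field = field, message = message,
             stringsAsFactors = FALSE)
}

issue_row <- function(rule_id, severity, record_index, field, message) {
  new_issues(rule_id, severity,
             if (is.null(record_index)) NA_integer_ else as.integer(record_index),
             if (is.null(field)) NA_character_ else field,
             message)
}

bind_issues <- function(issues) {
  if (length(issues) == 0L) return(new_issues())
  do.call(rbind, issues)
}

parse_header_line <- function(line, path = "<stream>") {
  if (length(line) == 0L || !nzchar(line[[1L]])) {
    abort_airr(sprintf("'%s': missing header line", path), "airr_header_error")
  }
  cols <- strsplit(sub("\r$", "", line[[1L]]), "\t", fixed = TRUE)[[1L]]
  if (anyDuplicated(cols)) {
    abort_airr(sprintf("'%s': duplicate column name(s): %s", path,
                       paste(unique(cols[duplicated(cols)]), collapse = ", ")),
               "airr_header_error")
  }
  cols
}

# Split data lines into a cell matrix, preserving trailing empty cells
# (a sentinel is appended before strsplit, which would otherwise drop
# them).  Returns list(cells = list of character vectors, nfield).
split_cells <- function(lines) {
  sp <- strsplit(paste0(lines, "\t\x01"), "\t", fixed = TRUE)
  lapply(sp, function(x) x[-length(x)])
}

#' Parse already-read data lines against a known header.
#' Returns list(records = typed data frame, issues).
#' @noRd
parse_record_lines <- function(lines, columns, schema, strict = TRUE,
                               first_index = 1L) {
  issues <- list()
  ncol_exp <- length(columns)
  cells <- split_cells(lines)
  widths <- lengths(cells)
  bad_rows <- which(widths != ncol_exp)
  if (length(bad_rows)) {
    if (strict) {
      abort_airr(sprintf(
        "record %d has %d cells, expected %d",
        first_index + bad_rows[1L] - 1L, widths[bad_rows[1L]], ncol_exp),
        "airr_row_error", record_index = first_index + bad_rows[1L] - 1L)
    }
    issues <- c(issues, lapply(bad_rows, function(i) {
      issue_row("ROW_WIDTH", "error", first_index + i - 1L, NULL,
                sprintf("row has %d cells, expected %d", widths[i], ncol_exp))
    }))
    cells <- cells[-bad_rows]
  }
  kept_index <- setdiff(seq_along(lines), bad_rows)

  # uniform widths from here on: one unlist + matrix beats per-cell access
  raw_cols <- if (length(cells)) {
    m <- matrix(unlist(cells, use.names = FALSE), nrow = ncol_exp)
    lapply(seq_len(ncol_exp), function(j) m[j, ])
  } else {
    rep(list(character(0)), ncol_exp)
  }
  names(raw_cols) <- columns

  declared <- schema$fields$name[schema$fields$name %in% columns]
  custom <- setdiff(columns, declared)

  out <- list()
  for (nm in declared) {
    kind <- field_kind(schema, nm)
    res <- coerce_column(raw_cols[[nm]], kind)
    if (length(res$bad)) {
      if (strict) {
        i <- res$bad[1L]
        abort_airr(sprintf(
          "record %d, field '%s': cannot parse %s as %s (expected %s)",
          first_index + kept_index[i] - 1L, nm,
          deparse(raw_cols[[nm]][i]), kind, res$detail),
          "airr_coercion_error", field = nm, kind = kind,
          text = raw_cols[[nm]][res$bad[1L]])
      }
      issues <- c(issues, lapply(res$bad, function(i) {
        issue_row("TYPE", "error", first_index + kept_index[i] - 1L, nm,
                  sprintf("cannot parse %s as %s",
                          deparse(raw_cols[[nm]][i]), kind))
      }))
      res$values[res$bad] <- typed_na(kind)
    }
    out[[nm]] <- res$values
  }
  for (nm in custom) {
    x <- raw_cols[[nm]]
    x[!nzchar(x)] <- NA_character_
    out[[nm]] <- x
  }
  # missing required columns: null-filled with the right type
  missing_req <- setdiff(required_fields(schema), columns)
  for (nm in missing_req) {
    out[[nm]] <- rep(typed_na(field_kind(schema, nm)), length(cells))
  }
  # canonical order: declared fields in schema order, then customs
  order_cols <- c(intersect(schema$fields$name, names(out)), custom)
  records <- structure(out[order_cols], names = order_cols,
                       class = "data.frame",
                       row.names = seq_along(cells))
  list(records = records, issues = bind_issues(issues))
}

#' Read a Rearrangement TSV file
#'
#' @param path file path; plain, gzip-, bzip2-, or BGZF-compressed
#'   input is decompressed transparently for sequential reads.
#' @param schema an `airr_schema`; defaults to the bundled catalogue.
#' @param strict if `TRUE` (the default), missing required columns,
#'   malformed rows, and unparseable cells abort with a classed error;
#'   if `FALSE` they are reported in the `issues` attribute, malformed
#'   rows are skipped, and bad cells become null.
#' @return a typed data frame, one row per rearrangement record, with
#'   declared columns in canonical schema order followed by custom
#'   columns in first-seen order.  Attributes: `header` (original
#'   column order) and `issues` (a data frame of read-time issues).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("sequence_id\tjunction_length", "r1\t21", "r2\t"), f)
#' x <- read_rearrangements(f, strict = FALSE)
#' x$junction_length   # 21 NA
#' @export
read_rearrangements <- function(path, schema = default_schema(),
                                strict = TRUE) {
  lines <- read_source_lines(path)
  if (length(lines) == 0L) {
    abort_airr(sprintf("'%s': empty file (no header)", path),
               "airr_header_error")
  }
  columns <- parse_header_line(lines[1L], path)
  header_issues <- validate_header(columns, schema)
  missing_req <- setdiff(required_fields(schema), columns)
  if (strict && length(missing_req)) {
    abort_airr(sprintf("'%s': missing required column(s): %s", path,
                       paste(missing_req, collapse = ", ")),
               "airr_header_error", missing = missing_req)
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  res <- parse_record_lines(body, columns, schema, strict = strict)
  structure(res$records,
            header = columns,
            issues = rbind(header_issues, res$issues))
}

#' Streaming chunked access to a Rearrangement TSV
#'
#' Returns a closure that yields successive chunks of typed records
#' (data frames of at most `chunk_size` rows) and `NULL` at end of
#' input, so that arbitrarily large files can be processed in constant
#' memory.  Used by [validate_file()].
#'
#' @inheritParams read_rearrangements
#' @param chunk_size rows per chunk.
#' @return a function `f()` yielding data frames then `NULL`; the
#'   chunk carries an `issues` attribute and a `first_index` attribute
#'   (1-based record index of its first row).
#' @export
rearrangement_reader <- function(path, schema = default_schema(),
                                 strict = FALSE, chunk_size = 2000L) {
  src <- open_source(path)
  con <- src$open()
  first <- readLines(con, n = 1L, warn = FALSE)
  if (length(first) == 0L) {
    close(con)
    abort_airr(sprintf("'%s': empty file (no header)", path),
               "airr_header_error")
  }
  columns <- parse_header_line(first, path)
  header_issues <- validate_header(columns, schema)
  if (strict && length(setdiff(required_fields(schema), columns))) {
    close(con)
    abort_airr(sprintf("'%s': missing required column(s): %s", path,
                       paste(setdiff(required_fields(schema), columns),
                             collapse = ", ")),
               "airr_header_error")
  }
  index <- 1L
  done <- FALSE
  emitted_header <- FALSE
  function() {
    if (done) return(NULL)
    lines <- readLines(con, n = chunk_size, warn = FALSE)
    lines <- sub("\r$", "", lines)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) {
      done <<- TRUE
      close(con)
      return(NULL)
    }
    res <- parse_record_lines(lines, columns, schema, strict = strict,
                              first_index = index)
    issues <- res$issues
    if (!emitted_header) {
      issues <- rbind(header_issues, issues)
      emitted_header <<- TRUE
    }
    chunk <- structure(res$records, issues = issues, first_index = index,
                       header = columns)
    index <<- index + length(lines)
    chunk
  }
}
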