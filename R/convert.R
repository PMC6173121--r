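#' @title Mapping-driven conversion of legacy dialects
#' @description
#' Legacy tabular annotation formats (Change-O-like, IgBLAST-like,
#' IMGT-summary-like) differ from the Rearrangement format in column
#' names, null tokens, coordinate conventions (start+length vs closed
#' intervals, 0- vs 1-based), boolean spellings, and alignment
#' encodings (BTOP vs CIGAR).  Conversion is driven by mapping
#' profiles — data files, not code — each an ordered list of
#' (source column, target field, transform) entries.  Conversion never
#' invents values: every non-null target is traceable to source cells
#' through its declared transform, and unmapped target fields are
#' null.
#'
#' Available transforms: `copy` (alias `rename`), `bool_norm`,
#' `end_from_length`, `length_from_end`, `shift_base`,
#' `btop_to_cigar`, `drop`.
#' @name converters
NULL

TRANSFORMS <- c("copy", "rename", "bool_norm", "end_from_length",
                "length_from_end", "shift_base", "btop_to_cigar", "drop")

#' Load a conversion mapping profile
#'
#' @param x a profile YAML path, a bundled profile name (see
#'   [list_profiles()]), or an already-parsed list.
#' @param schema an `airr_schema`; non-drop targets must be declared
#'   in it unless the mapping sets `custom: true`.
#' @return an `airr_profile`.
#' @export
load_profile <- function(x, schema = default_schema()) {
  doc <- if (is.list(x)) {
    x
  } else if (file.exists(x)) {
    yaml::read_yaml(x)
  } else {
    bundled <- system.file("extdata", "profiles", paste0(x, ".yaml"),
                           package = "airrkit")
    if (!nzchar(bundled)) {
      abort_airr(sprintf("unknown profile '%s' (not a file or bundled name)", x),
                 "airr_profile_error")
    }
    yaml::read_yaml(bundled)
  }
  dialect <- doc$dialect %||% list()
  dialect$delimiter <- dialect$delimiter %||% "\t"
  dialect$null_tokens <- as.character(dialect$null_tokens %||% "")
  mappings <- lapply(doc$mappings %||% list(), function(m) {
    m$transform <- m$transform %||% "copy"
    if (!m$transform %in% TRANSFORMS) {
      abort_airr(sprintf("unknown transform '%s' (source '%s')",
                         m$transform, m$source %||% "?"),
                 "airr_profile_error")
    }
    if (m$transform != "drop") {
      if (is.null(m$target) || !nzchar(m$target)) {
        abort_airr(sprintf("mapping for source '%s' lacks a target",
                           m$source %||% "?"), "airr_profile_error")
      }
      if (!isTRUE(m$custom) && is_custom_field(schema, m$target)) {
        abort_airr(sprintf(
          "target '%s' is not a schema field (set custom: true to keep it)",
          m$target), "airr_profile_error")
      }
    }
    if (m$transform %in% c("end_from_length", "length_from_end") &&
        is.null(m$start_source)) {
      abort_airr(sprintf("transform %s for target '%s' needs a start_source",
                         m$transform, m$target), "airr_profile_error")
    }
    m
  })
  targets <- unlist(lapply(mappings, function(m) {
    if (m$transform == "drop") NULL else m$target
  }))
  if (anyDuplicated(targets)) {
    abort_airr(sprintf("profile maps more than one source to: %s",
                       paste(unique(targets[duplicated(targets)]),
                             collapse = ", ")),
               "airr_profile_error")
  }
  structure(list(name = doc$name %||% "unnamed",
                 version = doc$version %||% "0",
                 dialect = dialect, mappings = mappings),
            class = "airr_profile")
}

#' Bundled profile names
#' @export
list_profiles <- function() {
  sub("\\.yaml$", "",
      list.files(system.file("extdata", "profiles", package = "airrkit"),
                 pattern = "\\.yaml$"))
}

#' @export
print.airr_profile <- function(x, ...) {
  cat(sprintf("<airr_profile '%s' v%s> %d mapping(s)\n", x$name, x$version,
              length(x$mappings)))
  invisible(x)
}

null_to_na <- function(raw, null_tokens) {
  if (is.null(raw) || is.na(raw) || raw %in% null_tokens) NA_character_ else raw
}

as_int_or_issue <- function(raw, what, issues) {
  if (is.na(raw)) return(list(value = NA_integer_, issues = issues))
  if (!grepl("^[+-]?[0-9]+$", raw)) {
    return(list(value = NA_integer_,
                issues = c(issues, sprintf("%s: %s is not an integer",
                                           what, deparse(raw)))))
  }
  list(value = as.integer(raw), issues = issues)
}

#' Convert one legacy source row to a rearrangement record
#'
#' @param row a named list or character vector of raw source cells
#'   (already split from the legacy file's own dialect).
#' @param profile an `airr_profile`.
#' @param schema an `airr_schema`.
#' @return a named list of typed values covering every schema field
#'   (unmapped fields null) plus custom targets, with a character
#'   vector attribute `issues` describing any transform failures
#'   (failed targets are null).
#' @export
convert_record <- function(row, profile, schema = default_schema()) {
  row <- as.list(row)
  nulls <- profile$dialect$null_tokens
  issues <- character(0)
  out <- list()
  for (nm in schema$fields$name) out[[nm]] <- typed_na(field_kind(schema, nm))

  for (m in profile$mappings) {
    if (m$transform == "drop") next
    raw <- null_to_na(row[[m$source]], nulls)
    if (!m$source %in% names(row)) {
      issues <- c(issues, sprintf("source column '%s' absent (target '%s')",
                                  m$source, m$target))
      next
    }
    kind <- if (isTRUE(m$custom)) "text" else field_kind(schema, m$target)
    value <- switch(m$transform,
      copy = ,
      rename = {
        if (is.na(raw)) typed_na(kind)
        else tryCatch(coerce_value(raw, kind), airr_coercion_error = function(e) {
          issues <<- c(issues, sprintf("target '%s': %s", m$target,
                                       conditionMessage(e)))
          typed_na(kind)
        })
      },
      bool_norm = {
        tt <- as.character(m$true_tokens %||% c("T", "TRUE", "true", "1"))
        ft <- as.character(m$false_tokens %||% c("F", "FALSE", "false", "0"))
        if (is.na(raw)) NA
        else if (raw %in% tt) TRUE
        else if (raw %in% ft) FALSE
        else {
          issues <- c(issues, sprintf("target '%s': unrecognized boolean %s",
                                      m$target, deparse(raw)))
          NA
        }
      },
      end_from_length = {
        sr <- null_to_na(row[[m$start_source]], nulls)
        lres <- as_int_or_issue(raw, sprintf("target '%s' length", m$target), issues)
        sres <- as_int_or_issue(sr, sprintf("target '%s' start", m$target), lres$issues)
        issues <- sres$issues
        if (is.na(lres$value) || is.na(sres$value)) NA_integer_
        else end_from_length(sres$value, lres$value)
      },
      length_from_end = {
        sr <- null_to_na(row[[m$start_source]], nulls)
        eres <- as_int_or_issue(raw, sprintf("target '%s' end", m$target), issues)
        sres <- as_int_or_issue(sr, sprintf("target '%s' start", m$target), eres$issues)
        issues <- sres$issues
        if (is.na(eres$value) || is.na(sres$value)) NA_integer_
        else length_from_end(sres$value, eres$value)
      },
      shift_base = {
        off <- as.integer(m$offset %||% 1L)
        res <- as_int_or_issue(raw, sprintf("target '%s'", m$target), issues)
        issues <- res$issues
        if (is.na(res$value)) typed_na(kind) else res$value + off
      },
      btop_to_cigar = {
        if (is.na(raw)) NA_character_
        else tryCatch(cigar_string(btop_to_cigar(raw, mode = m$mode %||% "M")),
                      airr_parse_error = function(e) {
          issues <<- c(issues, sprintf("target '%s': %s", m$target,
                                       conditionMessage(e)))
          NA_character_
        })
      })
    out[[m$target]] <- value
  }
  attr(out, "issues") <- issues
  out
}

read_delim_rows <- function(path, delimiter) {
  lines <- read_source_lines(path)
  if (length(lines) == 0L) {
    abort_airr(sprintf("'%s': empty file (no header)", path),
               "airr_header_error")
  }
  sp <- strsplit(paste0(lines, delimiter, "\x01"), delimiter, fixed = TRUE)
  sp <- lapply(sp, function(x) x[-length(x)])
  list(header = sp[[1L]], rows = sp[-1L])
}

#' Convert a legacy annotation file to a Rearrangement TSV
#'
#' @param src path to the legacy file (in the profile's dialect).
#' @param profile an `airr_profile` (or a name/path for
#'   [load_profile()]).
#' @param out destination TSV path.
#' @param schema an `airr_schema`.
#' @param strict if `TRUE`, the first transform failure aborts with
#'   the offending row index; otherwise failures are collected and
#'   the affected targets left null.
#' @return a list with `n` (records written) and `issues` (character
#'   vector of collected messages, prefixed with the row index).
#' @export
convert_file <- function(src, profile, out, schema = default_schema(),
                         strict = FALSE) {
  if (!inherits(profile, "airr_profile")) profile <- load_profile(profile, schema)
  parsed <- read_delim_rows(src, profile$dialect$delimiter)
  header <- parsed$header
  mapped_sources <- unlist(lapply(profile$mappings, function(m) {
    if (m$transform == "drop") NULL else c(m$source, m$start_source)
  }))
  absent <- setdiff(unique(mapped_sources), header)
  issues <- if (length(absent)) {
    sprintf("source column '%s' absent from '%s'", absent, src)
  } else character(0)

  records <- vector("list", length(parsed$rows))
  for (i in seq_along(parsed$rows)) {
    cells <- parsed$rows[[i]]
    if (length(cells) != length(header)) {
      msg <- sprintf("row %d: %d cells, expected %d", i, length(cells),
                     length(header))
      if (strict) abort_airr(msg, "airr_row_error", record_index = i)
      issues <- c(issues, msg)
      next
    }
    names(cells) <- header
    rec <- convert_record(cells, profile, schema)
    rec_issues <- attr(rec, "issues")
    rec_issues <- setdiff(rec_issues, sprintf(
      "source column '%s' absent (target '%s')",
      vcharacter(profile$mappings, function(m) m$source %||% ""),
      vcharacter(profile$mappings, function(m) m$target %||% "")))
    if (length(rec_issues)) {
      if (strict) {
        abort_airr(sprintf("row %d: %s", i, rec_issues[1L]),
                   "airr_conversion_error", record_index = i)
      }
      issues <- c(issues, sprintf("row %d: %s", i, rec_issues))
    }
    attr(rec, "issues") <- NULL
    records[[i]] <- rec
  }
  records <- records[!vlogical(records, is.null)]
  cols <- if (length(records)) names(records[[1L]]) else schema$fields$name
  df <- structure(
    lapply(cols, function(nm) unlist(lapply(records, function(r) r[[nm]]))),
    names = cols, class = "data.frame",
    row.names = seq_along(records))
  if (length(records) == 0L) {
    df <- structure(lapply(cols, function(nm) {
      vector(typeof(typed_na(field_kind(schema, nm))), 0L)
    }), names = cols, class = "data.frame", row.names = integer(0))
  }
  write_rearrangements(df, out, schema)
  list(n = nrow(df), issues = issues)
}

#' Export records to a legacy dialect through an invertible profile
#'
#' The inverse of [convert_file()]: each profile mapping is applied
#' backwards (`end_from_length` becomes length-from-end, `shift_base`
#' negates its offset, `bool_norm` emits its canonical tokens), so
#' that converting the exported file back through the same profile
#' recovers every mapped field exactly.  Profiles containing
#' non-invertible transforms (`btop_to_cigar`) are rejected.
#'
#' @param x a typed data frame of records.
#' @param profile an `airr_profile`.
#' @param path destination path (written in the profile's dialect).
#' @param schema an `airr_schema`.
#' @return the number of rows written, invisibly.
#' @export
export_legacy <- function(x, profile, path, schema = default_schema()) {
  if (!inherits(profile, "airr_profile")) profile <- load_profile(profile, schema)
  null_out <- profile$dialect$null_tokens[1L]
  mappings <- Filter(function(m) m$transform != "drop", profile$mappings)
  target_of_source <- function(src) {
    for (m in mappings) if (identical(m$source, src)) return(m$target)
    abort_airr(sprintf(
      "cannot invert: start_source '%s' is not itself mapped", src),
      "airr_profile_error")
  }
  cols <- lapply(mappings, function(m) {
    v <- x[[m$target]]
    if (is.null(v)) v <- rep(typed_na(
      if (isTRUE(m$custom)) "text" else field_kind(schema, m$target)), nrow(x))
    rendered <- switch(m$transform,
      copy = ,
      rename = render_column(v, if (isTRUE(m$custom)) "text"
                             else field_kind(schema, m$target), m$target),
      bool_norm = {
        tt <- as.character(m$true_tokens %||% c("T", "TRUE", "true", "1"))[1L]
        ft <- as.character(m$false_tokens %||% c("F", "FALSE", "false", "0"))[1L]
        ifelse(is.na(v), "", ifelse(v, tt, ft))
      },
      end_from_length = {
        start <- x[[target_of_source(m$start_source)]]
        len <- ifelse(is.na(v) | is.na(start), NA_integer_,
                      as.integer(v - start + 1L))
        ifelse(is.na(len), "", as.character(len))
      },
      length_from_end = {
        start <- x[[target_of_source(m$start_source)]]
        end <- ifelse(is.na(v) | is.na(start), NA_integer_,
                      as.integer(start + v - 1L))
        ifelse(is.na(end), "", as.character(end))
      },
      shift_base = {
        off <- as.integer(m$offset %||% 1L)
        ifelse(is.na(v), "", as.character(v - off))
      },
      btop_to_cigar = abort_airr(
        sprintf("profile '%s' is not invertible: btop_to_cigar (target '%s')",
                profile$name, m$target), "airr_profile_error"))
    rendered[rendered == ""] <- null_out
    rendered
  })
  header <- vcharacter(mappings, function(m) m$source)
  delim <- profile$dialect$delimiter
  body <- if (nrow(x) > 0L) do.call(paste, c(cols, sep = delim)) else character(0)
  write_atomic(path, function(tmp) {
    con <- file(tmp, "wb")
    on.exit(close(con))
    writeLines(c(paste(header, collapse = delim), body), con, sep = "\n",
               useBytes = TRUE)
  })
  invisible(nrow(x))
}
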