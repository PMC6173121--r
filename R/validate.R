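#' @title Rule-based validation
#' @description
#' Validation is organised as a registry of identified rules, each
#' with a fixed severity, applied to headers, single records, or whole
#' datasets.  Because every field is nullable, cross-field rules fire
#' only when all participating fields are non-null: absence is never
#' itself an error beyond header requiredness.  Rules are also
#' hierarchical — a consistency rule that presupposes a well-formed
#' ingredient (an ordered interval, a valid coordinate) is skipped
#' when that ingredient has already failed its own rule, so one defect
#' is reported once, under the rule that owns it.
#'
#' Error-level rules:
#' \describe{
#'   \item{MISSING_REQUIRED}{a required column is absent from the header.}
#'   \item{ROW_WIDTH}{a data row has the wrong number of cells.}
#'   \item{TYPE}{a non-null cell does not satisfy its column's value
#'     kind (including coordinates < 1 and unparseable CIGAR text).}
#'   \item{INTERVAL}{for a paired `x_start`/`x_end`, start > end.}
#'   \item{JUNC_LEN}{`junction_length` differs from the character count
#'     of `junction`.}
#'   \item{JUNC_AA}{3 x length of `junction_aa` differs from the
#'     length of `junction`.}
#'   \item{CIGAR_SPAN}{a gene's CIGAR aligned query span differs from
#'     its `*_sequence_start/_end` interval length, or the aligned
#'     reference span from `*_germline_start/_end` (soft clips and
#'     reference skips excluded from the span).}
#'   \item{REGION_BOUNDS}{a region interval falls outside
#'     `[1, nchar(sequence)]`.}
#'   \item{ALN_LEN}{`sequence_alignment` and `germline_alignment`
#'     lengths differ.}
#' }
#' Warning-level rules: DUP_COLUMN (case-fold header collision),
#' NAME_WHITESPACE, NT_ALPHABET, AA_ALPHABET, IDENTITY_RANGE
#' (`*_identity` outside both `[0, 1]` and `[0, 100]`; `_score`,
#' `_identity`, `_support` are otherwise context-dependent and only
#' checked for numeric parseability).
#' @name validation
NULL

#' The validation rule registry
#'
#' @return a data frame with `rule_id`, `severity`, `scope`
#'   (header/record), `corruptible` (whether [corrupt_record()] can
#'   produce a minimal targeted violation), and `description`.
#' @export
validation_rules <- function() {
  data.frame(
    rule_id = c("MISSING_REQUIRED", "DUP_COLUMN", "NAME_WHITESPACE",
                "ROW_WIDTH", "TYPE", "INTERVAL", "JUNC_LEN", "JUNC_AA",
                "CIGAR_SPAN", "REGION_BOUNDS", "ALN_LEN",
                "NT_ALPHABET", "AA_ALPHABET", "IDENTITY_RANGE"),
    severity = c("error", "warning", "warning",
                 "error", "error", "error", "error", "error",
                 "error", "error", "error",
                 "warning", "warning", "warning"),
    scope = c("header", "header", "header",
              "record", "record", "record", "record", "record",
              "record", "record", "record",
              "record", "record", "record"),
    corruptible = c(FALSE, FALSE, FALSE,
                    FALSE, TRUE, TRUE, TRUE, TRUE,
                    TRUE, TRUE, TRUE,
                    FALSE, FALSE, FALSE),
    description = c(
      "required column missing from header",
      "column names collide after case folding",
      "column name carries whitespace",
      "row has wrong cell count",
      "cell does not satisfy its value kind",
      "start > end in a paired interval",
      "junction_length != nchar(junction)",
      "3 * nchar(junction_aa) != nchar(junction)",
      "CIGAR aligned span disagrees with the start/end interval",
      "region interval outside [1, nchar(sequence)]",
      "sequence_alignment and germline_alignment lengths differ",
      "nucleotide sequence has non-IUPAC characters",
      "amino acid sequence has non-standard characters",
      "identity outside [0,1] and [0,100]"),
    stringsAsFactors = FALSE)
}

NT_CHARS <- "ACGTURYSWKMBDHVN"
AA_CHARS <- "ACDEFGHIKLMNPQRSTVWYX*"

#' Validate a TSV header against the schema
#'
#' @param columns character vector of header column names.
#' @param schema an `airr_schema`.
#' @return an issues data frame (`rule_id`, `severity`,
#'   `record_index`, `field`, `message`); header issues have a null
#'   record index.
#' @export
validate_header <- function(columns, schema = default_schema()) {
  issues <- list()
  for (nm in setdiff(required_fields(schema), columns)) {
    issues <- c(issues, list(issue_row(
      "MISSING_REQUIRED", "error", NULL, nm,
      sprintf("required column '%s' missing from header", nm))))
  }
  folded <- tolower(trimws(columns))
  for (nm in unique(columns[duplicated(folded) |
                            duplicated(folded, fromLast = TRUE)])) {
    issues <- c(issues, list(issue_row(
      "DUP_COLUMN", "warning", NULL, nm,
      sprintf("column '%s' collides with another after case folding", nm))))
  }
  for (nm in columns[grepl("\\s", columns)]) {
    issues <- c(issues, list(issue_row(
      "NAME_WHITESPACE", "warning", NULL, nm,
      sprintf("column name %s contains whitespace", deparse(nm)))))
  }
  bind_issues(issues)
}

# non-null scalar helper
nn <- function(x) !is.null(x) && length(x) == 1L && !is.na(x)

valid_interval <- function(s, e) nn(s) && nn(e) && s >= 1L && s <= e

#' Validate one typed rearrangement record
#'
#' @param record a named list or one-row data frame of typed values
#'   (as produced by [read_rearrangements()]).
#' @param schema an `airr_schema`.
#' @param record_index index to stamp on the issues (default `NA`).
#' @return an issues data frame; zero rows for a clean record.
#' @examples
#' r <- list(v_sequence_start = 10L, v_sequence_end = 9L)
#' validate_record(r)$rule_id   # "INTERVAL"
#' @export
validate_record <- function(record, schema = default_schema(),
                            record_index = NA_integer_) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  fields <- schema$fields
  issues <- list()
  add <- function(rule, severity, field, msg) {
    issues[[length(issues) + 1L]] <<- issue_row(rule, severity, record_index,
                                                field, msg)
  }
  get <- function(nm) record[[nm]]
  kind_of <- function(nm) fields$value_kind[match(nm, fields$name)]
  declared <- intersect(names(record), fields$name)

  # TYPE: coordinates >= 1; CIGAR text parseable
  cigar_ok <- list()
  for (nm in declared) {
    v <- get(nm)
    if (!nn(v)) next
    k <- kind_of(nm)
    if (k == "coordinate" && v < 1L) {
      add("TYPE", "error", nm,
          sprintf("coordinate %s is not >= 1", v))
    } else if (k == "cigar_text") {
      ops <- tryCatch(parse_cigar(v), airr_parse_error = function(e) NULL)
      if (is.null(ops)) {
        add("TYPE", "error", nm, sprintf("unparseable CIGAR %s", deparse(v)))
      }
      cigar_ok[[nm]] <- ops
    }
  }

  coord_valid <- function(nm) {
    v <- get(nm)
    nn(v) && v >= 1L
  }

  # INTERVAL: ordering of every paired *_start/*_end present
  start_names <- intersect(declared, fields$name[endsWith(fields$name, "_start")])
  for (s in start_names) {
    e <- sub("_start$", "_end", s)
    if (!e %in% names(record)) next
    sv <- get(s)
    ev <- get(e)
    if (nn(sv) && nn(ev) && sv > ev) {
      add("INTERVAL", "error", s,
          sprintf("interval start %d > end %d (%s/%s)", sv, ev, s, e))
    }
  }

  # JUNC_LEN: declared length vs the string itself
  if (nn(get("junction")) && nn(get("junction_length")) &&
      get("junction_length") != nchar(get("junction"))) {
    add("JUNC_LEN", "error", "junction_length",
        sprintf("junction_length %d != nchar(junction) %d",
                get("junction_length"), nchar(get("junction"))))
  }

  # JUNC_AA: translation length consistency
  if (nn(get("junction")) && nn(get("junction_aa")) &&
      3L * nchar(get("junction_aa")) != nchar(get("junction"))) {
    add("JUNC_AA", "error", "junction_aa",
        sprintf("3 * nchar(junction_aa) = %d != nchar(junction) = %d",
                3L * nchar(get("junction_aa")), nchar(get("junction"))))
  }

  # CIGAR_SPAN: per-gene aligned spans vs coordinate intervals.
  # Skipped when the interval itself is malformed (TYPE/INTERVAL own that).
  for (nm in intersect(declared, fields$name[endsWith(fields$name, "_cigar")])) {
    gene <- sub("_cigar$", "", nm)
    ops <- cigar_ok[[nm]]
    if (is.null(ops)) next   # null cigar or unparseable (TYPE fired)
    spans <- cigar_spans(ops, clipped = FALSE)
    qs <- paste0(gene, "_sequence_start")
    qe <- paste0(gene, "_sequence_end")
    if (all(c(qs, qe) %in% names(record)) && valid_interval(get(qs), get(qe))) {
      want <- get(qe) - get(qs) + 1L
      if (spans[["query"]] != want) {
        add("CIGAR_SPAN", "error", nm,
            sprintf("%s aligned query span %d != %s interval length %d",
                    nm, spans[["query"]], gene, want))
      }
    }
    gs <- paste0(gene, "_germline_start")
    ge <- paste0(gene, "_germline_end")
    if (all(c(gs, ge) %in% names(record)) && valid_interval(get(gs), get(ge))) {
      want <- get(ge) - get(gs) + 1L
      if (spans[["ref"]] != want) {
        add("CIGAR_SPAN", "error", nm,
            sprintf("%s aligned reference span %d != %s germline interval length %d",
                    nm, spans[["ref"]], gene, want))
      }
    }
  }

  # REGION_BOUNDS: region intervals within the query sequence
  seq_len_ <- if (nn(get("sequence"))) nchar(get("sequence")) else NA_integer_
  region_starts <- intersect(
    declared, fields$name[fields$category == "region_positions" &
                          endsWith(fields$name, "_start")])
  if (!is.na(seq_len_)) {
    for (s in region_starts) {
      e <- sub("_start$", "_end", s)
      if (!e %in% names(record)) next
      if (!valid_interval(get(s), get(e))) next  # TYPE/INTERVAL own it
      if (get(e) > seq_len_) {
        add("REGION_BOUNDS", "error", e,
            sprintf("region interval [%d, %d] outside [1, %d]",
                    get(s), get(e), seq_len_))
      }
    }
  }

  # ALN_LEN: the two alignment rows must agree in length
  if (nn(get("sequence_alignment")) && nn(get("germline_alignment")) &&
      nchar(get("sequence_alignment")) != nchar(get("germline_alignment"))) {
    add("ALN_LEN", "error", "sequence_alignment",
        sprintf("sequence_alignment length %d != germline_alignment length %d",
                nchar(get("sequence_alignment")),
                nchar(get("germline_alignment"))))
  }

  # alphabet warnings
  for (nm in declared) {
    v <- get(nm)
    if (!nn(v)) next
    k <- kind_of(nm)
    if (k %in% c("nt_sequence", "gapped_nt_sequence")) {
      allowed <- if (k == "gapped_nt_sequence") paste0(NT_CHARS, ".-") else NT_CHARS
      if (grepl(sprintf("[^%s]", allowed), toupper(v))) {
        add("NT_ALPHABET", "warning", nm,
            sprintf("'%s' has characters outside the IUPAC nucleotide set", nm))
      }
    } else if (k == "aa_sequence") {
      if (grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", toupper(v))) {
        add("AA_ALPHABET", "warning", nm,
            sprintf("'%s' has characters outside the amino acid set", nm))
      }
    } else if (k == "number" && endsWith(nm, "_identity")) {
      if (v < 0 || v > 100) {
        add("IDENTITY_RANGE", "warning", nm,
            sprintf("identity %s outside [0,1] and [0,100]", v))
      }
    }
  }

  bind_issues(issues)
}

new_report <- function(issues, n_records) {
  errs <- issues$severity == "error"
  structure(list(
    issues = issues,
    n_records = n_records,
    n_errors = sum(errs),
    n_warnings = sum(!errs),
    rule_counts = table(issues$rule_id),
    pass = !any(errs)
  ), class = "airr_validation_report")
}

#' @export
print.airr_validation_report <- function(x, ...) {
  cat(sprintf("<airr_validation_report> %s: %d record(s), %d error(s), %d warning(s)\n",
              if (x$pass) "PASS" else "FAIL",
              x$n_records, x$n_errors, x$n_warnings))
  if (length(x$rule_counts)) {
    for (nm in names(x$rule_counts)) {
      cat(sprintf("  %-16s %d\n", nm, x$rule_counts[[nm]]))
    }
  }
  invisible(x)
}

#' Validate an in-memory table of records
#'
#' @param x a typed data frame of records.
#' @param schema an `airr_schema`.
#' @param header optional original header (defaults to `names(x)`).
#' @return an `airr_validation_report`: issues, counts per rule, and a
#'   `pass` flag that is true iff no error-severity issue was found.
#' @export
validate_rearrangements <- function(x, schema = default_schema(),
                                    header = names(x)) {
  issues <- list(validate_header(header, schema))
  for (i in seq_len(nrow(x))) {
    issues <- c(issues, list(validate_record(x[i, , drop = FALSE], schema,
                                             record_index = i)))
  }
  new_report(bind_issues(issues), nrow(x))
}

#' Validate a file or dataset in a streaming pass
#'
#' Records are read and checked chunk by chunk; the dataset is never
#' materialized in memory.  Read-time issues (row width, unparseable
#' cells) are folded into the report alongside the record rules.
#'
#' @param x a file path or an `airr_dataset` handle.
#' @param schema an `airr_schema`.
#' @param chunk_size records per streaming chunk.
#' @return an `airr_validation_report`.
#' @export
validate_file <- function(x, schema = default_schema(), chunk_size = 2000L) {
  paths <- if (inherits(x, "airr_dataset")) x$sources else x
  all_issues <- list()
  total <- 0L
  for (p in paths) {
    base <- total
    reader <- rearrangement_reader(p, schema, strict = FALSE,
                                   chunk_size = chunk_size)
    repeat {
      chunk <- reader()
      if (is.null(chunk)) break
      first <- attr(chunk, "first_index")
      read_issues <- attr(chunk, "issues")
      for (i in seq_len(nrow(chunk))) {
        all_issues <- c(all_issues, list(
          validate_record(chunk[i, , drop = FALSE], schema,
                          record_index = base + first + i - 1L)))
      }
      if (nrow(read_issues)) {
        read_issues$record_index <- read_issues$record_index + base
        all_issues <- c(all_issues, list(read_issues))
      }
      total <- total + nrow(chunk)
    }
  }
  new_report(bind_issues(all_issues), total)
}
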