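#' @title Multi-file datasets
#' @description
#' A dataset is a TSV file, a TSV with a companion YAML metadata file,
#' or an ordered collection of TSV files treated as one logical table:
#' the record stream is the in-order concatenation and the column set
#' is the union (columns absent from a member are null-filled).
#' Members must agree on which required columns they carry; optional
#' and custom columns may differ — "compatible schema" is read here as
#' identical required-column sets.
#' @name datasets
NULL

dataset_header <- function(path) {
  parse_header_line(read_source_lines(path, n = 1L), path)
}

#' Logically concatenate TSV files into one dataset
#'
#' @param paths one or more readable Rearrangement TSV files (possibly
#'   compressed).
#' @param schema an `airr_schema`.
#' @return an `airr_dataset` handle: `$sources`, `$columns` (resolved
#'   union, canonical order), `$metadata` (per-source companion
#'   document paths or `NA`).
#' @export
concat_datasets <- function(paths, schema = default_schema()) {
  if (length(paths) < 1L) {
    abort_airr("a dataset needs at least one source file", "airr_io_error")
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort_airr(sprintf("no such file(s): %s", paste(missing, collapse = ", ")),
               "airr_io_error")
  }
  headers <- lapply(paths, dataset_header)
  req <- required_fields(schema)
  req_sets <- lapply(headers, intersect, x = req)
  ref <- req_sets[[1L]]
  for (i in seq_along(req_sets)[-1L]) {
    if (!setequal(ref, req_sets[[i]])) {
      d1 <- setdiff(ref, req_sets[[i]])
      d2 <- setdiff(req_sets[[i]], ref)
      abort_airr(sprintf(
        "incompatible required columns between '%s' and '%s': %s",
        paths[1L], paths[i],
        paste(c(sprintf("missing %s", d1), sprintf("extra %s", d2)),
              collapse = "; ")),
        "airr_compat_error")
    }
  }
  all_cols <- unique(unlist(headers))
  columns <- c(intersect(schema$fields$name, all_cols),
               setdiff(all_cols, schema$fields$name))
  metadata <- vcharacter(paths, function(p) {
    mp <- metadata_path(p)
    if (file.exists(mp)) mp else NA_character_
  }, USE.NAMES = FALSE)
  structure(list(sources = paths, columns = columns, metadata = metadata,
                 schema = schema),
            class = "airr_dataset")
}

#' @export
print.airr_dataset <- function(x, ...) {
  cat(sprintf("<airr_dataset> %d source(s), %d column(s)\n",
              length(x$sources), length(x$columns)))
  invisible(x)
}

#' Materialize a dataset handle as one data frame
#'
#' @param handle an `airr_dataset` from [concat_datasets()].
#' @param strict passed to the per-file reader.
#' @return the concatenated typed records, columns in the handle's
#'   resolved order; missing columns are null-filled per file.
#' @export
read_dataset <- function(handle, strict = FALSE) {
  stopifnot(inherits(handle, "airr_dataset"))
  schema <- handle$schema
  parts <- lapply(handle$sources, function(p) {
    df <- read_rearrangements(p, schema, strict = strict)
    for (nm in setdiff(handle$columns, names(df))) {
      df[[nm]] <- if (is_custom_field(schema, nm)) {
        rep(NA_character_, nrow(df))
      } else {
        rep(typed_na(field_kind(schema, nm)), nrow(df))
      }
    }
    df[handle$columns]
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# ---- companion metadata ---------------------------------------------------

metadata_path <- function(path) {
  sub("\\.tsv(\\.(gz|bgz|bgzf|bz2))?$", ".yaml", path)
}

#' Read/write a companion metadata document
#'
#' Datasets may carry a sidecar YAML document (same basename, `.yaml`
#' extension) with experiment metadata.  The document is treated as an
#' opaque structure: it is checked for well-formedness only, since the
#' metadata schema itself is defined elsewhere.
#'
#' @param path the metadata file (or the TSV it accompanies).
#' @return `read_metadata()`: the parsed document (a list).
#' @export
read_metadata <- function(path) {
  if (grepl("\\.tsv(\\..*)?$", path)) path <- metadata_path(path)
  if (!file.exists(path)) {
    abort_airr(sprintf("no metadata document at '%s'", path), "airr_io_error")
  }
  doc <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort_airr(sprintf("malformed metadata document '%s': %s", path,
                       conditionMessage(e)), "airr_metadata_error")
  })
  doc
}

#' @rdname read_metadata
#' @param x a list (YAML-representable structure).
#' @export
write_metadata <- function(x, path) {
  write_atomic(path, function(tmp) yaml::write_yaml(x, tmp))
  invisible(path)
}
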