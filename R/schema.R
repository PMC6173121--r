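#' @title The Rearrangement schema as data
#'
#' @description
#' The column catalogue of the AIRR Rearrangement format is shipped as a
#' machine-readable YAML document and loaded into an `airr_schema`
#' object: an ordered table of field specifications (name, category,
#' value kind, requiredness, description) plus a semantic version
#' triple.  Keeping the catalogue as data rather than code means
#' corrections are configuration-only, in keeping with the standard's
#' deprecate-don't-rename policy.
#'
#' @details
#' Field value kinds are one of `text`, `nt_sequence`, `aa_sequence`,
#' `gapped_nt_sequence`, `integer`, `coordinate`, `number`, `boolean`,
#' `cigar_text`.  Several kinds are dictated by the field-name suffix
#' and are applied (and cross-checked) at load time:
#' `_aa` -> `aa_sequence`, `_start`/`_end` -> `coordinate`,
#' `_cigar` -> `cigar_text`, `_alignment` -> `gapped_nt_sequence`,
#' `_score`/`_identity`/`_support` -> `number`.
#'
#' Every field, required or not, is nullable; null is encoded on disk
#' as the empty string.  "Required" means the column must be present in
#' the TSV header, not that its values are non-null.
#' @name airr_schema
NULL

VALUE_KINDS <- c(
  "text", "nt_sequence", "aa_sequence", "gapped_nt_sequence",
  "integer", "coordinate", "number", "boolean", "cigar_text"
)

FIELD_CATEGORIES <- c(
  "input", "primary_annotations", "alignment_annotations",
  "alignment_positions", "region_sequence", "region_positions",
  "junction_lengths"
)

# value kinds forced by name suffix; checked in load order
SUFFIX_KINDS <- list(
  "_aa"        = "aa_sequence",
  "_start"     = "coordinate",
  "_end"       = "coordinate",
  "_cigar"     = "cigar_text",
  "_alignment" = "gapped_nt_sequence",
  "_score"     = "number",
  "_identity"  = "number",
  "_support"   = "number"
)

suffix_kind <- function(name) {
  for (sfx in names(SUFFIX_KINDS)) {
    if (endsWith(name, sfx)) return(SUFFIX_KINDS[[sfx]])
  }
  NA_character_
}

#' Parse a semantic version string
#'
#' @param x a string of the form `"X.Y.Z"`.
#' @return integer vector `c(major, minor, patch)`.
#' @examples
#' parse_version("1.2.0")
#' @export
parse_version <- function(x) {
  if (!is_string(x) || !grepl("^[0-9]+\\.[0-9]+\\.[0-9]+$", x)) {
    abort_airr(sprintf("malformed version string: %s",
                       deparse(substitute(x))), "airr_version_error")
  }
  as.integer(strsplit(x, ".", fixed = TRUE)[[1L]])
}

as_version <- function(x) {
  if (is.character(x)) return(parse_version(x))
  if (is.numeric(x) && length(x) == 3L && !anyNA(x)) return(as.integer(x))
  abort_airr("a version must be an 'X.Y.Z' string or an integer triple",
             "airr_version_error")
}

#' Classify the change between two schema versions
#'
#' Under the standard's semantic-versioning variant, the major number is
#' reserved for changes spanning multiple standards, the minor number
#' for schema/API changes, and the patch number for software or
#' documentation updates without schema modification.  This helper
#' reports the highest-order component at which two versions differ.
#'
#' @param old,new version strings (`"X.Y.Z"`) or integer triples.
#' @return one of `"major"`, `"minor"`, `"patch"`, `"none"`.
#' @examples
#' classify_version_change("1.2.0", "1.3.0")  # "minor"
#' @export
classify_version_change <- function(old, new) {
  old <- as_version(old)
  new <- as_version(new)
  diff <- which(old != new)
  if (length(diff) == 0L) return("none")
  c("major", "minor", "patch")[min(diff)]
}

#' Load a Rearrangement schema document
#'
#' @param source path to a YAML schema document, or an already-parsed
#'   list with elements `version` and `fields`.  Defaults to the
#'   bundled catalogue.
#' @return an `airr_schema` object: `$version` (integer triple) and
#'   `$fields` (a data frame with columns `name`, `category`,
#'   `value_kind`, `required`, `description`, in canonical order).
#' @examples
#' sch <- load_schema()
#' schema_version(sch)
#' @export
load_schema <- function(source = default_schema_file()) {
  doc <- if (is.list(source)) source else yaml::read_yaml(source)
  if (is.null(doc$version) || is.null(doc$fields) || length(doc$fields) < 1L) {
    abort_airr("schema document must declare a version and at least one field",
               "airr_schema_error")
  }
  version <- as_version(doc$version)

  specs <- lapply(doc$fields, function(f) {
    name <- f$name %||% ""
    if (!is_string(name) || !nzchar(name) || grepl("[\t\n\r]", name)) {
      abort_airr("field names must be non-empty and free of tabs/newlines",
                 "airr_schema_error")
    }
    category <- f$category %||% "input"
    if (!category %in% FIELD_CATEGORIES) {
      abort_airr(sprintf("field '%s': unknown category '%s'", name, category),
                 "airr_schema_error")
    }
    skind <- suffix_kind(name)
    kind <- f$kind %||% (if (is.na(skind)) "text" else skind)
    if (!is.na(skind) && kind != skind) {
      abort_airr(sprintf(
        "field '%s': declared kind '%s' conflicts with suffix-mandated '%s'",
        name, kind, skind), "airr_schema_error")
    }
    if (!kind %in% VALUE_KINDS) {
      abort_airr(sprintf("field '%s': unknown value kind '%s'", name, kind),
                 "airr_schema_error")
    }
    data.frame(name = name, category = category, value_kind = kind,
               required = isTRUE(f$required),
               description = f$description %||% "",
               stringsAsFactors = FALSE)
  })
  fields <- do.call(rbind, specs)
  if (anyDuplicated(fields$name)) {
    abort_airr(sprintf("duplicate field name(s): %s",
                       paste(unique(fields$name[duplicated(fields$name)]),
                             collapse = ", ")),
               "airr_schema_error")
  }
  schema <- structure(list(version = version, fields = fields),
                      class = "airr_schema")
  check_interval_pairing(schema)
  schema
}

# every *_start must have a *_end partner in the same category
check_interval_pairing <- function(schema) {
  f <- schema$fields
  starts <- f$name[endsWith(f$name, "_start")]
  for (s in starts) {
    e <- sub("_start$", "_end", s)
    i <- match(e, f$name)
    if (is.na(i) || f$category[i] != f$category[match(s, f$name)]) {
      abort_airr(sprintf("field '%s' has no '%s' partner in its category",
                         s, e), "airr_schema_error")
    }
  }
  invisible(schema)
}

#' Path of the bundled schema document
#' @export
default_schema_file <- function() {
  system.file("extdata", "rearrangement-schema.yaml", package = "airrkit",
              mustWork = TRUE)
}

#' The bundled Rearrangement schema (cached)
#' @export
default_schema <- function() {
  if (is.null(the$schema)) the$schema <- load_schema(default_schema_file())
  the$schema
}

#' Serialize a schema back to a YAML document
#'
#' `load_schema(write_schema(x, f))` reproduces `x` exactly (field
#' order, kinds, and requiredness are preserved).
#'
#' @param schema an `airr_schema`.
#' @param file destination path.
#' @return `file`, invisibly.
#' @export
write_schema <- function(schema, file) {
  stopifnot(inherits(schema, "airr_schema"))
  doc <- list(
    version = paste(schema$version, collapse = "."),
    fields = lapply(seq_len(nrow(schema$fields)), function(i) {
      f <- schema$fields[i, ]
      list(name = f$name, category = f$category, kind = f$value_kind,
           required = f$required, description = f$description)
    })
  )
  write_atomic(file, function(tmp) yaml::write_yaml(doc, tmp))
  invisible(file)
}

#' @export
print.airr_schema <- function(x, ...) {
  cat(sprintf("<airr_schema v%s> %d fields (%d required)\n",
              paste(x$version, collapse = "."), nrow(x$fields),
              sum(x$fields$required)))
  tab <- table(factor(x$fields$category, levels = FIELD_CATEGORIES))
  for (cat_ in names(tab)) cat(sprintf("  %-22s %d\n", cat_, tab[[cat_]]))
  invisible(x)
}

#' Schema accessors
#'
#' @param schema an `airr_schema`.
#' @return `schema_fields()`: the field data frame; `required_fields()`:
#'   character vector of required column names; `schema_version()`: the
#'   version triple; `field_kind()`: the value kind of a declared field.
#' @name schema-accessors
NULL

#' @rdname schema-accessors
#' @export
schema_fields <- function(schema) schema$fields

#' @rdname schema-accessors
#' @export
required_fields <- function(schema) {
  schema$fields$name[schema$fields$required]
}

#' @rdname schema-accessors
#' @export
schema_version <- function(schema) schema$version

#' @rdname schema-accessors
#' @param name a field name.
#' @export
field_kind <- function(schema, name) {
  i <- match(name, schema$fields$name)
  if (anyNA(i)) {
    abort_airr(sprintf("field(s) not declared in schema: %s",
                       paste(name[is.na(i)], collapse = ", ")),
               "airr_schema_error")
  }
  schema$fields$value_kind[i]
}

#' Is a column name a custom (undeclared) field?
#'
#' The format reserves an extensive list of field names but places no
#' restriction on additional custom columns, provided names are unique.
#' Custom fields are carried through I/O untyped, as text.
#'
#' @param schema an `airr_schema`.
#' @param name column name(s); must be non-empty.
#' @return logical: `TRUE` where `name` is not declared in the schema.
#' @examples
#' is_custom_field(load_schema(), c("junction", "my_clone_score"))
#' @export
is_custom_field <- function(schema, name) {
  if (any(!nzchar(name))) {
    abort_airr("field names must be non-empty", "airr_schema_error")
  }
  !(name %in% schema$fields$name)
}
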