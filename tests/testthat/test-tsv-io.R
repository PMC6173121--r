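test_that("empty strings are null for every value kind", {
  for (kind in c("text", "nt_sequence", "aa_sequence", "gapped_nt_sequence",
                 "integer", "coordinate", "number", "boolean", "cigar_text")) {
    expect_true(is.na(coerce_value("", kind)), info = kind)
  }
})

test_that("cells parse per kind, and coordinates must be >= 1", {
  expect_identical(coerce_value("42", "coordinate"), 42L)
  expect_identical(coerce_value("-3", "integer"), -3L)
  expect_identical(coerce_value("3.5e2", "number"), 350)
  expect_true(coerce_value("TRUE", "boolean"))
  expect_false(coerce_value("false", "boolean"))
  expect_error(coerce_value("0", "coordinate"), class = "airr_coercion_error")
  expect_error(coerce_value("x1", "integer"), class = "airr_coercion_error")
  expect_error(coerce_value("maybe", "boolean"), class = "airr_coercion_error")
})

test_that("coerce(render(x)) is the identity, including nulls", {
  cases <- list(
    list("integer", c(0L, -5L, 123L, NA)),
    list("coordinate", c(1L, 99L, NA)),
    list("number", c(0.25, -3.5, 1e6, 98.72, NA)),
    list("boolean", c(TRUE, FALSE, NA)),
    list("text", c("IGHV1-2*02", "", NA)),
    list("nt_sequence", c("ACGT", NA)))
  for (cs in cases) {
    kind <- cs[[1L]]
    for (v in cs[[2L]]) {
      rendered <- render_value(v, kind)
      back <- coerce_value(rendered, kind)
      if (is.na(v) || (kind == "text" && !nzchar(v))) {
        expect_true(is.na(back), info = kind)
      } else {
        expect_identical(back, v, info = kind)
      }
    }
  }
})

test_that("boolean input spellings normalize; output is canonical T/F", {
  for (tok in c("T", "TRUE", "true")) expect_true(coerce_value(tok, "boolean"))
  for (tok in c("F", "FALSE", "false")) expect_false(coerce_value(tok, "boolean"))
  expect_identical(render_value(TRUE, "boolean"), "T")
  expect_identical(render_value(FALSE, "boolean"), "F")
})

test_that("reading types declared columns and reports missing required ones", {
  sch <- mini_schema()
  f <- write_tsv_lines(c("sequence_id\tjunction\tjunction_length",
                         "r1\tTGTGCGTGG\t9",
                         "r2\t\t"))
  expect_error(read_rearrangements(f, sch, strict = TRUE),
               class = "airr_header_error")
  x <- read_rearrangements(f, sch, strict = FALSE)
  expect_identical(nrow(x), 2L)
  expect_identical(x$junction_length, c(9L, NA_integer_))
  expect_true(is.na(x$junction[2L]))       # empty cell is null
  expect_true("sequence" %in% names(x))    # required column null-filled
  expect_true(all(is.na(x$sequence)))
  issues <- attr(x, "issues")
  expect_true("MISSING_REQUIRED" %in% issues$rule_id)
})

test_that("unknown columns are carried through untyped as custom fields", {
  sch <- mini_schema()
  f <- write_tsv_lines(c("sequence_id\tsequence\tlab_tag",
                         "r1\tACGT\tbatchA",
                         "r2\tGGGG\t"))
  x <- read_rearrangements(f, sch)
  expect_type(x$lab_tag, "character")
  expect_identical(x$lab_tag, c("batchA", NA))
  out <- tempfile(fileext = ".tsv")
  write_rearrangements(x, out, sch)
  header <- readLines(out, n = 1L)
  # canonical order first, customs last
  expect_identical(header, "sequence_id\tsequence\tlab_tag")
})

test_that("writers emit canonical column order and empty cells for nulls", {
  sch <- mini_schema()
  df <- data.frame(junction = c("TGT", NA), sequence_id = c("a", "b"),
                   sequence = c("ACGT", "ACGT"), stringsAsFactors = FALSE)
  out <- tempfile(fileext = ".tsv")
  write_rearrangements(df, out, sch)
  lines <- readLines(out)
  expect_identical(lines[1L], "sequence_id\tsequence\tjunction")
  expect_identical(lines[3L], "b\tACGT\t")
})

test_that("write(read(f)) is byte-identical for canonical files", {
  sim <- cached_sim(40, seed = 5)
  f1 <- tempfile(fileext = ".tsv")
  write_rearrangements(sim$records, f1)
  x <- read_rearrangements(f1)
  f2 <- tempfile(fileext = ".tsv")
  write_rearrangements(x, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("values with tabs or newlines are rejected at write time", {
  sch <- mini_schema()
  df <- data.frame(sequence_id = "a\tb", sequence = "ACGT",
                   stringsAsFactors = FALSE)
  expect_error(write_rearrangements(df, tempfile(), sch),
               class = "airr_render_error")
})

test_that("CRLF line endings are tolerated on read", {
  sch <- mini_schema()
  f <- write_tsv_lines(c("sequence_id\tsequence\r", "r1\tACGT\r"))
  x <- read_rearrangements(f, sch)
  expect_identical(x$sequence, "ACGT")
})

test_that("malformed rows abort in strict mode and are skipped in lenient", {
  sch <- mini_schema()
  f <- write_tsv_lines(c("sequence_id\tsequence", "r1\tACGT\textra", "r2\tGG"))
  expect_error(read_rearrangements(f, sch, strict = TRUE),
               class = "airr_row_error")
  x <- read_rearrangements(f, sch, strict = FALSE)
  expect_identical(x$sequence_id, "r2")
  expect_true("ROW_WIDTH" %in% attr(x, "issues")$rule_id)
})

test_that("duplicate header names are a header error", {
  f <- write_tsv_lines(c("sequence_id\tsequence_id", "a\tb"))
  expect_error(read_rearrangements(f, mini_schema()),
               class = "airr_header_error")
})

test_that("unparseable cells: strict error vs lenient null + TYPE issue", {
  sch <- mini_schema()
  f <- write_tsv_lines(c("sequence_id\tsequence\tjunction_length",
                         "r1\tACGT\tabc"))
  expect_error(read_rearrangements(f, sch, strict = TRUE),
               class = "airr_coercion_error")
  x <- read_rearrangements(f, sch, strict = FALSE)
  expect_true(is.na(x$junction_length))
  iss <- attr(x, "issues")
  expect_identical(iss$rule_id[iss$field %in% "junction_length"], "TYPE")
})

test_that("datasets concatenate in order with union-filled columns", {
  sim <- cached_sim(15, seed = 9)
  a <- tempfile(fileext = ".tsv")
  b <- tempfile(fileext = ".tsv")
  da <- sim$records[1:10, ]
  da$lab_x <- paste0("x", 1:10)
  db <- sim$records[11:15, ]
  write_rearrangements(da, a)
  write_rearrangements(db, b)
  handle <- concat_datasets(c(a, b))
  df <- read_dataset(handle)
  expect_identical(nrow(df), 15L)
  expect_identical(df$sequence_id, sim$records$sequence_id)
  # union fill: records from b have lab_x null
  expect_identical(df$lab_x[1:10], paste0("x", 1:10))
  expect_true(all(is.na(df$lab_x[11:15])))
})

test_that("incompatible required-column sets are rejected with the discrepancy", {
  sim <- cached_sim(4, seed = 2)
  a <- tempfile(fileext = ".tsv")
  b <- tempfile(fileext = ".tsv")
  write_rearrangements(sim$records, a)
  broken <- sim$records[, setdiff(names(sim$records), "junction")]
  write_rearrangements(broken, b)
  err <- tryCatch(concat_datasets(c(a, b)), airr_compat_error = identity)
  expect_s3_class(err, "airr_compat_error")
  expect_match(conditionMessage(err), "junction")
})

test_that("concatenation is associative on the record stream", {
  sim <- cached_sim(12, seed = 3)
  fs <- replicate(3, tempfile(fileext = ".tsv"))
  write_rearrangements(sim$records[1:4, ], fs[1])
  write_rearrangements(sim$records[5:8, ], fs[2])
  write_rearrangements(sim$records[9:12, ], fs[3])
  ab <- tempfile(fileext = ".tsv")
  write_rearrangements(read_dataset(concat_datasets(fs[1:2])), ab)
  left <- read_dataset(concat_datasets(c(ab, fs[3])))
  flat <- read_dataset(concat_datasets(fs))
  expect_identical(left, flat)
})

test_that("companion metadata round-trips as an opaque document", {
  f <- tempfile(fileext = ".tsv")
  write_rearrangements(cached_sim(2, seed = 1)$records, f)
  meta <- list(study = list(id = "S1", species = "toy"),
               pipeline = c("simulate", "validate"))
  write_metadata(meta, sub("\\.tsv$", ".yaml", f))
  back <- read_metadata(f)
  expect_identical(back$study$id, "S1")
  handle <- concat_datasets(f)
  expect_false(is.na(handle$metadata[1L]))
})
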