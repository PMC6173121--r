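test_that("header rules: missing required, case-fold collisions, whitespace", {
  sch <- default_schema()
  full <- schema_fields(sch)$name
  expect_identical(nrow(validate_header(full, sch)), 0L)

  iss <- validate_header(setdiff(full, "sequence_id"), sch)
  expect_identical(iss$rule_id, "MISSING_REQUIRED")
  expect_identical(iss$severity, "error")
  expect_identical(iss$field, "sequence_id")

  iss <- validate_header(c(full, "V_call"), sch)
  expect_true(all(c("DUP_COLUMN") %in% iss$rule_id))
  expect_true(all(iss$severity[iss$rule_id == "DUP_COLUMN"] == "warning"))

  iss <- validate_header(c(full, "my col"), sch)
  expect_true("NAME_WHITESPACE" %in% iss$rule_id)
})

test_that("interval ordering violations are flagged", {
  iss <- validate_record(list(v_sequence_start = 10L, v_sequence_end = 9L))
  expect_identical(iss$rule_id, "INTERVAL")
  expect_identical(
    nrow(validate_record(list(v_sequence_start = 9L, v_sequence_end = 9L))),
    0L)
  # nullability: absence is never an error
  expect_identical(
    nrow(validate_record(list(v_sequence_start = NA_integer_,
                              v_sequence_end = 9L))), 0L)
})

test_that("junction length rules count the actual strings", {
  rec <- list(junction = "TGTGCGAGAGATTTTTGG", junction_length = 18L)
  expect_identical(nrow(validate_record(rec)), 0L)
  rec$junction_length <- 17L
  expect_identical(validate_record(rec)$rule_id, "JUNC_LEN")
  rec <- list(junction = "TGTGCGTGG", junction_aa = "CAW")
  expect_identical(nrow(validate_record(rec)), 0L)
  rec$junction_aa <- "CAWX"
  expect_identical(validate_record(rec)$rule_id, "JUNC_AA")
})

test_that("CIGAR spans are checked against coordinate intervals", {
  rec <- list(sequence = strrep("A", 30),
              v_cigar = "10M20S",
              v_sequence_start = 1L, v_sequence_end = 10L,
              v_germline_start = 1L, v_germline_end = 10L)
  expect_identical(nrow(validate_record(rec)), 0L)
  rec$v_sequence_end <- 12L
  expect_identical(validate_record(rec)$rule_id, "CIGAR_SPAN")
  # germline side uses the reference-consuming span
  rec$v_sequence_end <- 10L
  rec$v_cigar <- "8M2D2I18S"   # query 10, ref 10 aligned
  expect_identical(nrow(validate_record(rec)), 0L)
  rec$v_germline_end <- 9L
  expect_identical(validate_record(rec)$rule_id, "CIGAR_SPAN")
})

test_that("unparseable CIGARs are a TYPE error, not a span error", {
  rec <- list(v_cigar = "XYZ",
              v_sequence_start = 1L, v_sequence_end = 10L)
  iss <- validate_record(rec)
  expect_identical(iss$rule_id, "TYPE")
})

test_that("region intervals must fall inside the sequence", {
  rec <- list(sequence = strrep("A", 50), cdr1_start = 19L, cdr1_end = 30L)
  expect_identical(nrow(validate_record(rec)), 0L)
  rec$cdr1_end <- 53L
  expect_identical(validate_record(rec)$rule_id, "REGION_BOUNDS")
})

test_that("alignment rows must agree in length", {
  rec <- list(sequence_alignment = "ACGTAC", germline_alignment = "ACGTA")
  expect_identical(validate_record(rec)$rule_id, "ALN_LEN")
})

test_that("context-dependent identity fields only warn on wild ranges", {
  rec <- list(v_identity = 98.6)
  expect_identical(nrow(validate_record(rec)), 0L)
  rec <- list(v_identity = 250)
  iss <- validate_record(rec)
  expect_identical(iss$rule_id, "IDENTITY_RANGE")
  expect_identical(iss$severity, "warning")
})

test_that("alphabet checks warn outside IUPAC nt / standard aa sets", {
  iss <- validate_record(list(junction = "ACGTZZ"))
  expect_identical(iss$rule_id, "NT_ALPHABET")
  # gaps allowed in gapped fields, N allowed everywhere
  expect_identical(nrow(validate_record(
    list(sequence_alignment = "AC-GTN", germline_alignment = "ACNGT-"))), 0L)
  iss <- validate_record(list(junction_aa = "CARB?W"))
  expect_identical(iss$rule_id, "AA_ALPHABET")
})

test_that("every corruptible rule fires exactly itself on targeted corruption", {
  sim <- cached_sim(60, seed = 71)
  clean <- sim$records[!is.na(sim$records$junction_aa), ]
  expect_gt(nrow(clean), 10L)
  rules <- validation_rules()
  corruptible <- rules$rule_id[rules$corruptible]
  for (rule in corruptible) {
    for (k in 1:5) {
      rec <- clean[((k - 1) %% nrow(clean)) + 1, , drop = FALSE]
      bad <- corrupt_record(rec, rule)
      iss <- validate_record(bad$record)
      errs <- unique(iss$rule_id[iss$severity == "error"])
      expect_identical(errs, rule, info = rule)
      # restoring the saved fields makes the record clean again
      restored <- restore_record(bad$record, bad$restore)
      iss2 <- validate_record(restored)
      expect_identical(sum(iss2$severity == "error"), 0L, info = rule)
    }
  }
  expect_error(corrupt_record(clean[1, ], "NO_SUCH_RULE"),
               class = "airr_domain_error")
})

test_that("validation is order-independent up to record indices", {
  sim <- cached_sim(40, seed = 81)
  df <- sim$records
  bad <- corrupt_record(df[5, , drop = FALSE], "JUNC_LEN")$record
  df[5, ] <- bad
  perm <- sample(nrow(df))
  r1 <- validate_rearrangements(df)
  r2 <- validate_rearrangements(df[perm, ])
  expect_identical(as.list(r1$rule_counts), as.list(r2$rule_counts))
  expect_identical(r1$pass, r2$pass)
})

test_that("an empty file with a valid header passes with zero records", {
  f <- tempfile(fileext = ".tsv")
  sim0 <- simulate_dataset(0, file = f)
  rep <- validate_file(f)
  expect_true(rep$pass)
  expect_identical(rep$n_records, 0L)
})

test_that("streaming file validation folds read-time TYPE issues in", {
  sim <- cached_sim(25, seed = 91)
  f <- tempfile(fileext = ".tsv")
  write_rearrangements(sim$records, f)
  lines <- readLines(f)
  cells <- strsplit(lines[7], "\t", fixed = TRUE)[[1L]]
  col <- which(strsplit(lines[1], "\t", fixed = TRUE)[[1L]] == "junction_length")
  cells[col] <- "not_a_number"
  lines[7] <- paste(cells, collapse = "\t")
  writeLines(lines, f)
  rep <- validate_file(f)
  expect_false(rep$pass)
  iss <- rep$issues
  type_rows <- iss[iss$rule_id == "TYPE", ]
  expect_identical(type_rows$record_index, 6L)
  expect_identical(type_rows$field, "junction_length")
  # and JUNC_LEN no longer fires for a null junction_length
  expect_false("JUNC_LEN" %in% iss$rule_id)
})
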