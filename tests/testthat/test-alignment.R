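test_that("CIGAR parsing canonicalizes and rejects malformed text", {
  expect_identical(parse_cigar("10M"),
                   data.frame(op = "M", length = 10L, stringsAsFactors = FALSE))
  expect_identical(cigar_string(parse_cigar("5M5M")), "10M")
  expect_identical(parse_cigar("3M1D4M2I1M")$op, c("M", "D", "M", "I", "M"))
  expect_error(parse_cigar("3M0D"), class = "airr_parse_error")
  expect_error(parse_cigar("3Q"), class = "airr_parse_error")
  expect_error(parse_cigar("M10"), class = "airr_parse_error")
  err <- tryCatch(parse_cigar("3M*2D"), airr_parse_error = identity)
  expect_identical(err$position, 3L)
  expect_error(parse_cigar(""), class = "airr_parse_error")
})

test_that("spans follow the SAM consumption table", {
  expect_identical(cigar_spans("3M1D4M2I1M"), c(query = 10L, ref = 9L))
  expect_identical(cigar_spans("7M"), c(query = 7L, ref = 7L))
  expect_identical(cigar_spans("2S5M"), c(query = 7L, ref = 5L))
  expect_identical(cigar_spans("100N3M"), c(query = 3L, ref = 103L))
  # aligned (clip/skip-free) spans
  expect_identical(cigar_spans("2S5M1S", clipped = FALSE),
                   c(query = 5L, ref = 5L))
  expect_identical(cigar_spans("100N3M", clipped = FALSE),
                   c(query = 3L, ref = 3L))
})

test_that("reconstruction expands operations column by column", {
  aln <- reconstruct_alignment("ACGT", "ACGT", "4M")
  expect_identical(aln$aligned_query, "ACGT")
  expect_identical(aln$aligned_ref, "ACGT")
  aln <- reconstruct_alignment("ACGGT", "ACT", "2M2I1M")
  expect_identical(aln$aligned_query, "ACGGT")
  expect_identical(aln$aligned_ref, "AC--T")
  # S consumes query without emitting columns; intervals cover the
  # column-emitting region only
  aln <- reconstruct_alignment("TTACG", "ACG", "2S3M")
  expect_identical(aln$aligned_query, "ACG")
  expect_identical(aln$query_interval, c(3L, 5L))
  expect_identical(aln$ref_interval, c(1L, 3L))
  err <- tryCatch(reconstruct_alignment("AC", "ACGT", "4M"),
                  airr_bounds_error = identity)
  expect_s3_class(err, "airr_bounds_error")
  expect_identical(err$op_index, 1L)
})

test_that("CIGARs derive from gapped pairs per column classification", {
  expect_identical(cigar_string(build_cigar_from_gapped("ACGT", "ACGT")), "4M")
  expect_identical(
    cigar_string(build_cigar_from_gapped("ACGT", "ACTT", mode = "=X")),
    "2=1X1=")
  expect_identical(cigar_string(build_cigar_from_gapped("AC-T", "ACGT")),
                   "2M1D1M")
  # "." accepted as a gap synonym
  expect_identical(cigar_string(build_cigar_from_gapped("AC.T", "ACGT")),
                   "2M1D1M")
  expect_error(build_cigar_from_gapped("A-C", "A-C"),
               class = "airr_structure_error")
  expect_error(build_cigar_from_gapped("AC", "ACG"),
               class = "airr_structure_error")
})

test_that("build and reconstruct are inverse on random gapped pairs", {
  set.seed(101)
  for (i in 1:200) {
    pair <- random_gapped_pair()
    ops <- build_cigar_from_gapped(pair$query, pair$ref, mode = "=X")
    q <- gsub("-", "", pair$query, fixed = TRUE)
    r <- gsub("-", "", pair$ref, fixed = TRUE)
    spans <- cigar_spans(ops)
    expect_identical(unname(spans), c(nchar(q), nchar(r)))
    aln <- reconstruct_alignment(q, r, ops)
    expect_identical(aln$aligned_query, pair$query)
    expect_identical(aln$aligned_ref, pair$ref)
    # round trip is exact in =X mode, and collapses to M-style
    expect_identical(build_cigar_from_gapped(aln$aligned_query,
                                             aln$aligned_ref, mode = "=X"),
                     ops)
    m_ops <- build_cigar_from_gapped(pair$query, pair$ref, mode = "M")
    expect_identical(cigar_string(m_ops),
                     oracle_cigar_from_pair(pair$query, pair$ref, mode = "M"))
  }
})

test_that("BTOP converts per its grammar", {
  expect_identical(cigar_string(btop_to_cigar("46")), "46M")
  expect_identical(cigar_string(btop_to_cigar("7AG38")), "46M")
  expect_identical(cigar_string(btop_to_cigar("7AG38", mode = "=X")),
                   "7=1X38=")
  expect_identical(cigar_string(btop_to_cigar("4C-3-A2")), "4M1I3M1D2M")
  expect_error(btop_to_cigar("7A"), class = "airr_parse_error")
  expect_error(btop_to_cigar("3--4"), class = "airr_parse_error")
})

test_that("BTOP conversion agrees with the expansion oracle", {
  set.seed(202)
  for (i in 1:300) {
    btop <- random_btop()
    pair <- oracle_expand_btop(btop)
    for (mode in c("M", "=X")) {
      expect_identical(cigar_string(btop_to_cigar(btop, mode = mode)),
                       oracle_cigar_from_pair(pair$query, pair$ref, mode),
                       info = btop)
    }
  }
})

test_that("coordinate conventions are bijective", {
  z <- interval_to_zero_based(1L, 10L)
  expect_identical(c(z$lo, z$hi), c(0L, 10L))
  z <- interval_to_zero_based(5L, 5L)
  expect_identical(z$hi - z$lo, 1L)
  set.seed(303)
  start <- sample(1:500, 200, replace = TRUE)
  end <- start + sample(0:100, 200, replace = TRUE)
  z <- interval_to_zero_based(start, end)
  back <- zero_based_to_interval(z$lo, z$hi)
  expect_identical(back$start, start)
  expect_identical(back$end, end)
  expect_identical(z$hi - z$lo, end - start + 1L)
  expect_error(interval_to_zero_based(10L, 9L), class = "airr_domain_error")
  expect_error(interval_to_zero_based(0L, 5L), class = "airr_domain_error")
})

test_that("end/length transforms invert each other; empty features are null", {
  expect_identical(end_from_length(1L, 10L), 10L)
  expect_identical(end_from_length(21L, 1L), 21L)
  expect_true(is.na(end_from_length(7L, 0L)))
  expect_error(end_from_length(3L, -1L), class = "airr_domain_error")
  set.seed(404)
  start <- sample(1:100, 100, replace = TRUE)
  len <- sample(1:50, 100, replace = TRUE)
  expect_identical(length_from_end(start, end_from_length(start, len)), len)
})
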