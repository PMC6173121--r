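test_that("with no trims, insertions, or mutations the record is pure germline", {
  set.seed(1)
  gl <- toy_germline_set("heavy")
  sim <- simulate_rearrangement(gl, degenerate_model())
  rec <- sim$record
  V <- gl$V[[rec$v_call]]
  D <- gl$D[[rec$d_call]]
  J <- gl$J[[rec$j_call]]
  expect_identical(rec$sequence, paste0(V$sequence, D$sequence, J$sequence))
  expect_identical(rec$sequence, rec$germline_alignment)
  # CIGARs are pure M/S
  for (cig in c(rec$v_cigar, rec$d_cigar, rec$j_cigar)) {
    expect_true(all(parse_cigar(cig)$op %in% c("M", "S")))
  }
  # junction runs anchor to anchor, verbatim germline
  expect_identical(
    rec$junction,
    paste0(substr(V$sequence, V$junction_start, V$length), D$sequence,
           substr(J$sequence, 1, J$junction_end)))
  expect_identical(rec$np1_length, 0L)
  expect_identical(sim$truth$n_mutations, 0L)
})

test_that("simulated heavy- and light-chain datasets validate cleanly", {
  for (chain in c("heavy", "light")) {
    sim <- cached_sim(150, seed = 13, chain = chain)
    rep <- validate_rearrangements(sim$records)
    expect_identical(rep$n_errors, 0L)
    expect_true(rep$pass)
  }
})

test_that("light-chain records exercise the nullability paths", {
  sim <- cached_sim(30, seed = 17, chain = "light")
  df <- sim$records
  expect_true(all(is.na(df$d_call)))
  expect_true(all(is.na(df$d_cigar)))
  expect_true(all(is.na(df$np2_length)))
  expect_true(all(is.na(df$d_sequence_start)))
  expect_identical(unique(df$locus), "TOYL")
})

test_that("per-gene CIGARs reconstruct against coordinates exactly", {
  gl <- toy_germline_set("heavy")
  sim <- cached_sim(25, seed = 19)
  df <- sim$records
  for (i in seq_len(nrow(df))) {
    r <- as.list(df[i, ])
    for (gene in c("v", "d", "j")) {
      cig <- r[[paste0(gene, "_cigar")]]
      germ <- gl[[toupper(gene)]][[r[[paste0(gene, "_call")]]]]
      aln <- reconstruct_alignment(r$sequence, germ$sequence, cig,
                                   query_start = 1L,
                                   ref_start = r[[paste0(gene, "_germline_start")]])
      expect_identical(aln$query_interval,
                       c(r[[paste0(gene, "_sequence_start")]],
                         r[[paste0(gene, "_sequence_end")]]))
      expect_identical(aln$ref_interval,
                       c(r[[paste0(gene, "_germline_start")]],
                         r[[paste0(gene, "_germline_end")]]))
      # ungapped rows equal the coordinate-sliced subsequences
      expect_identical(aln$aligned_query,
                       substr(r$sequence, aln$query_interval[1],
                              aln$query_interval[2]))
      expect_identical(aln$aligned_ref,
                       substr(germ$sequence, aln$ref_interval[1],
                              aln$ref_interval[2]))
    }
  }
})

test_that("the truth ledger satisfies the junction conservation law", {
  for (chain in c("heavy", "light")) {
    sim <- cached_sim(100, seed = 23, chain = chain)
    tr <- sim$truth
    df <- sim$records
    d_len <- ifelse(is.na(tr$d_length), 0L, tr$d_length)
    np2 <- ifelse(is.na(tr$np2_length), 0L, tr$np2_length)
    expect_identical(df$junction_length,
                     tr$v_junction + tr$np1_length + d_len + np2 + tr$j_junction)
    expect_identical(df$np1_length, tr$np1_length)
    expect_identical(nchar(df$sequence),
                     tr$v_length + tr$np1_length + d_len + np2 + tr$j_length)
    expect_identical(nchar(df$sequence), tr$sequence_length)
  }
})

test_that("productivity is frame and stop-codon consistency under mu = 0", {
  set.seed(29)
  gl <- toy_germline_set("heavy")
  model <- recombination_model(mu = 0)
  for (i in 1:40) {
    rec <- simulate_rearrangement(gl, model)$record
    in_frame <- rec$junction_length %% 3L == 0L
    want <- in_frame && !grepl("*", rec$junction_aa, fixed = TRUE)
    expect_identical(rec$productive, want)
    if (in_frame) {
      # anchors survive untrimmed junction boundaries: Cys...Trp
      expect_identical(substr(rec$junction_aa, 1, 1), "C")
      expect_identical(substr(rec$junction_aa, nchar(rec$junction_aa),
                              nchar(rec$junction_aa)), "W")
    }
  }
})

test_that("datasets are byte-deterministic under a fixed seed", {
  f1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".tsv")
  t1 <- tempfile(fileext = ".json")
  simulate_dataset(80, file = f1, truth_file = t1, seed = 7)
  simulate_dataset(80, file = f2, seed = 7)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_true(jsonlite::validate(paste(readLines(t1), collapse = "")))
  # and a header-only file for n = 0 is valid
  f0 <- tempfile(fileext = ".tsv")
  simulate_dataset(0, file = f0)
  expect_identical(length(readLines(f0)), 1L)
  expect_true(validate_file(f0)$pass)
})

test_that("the generator leaves the caller's RNG stream untouched", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(simulate_dataset(5, seed = 3))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("observed mutation load tracks the model rate", {
  sim <- cached_sim(400, seed = 37, mu = 0.02)
  total_nt <- sum(sim$truth$sequence_length)
  frac <- sum(sim$truth$n_mutations) / total_nt
  se <- sqrt(0.02 * 0.98 / total_nt)
  expect_lt(abs(frac - 0.02), 3 * se)
})
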