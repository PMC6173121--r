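#' @title Synthetic V(D)J rearrangement simulation
#' @description
#' The simulator draws germline V, (D,) and J segments from a toy gene
#' set, trims the joining ends, inserts untemplated (np) nucleotides,
#' applies point mutations, and emits a fully annotated record —
#' calls, junction, translations, per-gene CIGARs and coordinates,
#' alignment rows, region sequences/positions, and junction lengths —
#' together with a hidden truth ledger (chosen alleles, trim lengths,
#' insertions, mutated positions) from which every reported field is
#' deterministically derivable.  Its purpose is testability: the
#' generator and the validator are independent code paths, so clean
#' simulated data passing validation is an end-to-end check of both.
#'
#' The toy germline set uses a `TOY` locus prefix so its alleles
#' cannot masquerade as real ones; sequences, anchors, and region
#' boundaries are synthetic fixtures, not biological references.
#' @name simulation
NULL

#' Load a germline gene set from FASTA plus an annotation sidecar
#'
#' The sidecar (YAML) declares, per gene: the segment (V/D/J); for V,
#' the 1-based, codon-aligned offset of the conserved junction-start
#' codon (cysteine) and the FWR1–FWR3/CDR1–CDR2 region boundaries,
#' which must tile `[1, junction_start - 1]` without overlap; for J,
#' the offset of the last base of the conserved junction-end codon
#' (tryptophan/phenylalanine).
#'
#' @param fasta path to the germline FASTA.
#' @param sidecar path to the YAML annotation sidecar.
#' @return a `germline_set`: `$locus` and `$V`, `$D`, `$J` gene lists
#'   (each gene: `name`, `sequence`, anchors, regions).  `$D` may be
#'   empty (light-chain set).
#' @export
load_germline_set <- function(fasta, sidecar) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ann <- yaml::read_yaml(sidecar)
  genes <- list(V = list(), D = list(), J = list())
  for (nm in names(ann$genes)) {
    g <- ann$genes[[nm]]
    if (!nm %in% names(seqs)) {
      abort_airr(sprintf("gene '%s' annotated but absent from FASTA", nm),
                 "airr_germline_error")
    }
    sq <- as.character(seqs[[nm]])
    len <- nchar(sq)
    seg <- g$segment
    gene <- list(name = nm, segment = seg, sequence = sq, length = len)
    if (seg == "V") {
      js <- g$junction_start
      if (is.null(js) || js < 4L || js + 2L > len || (js - 1L) %% 3L != 0L) {
        abort_airr(sprintf(
          "V gene '%s': junction_start must be codon-aligned and inside the sequence", nm),
          "airr_germline_error")
      }
      regions <- lapply(g$regions, function(iv) as.integer(iv))
      pos <- unname(unlist(lapply(regions, function(iv) seq(iv[1L], iv[2L]))))
      if (!identical(sort(as.integer(pos)), seq_len(js - 1L))) {
        abort_airr(sprintf(
          "V gene '%s': regions must tile [1, %d] without overlap", nm, js - 1L),
          "airr_germline_error")
      }
      gene$junction_start <- as.integer(js)
      gene$regions <- regions
    } else if (seg == "J") {
      je <- g$junction_end
      if (is.null(je) || je < 3L || je >= len) {
        abort_airr(sprintf(
          "J gene '%s': junction_end must lie inside the sequence", nm),
          "airr_germline_error")
      }
      gene$junction_end <- as.integer(je)
    } else if (seg != "D") {
      abort_airr(sprintf("gene '%s': unknown segment '%s'", nm, seg),
                 "airr_germline_error")
    }
    genes[[seg]][[nm]] <- gene
  }
  if (length(genes$V) == 0L || length(genes$J) == 0L) {
    abort_airr("a germline set needs at least one V and one J gene",
               "airr_germline_error")
  }
  structure(list(locus = ann$locus %||% "TOY", V = genes$V, D = genes$D,
                 J = genes$J),
            class = "germline_set")
}

#' The bundled toy germline sets
#'
#' @param chain `"heavy"` (V, D, and J segments) or `"light"` (no D —
#'   exercises the nullability paths for `d_*` and `np2_*` fields).
#' @return a `germline_set` (cached).
#' @export
toy_germline_set <- function(chain = c("heavy", "light")) {
  chain <- match.arg(chain)
  key <- paste0("germline_", chain)
  if (is.null(the[[key]])) {
    dir <- system.file("extdata", "germline", package = "airrkit",
                       mustWork = TRUE)
    the[[key]] <- load_germline_set(
      file.path(dir, sprintf("toy_%s.fasta", chain)),
      file.path(dir, sprintf("toy_%s.yaml", chain)))
  }
  the[[key]]
}

#' Stochastic recombination parameters
#'
#' Trim lengths at each joining end follow a truncated geometric
#' distribution (support `0..max`), untemplated insertion lengths a
#' Poisson, and point mutations strike each position independently
#' with probability `mu`.  Defaults give mean trims of about 2 nt,
#' mean insertions of 4 nt, and a 1% per-base mutation rate.
#'
#' @param trim_prob geometric success probability for trim lengths.
#' @param max_trim named integer caps `c(v3=, d5=, d3=, j5=)`; chosen
#'   so that every toy gene geometry stays feasible (the V junction
#'   anchor and at least one D nucleotide always survive).
#' @param np_lambda Poisson means `c(np1=, np2=)` for insertion lengths.
#' @param mu per-nucleotide point mutation probability in `[0, 1)`.
#' @param dup_lambda,cons_lambda Poisson parts of the duplicate and
#'   consensus count distributions (`1 + rpois`).
#' @return a `recombination_model`.
#' @export
recombination_model <- function(trim_prob = 0.3,
                                max_trim = c(v3 = 8L, d5 = 4L, d3 = 4L, j5 = 8L),
                                np_lambda = c(np1 = 4, np2 = 4),
                                mu = 0.01,
                                dup_lambda = 2, cons_lambda = 3) {
  stopifnot(trim_prob > 0, trim_prob <= 1,
            all(c("v3", "d5", "d3", "j5") %in% names(max_trim)),
            all(max_trim >= 0),
            all(c("np1", "np2") %in% names(np_lambda)),
            all(np_lambda >= 0),
            mu >= 0, mu < 1,
            dup_lambda >= 0, cons_lambda >= 0)
  structure(list(trim_prob = trim_prob,
                 max_trim = vapply(max_trim, as.integer, integer(1L)),
                 np_lambda = np_lambda, mu = mu,
                 dup_lambda = dup_lambda, cons_lambda = cons_lambda),
            class = "recombination_model")
}

# truncated geometric pmf over 0..max (renormalized)
trim_pmf <- function(p, max) {
  w <- (1 - p)^(0:max) * p
  w / sum(w)
}

rtrim <- function(n, p, max) {
  if (max == 0L) return(rep(0L, n))
  sample.int(max + 1L, n, replace = TRUE, prob = trim_pmf(p, max)) - 1L
}

random_nt <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

translate_nt <- function(nt) {
  n <- nchar(nt)
  if (n == 0L || n %% 3L != 0L) return(NA_character_)
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

count_mismatches <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

# feasibility of the model against the gene set geometry
check_geometry <- function(germline, model) {
  mt <- model$max_trim
  for (g in germline$V) {
    if (mt[["v3"]] > g$length - g$junction_start - 2L) {
      abort_airr(sprintf(
        "max v3 trim %d would erase the junction anchor of '%s'",
        mt[["v3"]], g$name), "airr_domain_error")
    }
  }
  for (g in germline$D) {
    if (mt[["d5"]] + mt[["d3"]] > g$length - 1L) {
      abort_airr(sprintf("max D trims would consume all of '%s'", g$name),
                 "airr_domain_error")
    }
  }
  for (g in germline$J) {
    if (mt[["j5"]] > g$junction_end - 3L) {
      abort_airr(sprintf(
        "max j5 trim %d would erase the junction anchor of '%s'",
        mt[["j5"]], g$name), "airr_domain_error")
    }
  }
  invisible(TRUE)
}

#' Simulate one annotated rearrangement
#'
#' @param germline a `germline_set`.
#' @param model a `recombination_model`.
#' @param sequence_id identifier to stamp on the record.
#' @return a list with `record` (named list of typed values covering
#'   every schema field) and `truth` (the hidden generation ledger:
#'   alleles, trims, insertion lengths, mutated positions, and segment
#'   contributions to the junction).
#' @export
simulate_rearrangement <- function(germline, model = recombination_model(),
                                   sequence_id = "sim_1") {
  has_d <- length(germline$D) > 0L
  V <- germline$V[[sample.int(length(germline$V), 1L)]]
  D <- if (has_d) germline$D[[sample.int(length(germline$D), 1L)]] else NULL
  J <- germline$J[[sample.int(length(germline$J), 1L)]]

  p <- model$trim_prob
  mt <- model$max_trim
  t_v3 <- rtrim(1L, p, mt[["v3"]])
  t_d5 <- if (has_d) rtrim(1L, p, mt[["d5"]]) else NA_integer_
  t_d3 <- if (has_d) rtrim(1L, p, mt[["d3"]]) else NA_integer_
  t_j5 <- rtrim(1L, p, mt[["j5"]])
  np1_len <- rpois(1L, model$np_lambda[["np1"]])
  np2_len <- if (has_d) rpois(1L, model$np_lambda[["np2"]]) else NA_integer_

  v_part <- substr(V$sequence, 1L, V$length - t_v3)
  d_part <- if (has_d) substr(D$sequence, t_d5 + 1L, D$length - t_d3) else ""
  j_part <- substr(J$sequence, t_j5 + 1L, J$length)
  np1 <- random_nt(np1_len)
  np2 <- if (has_d) random_nt(np2_len) else ""

  germ_concat <- paste0(v_part, np1, d_part, np2, j_part)
  L <- nchar(germ_concat)

  # point mutations
  mut_pos <- which(runif(L) < model$mu)
  sequence <- germ_concat
  if (length(mut_pos)) {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    for (i in mut_pos) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    }
    sequence <- paste(chars, collapse = "")
  }

  # coordinates (1-based closed, V starts the query)
  v_len <- nchar(v_part)
  d_len <- nchar(d_part)
  j_len <- nchar(j_part)
  v_iv <- c(1L, v_len)
  d_iv <- if (has_d) c(v_len + np1_len + 1L, v_len + np1_len + d_len) else c(NA_integer_, NA_integer_)
  j_start <- L - j_len + 1L
  j_iv <- c(j_start, L)

  # per-gene CIGARs: M inside the aligned segment, S for the rest of
  # the query (the simulator introduces no indels)
  scig <- function(pre, m, post) {
    paste0(if (pre > 0L) paste0(pre, "S"), m, "M",
           if (post > 0L) paste0(post, "S"))
  }
  v_cigar <- scig(0L, v_len, L - v_len)
  d_cigar <- if (has_d) scig(d_iv[1L] - 1L, d_len, L - d_iv[2L]) else NA_character_
  j_cigar <- scig(j_start - 1L, j_len, 0L)

  # junction: conserved V anchor through conserved J anchor, inclusive
  js_q <- V$junction_start
  je_q <- j_start + (J$junction_end - t_j5) - 1L
  junction <- substr(sequence, js_q, je_q)
  junction_length <- je_q - js_q + 1L
  junction_aa <- translate_nt(junction)
  in_frame <- junction_length %% 3L == 0L
  productive <- in_frame && !grepl("*", junction_aa, fixed = TRUE)

  # alignment rows: the query against the assembled germline, with the
  # untemplated insertions masked as N on the germline side
  germline_row <- paste0(v_part, strrep("N", np1_len), d_part,
                         if (has_d) strrep("N", np2_len) else "", j_part)

  mismatches <- function(iv, germ_sub) {
    if (is.na(iv[1L])) return(NA_integer_)
    count_mismatches(substr(sequence, iv[1L], iv[2L]), germ_sub)
  }
  v_mm <- mismatches(v_iv, v_part)
  d_mm <- if (has_d) mismatches(d_iv, d_part) else NA_integer_
  j_mm <- mismatches(j_iv, j_part)

  score <- function(len, mm) {
    if (is.na(mm)) NA_real_ else as.numeric(5L * (len - mm) - 4L * mm)
  }
  identity <- function(len, mm) {
    if (is.na(mm)) NA_real_ else round(100 * (len - mm) / len, 2L)
  }

  # regions: FWR1-FWR3/CDR1-CDR2 map through the (identity) V
  # alignment; CDR3 is the junction without its anchor codons; FWR4
  # follows the junction to the end of the J gene
  region <- function(iv) {
    list(seq = substr(sequence, iv[1L], iv[2L]),
         start = iv[1L], end = iv[2L])
  }
  regions <- lapply(V$regions, region)
  cdr3 <- if (junction_length > 6L) {
    list(seq = substr(sequence, js_q + 3L, je_q - 3L),
         start = js_q + 3L, end = je_q - 3L)
  } else list(seq = NA_character_, start = NA_integer_, end = NA_integer_)
  fwr4 <- if (je_q < L) {
    list(seq = substr(sequence, je_q + 1L, L),
         start = je_q + 1L, end = L)
  } else list(seq = NA_character_, start = NA_integer_, end = NA_integer_)

  duplicate_count <- 1L + rpois(1L, model$dup_lambda)
  consensus_count <- duplicate_count + rpois(1L, model$cons_lambda)

  record <- list(
    sequence_id = sequence_id,
    sequence = sequence,
    sequence_aa = translate_nt(sequence),
    locus = germline$locus,
    v_call = V$name,
    d_call = if (has_d) D$name else NA_character_,
    j_call = J$name,
    c_call = NA_character_,
    rev_comp = FALSE,
    productive = productive,
    junction = junction,
    junction_aa = junction_aa,
    duplicate_count = duplicate_count,
    consensus_count = consensus_count,
    v_score = score(v_len, v_mm),
    v_identity = identity(v_len, v_mm),
    v_support = NA_real_,
    v_cigar = v_cigar,
    d_score = if (has_d) score(d_len, d_mm) else NA_real_,
    d_identity = if (has_d) identity(d_len, d_mm) else NA_real_,
    d_support = NA_real_,
    d_cigar = d_cigar,
    j_score = score(j_len, j_mm),
    j_identity = identity(j_len, j_mm),
    j_support = NA_real_,
    j_cigar = j_cigar,
    sequence_alignment = sequence,
    germline_alignment = germline_row,
    v_sequence_start = v_iv[1L], v_sequence_end = v_iv[2L],
    v_germline_start = 1L, v_germline_end = v_len,
    d_sequence_start = d_iv[1L], d_sequence_end = d_iv[2L],
    d_germline_start = if (has_d) t_d5 + 1L else NA_integer_,
    d_germline_end = if (has_d) D$length - t_d3 else NA_integer_,
    j_sequence_start = j_iv[1L], j_sequence_end = j_iv[2L],
    j_germline_start = t_j5 + 1L, j_germline_end = J$length,
    fwr1 = regions$fwr1$seq, cdr1 = regions$cdr1$seq,
    fwr2 = regions$fwr2$seq, cdr2 = regions$cdr2$seq,
    fwr3 = regions$fwr3$seq, cdr3 = cdr3$seq, fwr4 = fwr4$seq,
    fwr1_start = regions$fwr1$start, fwr1_end = regions$fwr1$end,
    cdr1_start = regions$cdr1$start, cdr1_end = regions$cdr1$end,
    fwr2_start = regions$fwr2$start, fwr2_end = regions$fwr2$end,
    cdr2_start = regions$cdr2$start, cdr2_end = regions$cdr2$end,
    fwr3_start = regions$fwr3$start, fwr3_end = regions$fwr3$end,
    cdr3_start = cdr3$start, cdr3_end = cdr3$end,
    fwr4_start = fwr4$start, fwr4_end = fwr4$end,
    junction_length = junction_length,
    junction_aa_length = if (in_frame) nchar(junction_aa) else NA_integer_,
    np1_length = as.integer(np1_len),
    np2_length = if (has_d) as.integer(np2_len) else NA_integer_
  )

  truth <- list(
    sequence_id = sequence_id,
    v_call = V$name, d_call = record$d_call, j_call = J$name,
    v_trim_3 = t_v3, d_trim_5 = t_d5, d_trim_3 = t_d3, j_trim_5 = t_j5,
    np1_length = as.integer(np1_len),
    np2_length = if (has_d) as.integer(np2_len) else NA_integer_,
    np1 = np1, np2 = if (has_d) np2 else NA_character_,
    v_length = v_len, d_length = if (has_d) d_len else NA_integer_,
    j_length = j_len,
    v_junction = v_len - V$junction_start + 1L,
    j_junction = J$junction_end - t_j5,
    n_mutations = length(mut_pos),
    mutated_positions = mut_pos,
    sequence_length = L
  )
  list(record = record, truth = truth)
}

#' Simulate a dataset of annotated rearrangements
#'
#' @param n number of records (>= 0).
#' @param germline a `germline_set`.
#' @param model a `recombination_model`.
#' @param file optional output TSV path (written via
#'   [write_rearrangements()]; `n = 0` gives a valid header-only file).
#' @param truth_file optional path for the truth ledger, written as a
#'   JSON document.
#' @param seed optional integer; when given, the generator is run on a
#'   private RNG state (the caller's state is untouched) and output is
#'   byte-deterministic.
#' @return invisibly, a list with `records` (typed data frame) and
#'   `truth` (data frame, one row per record, scalar ledger fields).
#' @export
simulate_dataset <- function(n, germline = toy_germline_set("heavy"),
                             model = recombination_model(), file = NULL,
                             truth_file = NULL, seed = NULL) {
  stopifnot(n >= 0)
  check_geometry(germline, model)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  sims <- lapply(seq_len(n), function(i) {
    simulate_rearrangement(germline, model,
                           sequence_id = sprintf("sim_%06d", i))
  })
  schema <- default_schema()
  cols <- schema$fields$name
  records <- if (n > 0L) {
    out <- lapply(cols, function(nm) unlist(lapply(sims, function(s) s$record[[nm]])))
    names(out) <- cols
    structure(out, class = "data.frame", row.names = seq_len(n))
  } else {
    out <- lapply(cols, function(nm) {
      k <- field_kind(schema, nm)
      vector(typeof(typed_na(k)), 0L)
    })
    names(out) <- cols
    structure(out, class = "data.frame", row.names = integer(0))
  }
  truth_cols <- c("sequence_id", "v_call", "d_call", "j_call", "v_trim_3",
                  "d_trim_5", "d_trim_3", "j_trim_5", "np1_length",
                  "np2_length", "v_length", "d_length", "j_length",
                  "v_junction", "j_junction", "n_mutations",
                  "sequence_length")
  truth <- if (n > 0L) {
    out <- lapply(truth_cols, function(nm) unlist(lapply(sims, function(s) s$truth[[nm]])))
    names(out) <- truth_cols
    structure(out, class = "data.frame", row.names = seq_len(n))
  } else NULL
  if (!is.null(file)) write_rearrangements(records, file, schema)
  if (!is.null(truth_file)) {
    write_atomic(truth_file, function(tmp) {
      jsonlite::write_json(truth, tmp, dataframe = "rows", na = "null")
    })
  }
  invisible(list(records = records, truth = truth))
}
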