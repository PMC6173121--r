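# Independent oracles for the alignment algebra.  These deliberately
# do not reuse the package's parsers: BTOP strings are expanded to an
# aligned placeholder pair column by column, and CIGARs are derived by
# naive column classification, so agreement with the package is a real
# cross-check.

# expand a BTOP string to an aligned (query, ref) pair over
# placeholder residues ("A" for matching positions)
oracle_expand_btop <- function(btop) {
  chars <- strsplit(btop, "", fixed = TRUE)[[1L]]
  q <- character(0)
  r <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    if (grepl("[0-9]", chars[i])) {
      j <- i
      while (j < length(chars) && grepl("[0-9]", chars[j + 1L])) j <- j + 1L
      n <- as.integer(paste(chars[i:j], collapse = ""))
      q <- c(q, rep("A", n))
      r <- c(r, rep("A", n))
      i <- j + 1L
    } else {
      q <- c(q, chars[i])
      r <- c(r, chars[i + 1L])
      i <- i + 2L
    }
  }
  list(query = paste(q, collapse = ""), ref = paste(r, collapse = ""))
}

# naive per-column CIGAR from an aligned pair (independent of the
# package's merge machinery: builds the run-length encoding directly)
oracle_cigar_from_pair <- function(aq, ar, mode = "=X") {
  q <- strsplit(aq, "", fixed = TRUE)[[1L]]
  r <- strsplit(ar, "", fixed = TRUE)[[1L]]
  ops <- character(length(q))
  for (k in seq_along(q)) {
    ops[k] <- if (r[k] == "-") "I" else if (q[k] == "-") "D"
      else if (mode == "M") "M" else if (q[k] == r[k]) "=" else "X"
  }
  rle_ops <- rle(ops)
  paste0(rle_ops$lengths, rle_ops$values, collapse = "")
}

# random gapped alignment with no double-gap columns and no leading/
# trailing structure constraints
random_gapped_pair <- function(len = sample(5:40, 1L)) {
  bases <- c("A", "C", "G", "T")
  kind <- sample(c("match", "mismatch", "ins", "del"), len, replace = TRUE,
                 prob = c(0.6, 0.2, 0.1, 0.1))
  q <- character(len)
  r <- character(len)
  for (k in seq_len(len)) {
    if (kind[k] == "match") {
      b <- sample(bases, 1L)
      q[k] <- b
      r[k] <- b
    } else if (kind[k] == "mismatch") {
      b <- sample(bases, 2L)
      q[k] <- b[1L]
      r[k] <- b[2L]
    } else if (kind[k] == "ins") {
      q[k] <- sample(bases, 1L)
      r[k] <- "-"
    } else {
      q[k] <- "-"
      r[k] <- sample(bases, 1L)
    }
  }
  list(query = paste(q, collapse = ""), ref = paste(r, collapse = ""))
}

# random syntactically valid BTOP string: mismatch pairs use distinct
# residues and digit runs never abut (both would be ill-formed BTOP)
random_btop <- function() {
  n_tok <- sample(1:8, 1L)
  bases <- c("A", "C", "G", "T")
  toks <- character(n_tok)
  prev_digit <- FALSE
  for (k in seq_len(n_tok)) {
    digit <- !prev_digit && runif(1) < 0.5
    toks[k] <- if (digit) {
      as.character(sample(1:50, 1L))
    } else {
      switch(sample(3, 1L),
        paste(sample(bases, 2L), collapse = ""),   # true mismatch
        paste0(sample(bases, 1L), "-"),
        paste0("-", sample(bases, 1L)))
    }
    prev_digit <- digit
  }
  paste(toks, collapse = "")
}
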