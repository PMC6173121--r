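#' @title CIGAR and BTOP alignment encodings
#' @description
#' Alignments of a query to a germline gene are conveyed as SAM-style
#' CIGAR strings.  Operator consumption follows the SAM convention:
#' `M`, `=`, `X` consume both query and reference; `I` and `S` consume
#' query only; `D` and `N` consume reference only.  Alignment columns
#' are emitted by `M`/`=`/`X` (both rows), `I` (gap in the reference
#' row), and `D` (gap in the query row); `S` (soft clip) and `N`
#' (skipped reference) consume sequence without emitting columns.
#' BLAST's BTOP traceback is an alternative compact encoding converted
#' from via [btop_to_cigar()].
#' @name cigar
NULL

CIGAR_OPS <- c("M", "=", "X", "I", "D", "S", "N")
QUERY_OPS <- c("M", "=", "X", "I", "S")
REF_OPS <- c("M", "=", "X", "D", "N")
COLUMN_OPS <- c("M", "=", "X", "I", "D")

# merge adjacent runs of the same operator (canonical form)
merge_ops <- function(ops) {
  if (nrow(ops) <= 1L) return(ops)
  grp <- cumsum(c(TRUE, ops$op[-1L] != ops$op[-nrow(ops)]))
  out <- data.frame(
    op = ops$op[!duplicated(grp)],
    length = as.integer(tapply(ops$length, grp, sum)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

as_ops <- function(x) {
  if (is.character(x)) return(parse_cigar(x))
  stopifnot(is.data.frame(x), all(c("op", "length") %in% names(x)))
  x
}

#' Parse a CIGAR string into canonical operations
#'
#' @param text a non-empty CIGAR string, e.g. `"3M1D4M2I1M"`.
#' @return a data frame with columns `op` and `length`, adjacent equal
#'   operators merged.  Unknown operator letters and zero lengths are
#'   rejected with a parse error reporting the byte position.
#' @examples
#' parse_cigar("5M5M")   # one 10M run
#' @export
parse_cigar <- function(text) {
  if (!is_string(text) || !nzchar(text)) {
    abort_airr("CIGAR text must be a non-empty string", "airr_parse_error")
  }
  m <- gregexpr("([0-9]+)([A-Za-z=])", text)[[1L]]
  tokens <- regmatches(text, gregexpr("([0-9]+)([A-Za-z=])", text))[[1L]]
  covered <- if (m[1L] == -1L) 0L else sum(attr(m, "match.length"))
  contiguous <- m[1L] == 1L &&
    all(m[-1L] == head(m, -1L) + head(attr(m, "match.length"), -1L))
  if (covered != nchar(text) || !contiguous) {
    # locate the first byte not part of a valid token
    pos <- if (m[1L] == -1L || m[1L] != 1L) 1L else {
      ends <- m + attr(m, "match.length")
      gap <- which(m[-1L] != ends[-length(ends)])
      if (length(gap)) ends[gap[1L]] else ends[length(ends)]
    }
    abort_airr(sprintf("malformed CIGAR at byte %d of %s", pos,
                       deparse(text)), "airr_parse_error", position = pos)
  }
  len <- as.integer(sub("[A-Za-z=]$", "", tokens))
  op <- sub("^[0-9]+", "", tokens)
  bad <- which(!(op %in% CIGAR_OPS) | len < 1L)
  if (length(bad)) {
    pos <- if (bad[1L] == 1L) 1L else sum(nchar(tokens[seq_len(bad[1L] - 1L)])) + 1L
    abort_airr(sprintf("invalid CIGAR operation '%s%s' at byte %d",
                       len[bad[1L]], op[bad[1L]], pos),
               "airr_parse_error", position = pos)
  }
  merge_ops(data.frame(op = op, length = len, stringsAsFactors = FALSE))
}

#' Serialize operations back to CIGAR text
#' @param ops an operation data frame (or a CIGAR string, returned
#'   canonicalized).
#' @export
cigar_string <- function(ops) {
  ops <- merge_ops(as_ops(ops))
  paste0(ops$length, ops$op, collapse = "")
}

#' Query and reference spans of a CIGAR
#'
#' @param ops operations (data frame or CIGAR string).
#' @param clipped if `TRUE` (default), count every consuming operator
#'   (`S` on the query side, `N` on the reference side included); if
#'   `FALSE`, count only the aligned span (clips and skips excluded) —
#'   the span that corresponds to the `*_start`/`*_end` interval of an
#'   aligned gene segment.
#' @return named numeric `c(query = , ref = )`.
#' @examples
#' cigar_spans("3M1D4M2I1M")            # query 10, ref 9
#' cigar_spans("2S5M", clipped = FALSE) # query 5, ref 5
#' @export
cigar_spans <- function(ops, clipped = TRUE) {
  ops <- as_ops(ops)
  qops <- if (clipped) QUERY_OPS else setdiff(QUERY_OPS, "S")
  rops <- if (clipped) REF_OPS else setdiff(REF_OPS, "N")
  c(query = sum(ops$length[ops$op %in% qops]),
    ref = sum(ops$length[ops$op %in% rops]))
}

#' Expand a CIGAR into the gapped alignment it encodes
#'
#' Walks the operations over the query and reference sequences,
#' starting at the given 1-based positions, and produces the two
#' equal-length aligned rows: `I` emits a gap in the reference row,
#' `D` a gap in the query row; `S` and `N` consume sequence without
#' emitting columns.
#'
#' @param query,ref nucleotide strings.
#' @param ops operations (data frame or CIGAR string).
#' @param query_start,ref_start 1-based start positions at which
#'   consumption begins.
#' @return a `gapped_alignment`: list with `aligned_query`,
#'   `aligned_ref` (equal-length strings over the sequence alphabet
#'   plus `"-"`), and `query_interval`, `ref_interval` (1-based closed
#'   intervals actually covered by alignment columns).
#' @examples
#' reconstruct_alignment("ACGGT", "ACT", "2M2I1M")
#' @export
reconstruct_alignment <- function(query, ref, ops, query_start = 1L,
                                  ref_start = 1L) {
  ops <- as_ops(ops)
  qchars <- strsplit(query, "", fixed = TRUE)[[1L]]
  rchars <- strsplit(ref, "", fixed = TRUE)[[1L]]
  qpos <- as.integer(query_start)
  rpos <- as.integer(ref_start)
  aq <- character(0)
  ar <- character(0)
  q_iv <- c(NA_integer_, NA_integer_)
  r_iv <- c(NA_integer_, NA_integer_)
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]
    n <- ops$length[i]
    takes_q <- op %in% QUERY_OPS
    takes_r <- op %in% REF_OPS
    if (takes_q && qpos + n - 1L > length(qchars)) {
      abort_airr(sprintf(
        "operation %d (%d%s) overruns the query sequence (length %d)",
        i, n, op, length(qchars)), "airr_bounds_error", op_index = i)
    }
    if (takes_r && rpos + n - 1L > length(rchars)) {
      abort_airr(sprintf(
        "operation %d (%d%s) overruns the reference sequence (length %d)",
        i, n, op, length(rchars)), "airr_bounds_error", op_index = i)
    }
    if (op %in% COLUMN_OPS) {
      if (takes_q) {
        if (is.na(q_iv[1L])) q_iv[1L] <- qpos
        q_iv[2L] <- qpos + n - 1L
      }
      if (takes_r) {
        if (is.na(r_iv[1L])) r_iv[1L] <- rpos
        r_iv[2L] <- rpos + n - 1L
      }
      aq <- c(aq, if (takes_q) qchars[qpos:(qpos + n - 1L)] else rep("-", n))
      ar <- c(ar, if (takes_r) rchars[rpos:(rpos + n - 1L)] else rep("-", n))
    }
    if (takes_q) qpos <- qpos + n
    if (takes_r) rpos <- rpos + n
  }
  structure(list(aligned_query = paste(aq, collapse = ""),
                 aligned_ref = paste(ar, collapse = ""),
                 query_interval = q_iv, ref_interval = r_iv),
            class = "gapped_alignment")
}

#' @export
print.gapped_alignment <- function(x, ...) {
  cat(sprintf("qry [%s-%s] %s\nref [%s-%s] %s\n",
              x$query_interval[1L], x$query_interval[2L], x$aligned_query,
              x$ref_interval[1L], x$ref_interval[2L], x$aligned_ref))
  invisible(x)
}

#' Derive CIGAR operations from a gapped alignment
#'
#' The inverse of [reconstruct_alignment()]: per column, two residues
#' give `M` (or `=`/`X` by equality in `=X` mode), a gap in the
#' reference row gives `I`, a gap in the query row gives `D`; adjacent
#' equal operators are merged.  `"."` is accepted as a gap synonym and
#' treated as `"-"`.
#'
#' @param aligned_query,aligned_ref equal-length aligned rows.
#' @param mode `"M"` (match/mismatch merged; the default, for maximal
#'   tool compatibility) or `"=X"` (distinguished).
#' @return canonical operation data frame.
#' @examples
#' cigar_string(build_cigar_from_gapped("ACGT", "ACTT", mode = "=X"))
#' @export
build_cigar_from_gapped <- function(aligned_query, aligned_ref,
                                    mode = c("M", "=X")) {
  mode <- match.arg(mode)
  if (nchar(aligned_query) != nchar(aligned_ref)) {
    abort_airr("aligned rows must have equal length", "airr_structure_error")
  }
  q <- strsplit(chartr(".", "-", aligned_query), "", fixed = TRUE)[[1L]]
  r <- strsplit(chartr(".", "-", aligned_ref), "", fixed = TRUE)[[1L]]
  qgap <- q == "-"
  rgap <- r == "-"
  if (any(qgap & rgap)) {
    abort_airr(sprintf("double-gap column at position %d",
                       which(qgap & rgap)[1L]), "airr_structure_error")
  }
  op <- character(length(q))
  op[rgap] <- "I"
  op[qgap] <- "D"
  both <- !qgap & !rgap
  op[both] <- if (mode == "M") "M" else ifelse(q[both] == r[both], "=", "X")
  merge_ops(data.frame(op = op, length = 1L, stringsAsFactors = FALSE))
}

#' Convert a BLAST BTOP traceback to CIGAR operations
#'
#' BTOP encodes an alignment as runs of digits (counts of matching
#' positions) interleaved with two-character tokens `(query, ref)`
#' where `"-"` in either slot denotes a gap.  Digits become `M` (or
#' `=`) runs; a residue pair becomes `1M` (or `1X`); `(nt, -)` becomes
#' `1I`; `(-, nt)` becomes `1D`.
#'
#' @param btop a BTOP string, e.g. `"7AG38"`.
#' @param mode `"M"` or `"=X"`, as in [build_cigar_from_gapped()].
#' @return canonical operation data frame.
#' @examples
#' cigar_string(btop_to_cigar("4C-3-A2"))   # "4M1I3M1D2M"
#' @export
btop_to_cigar <- function(btop, mode = c("M", "=X")) {
  mode <- match.arg(mode)
  if (!is_string(btop) || !nzchar(btop)) {
    abort_airr("BTOP text must be a non-empty string", "airr_parse_error")
  }
  match_op <- if (mode == "M") "M" else "="
  mismatch_op <- if (mode == "M") "M" else "X"
  chars <- strsplit(btop, "", fixed = TRUE)[[1L]]
  ops <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    if (grepl("[0-9]", chars[i])) {
      j <- i
      while (j < n && grepl("[0-9]", chars[j + 1L])) j <- j + 1L
      run <- as.integer(paste(chars[i:j], collapse = ""))
      if (run > 0L) {
        ops[[length(ops) + 1L]] <- data.frame(op = match_op, length = run,
                                              stringsAsFactors = FALSE)
      }
      i <- j + 1L
    } else {
      if (i + 1L > n) {
        abort_airr(sprintf("dangling single character at byte %d of BTOP %s",
                           i, deparse(btop)), "airr_parse_error")
      }
      a <- chars[i]
      b <- chars[i + 1L]
      if (a == "-" && b == "-") {
        abort_airr(sprintf("invalid '--' pair at byte %d of BTOP %s",
                           i, deparse(btop)), "airr_parse_error")
      }
      op <- if (a == "-") "D" else if (b == "-") "I" else mismatch_op
      ops[[length(ops) + 1L]] <- data.frame(op = op, length = 1L,
                                            stringsAsFactors = FALSE)
      i <- i + 2L
    }
  }
  if (length(ops) == 0L) {
    abort_airr("BTOP encodes an empty alignment", "airr_parse_error")
  }
  merge_ops(do.call(rbind, ops))
}
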