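#' @title Splittable file access
#' @description
#' The format is line-oriented so that a reader can start at an
#' arbitrary byte offset, skip to the next newline, and pick up whole
#' records — provided the container is splittable.  Plain text and
#' blocked gzip (BGZF) are splittable; standard gzip is not, because a
#' mid-stream byte offset cannot be decoded without the preceding
#' history.  bzip2 is splittable in principle (block-structured) but
#' offset reads for it are not implemented here.
#' @name splittable-io
NULL

#' Identify the compression container of a file
#'
#' Detection is by magic bytes, not file extension: BGZF is a gzip
#' member stream whose extra field carries a `BC` block-size subfield.
#'
#' @param path an existing file.
#' @return one of `"plain"`, `"gzip"`, `"bgzf"`, `"bzip2"`.
#' @export
detect_compression <- function(path) {
  if (!file.exists(path)) {
    abort_airr(sprintf("no such file: '%s'", path), "airr_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 4L)
  if (length(hdr) >= 3L && identical(hdr[1:3], charToRaw("BZh"))) {
    return("bzip2")
  }
  if (length(hdr) >= 2L && hdr[1L] == as.raw(0x1f) && hdr[2L] == as.raw(0x8b)) {
    # FLG.FEXTRA set and a BC subfield present => BGZF
    if (length(hdr) == 4L && as.integer(hdr[4L]) %% 8L >= 4L) {
      rest <- readBin(con, "raw", 8L)           # MTIME/XFL/OS + XLEN
      if (length(rest) == 8L) {
        xlen <- as.integer(rest[7L]) + 256L * as.integer(rest[8L])
        extra <- readBin(con, "raw", xlen)
        i <- 1L
        while (i + 3L <= length(extra)) {
          si <- rawToChar(extra[i:(i + 1L)])
          slen <- as.integer(extra[i + 2L]) + 256L * as.integer(extra[i + 3L])
          if (si == "BC" && slen == 2L) return("bgzf")
          i <- i + 4L + slen
        }
      }
    }
    return("gzip")
  }
  "plain"
}

#' Open a rearrangement TSV source
#'
#' @param path an existing file, possibly compressed.
#' @return a list with `path`, `compression` (see
#'   [detect_compression()]), `splittable` (whether the container
#'   admits record-boundary recovery from arbitrary offsets), and
#'   `open`, a zero-argument function returning a fresh text-mode
#'   connection for sequential reading.
#' @export
open_source <- function(path) {
  compression <- detect_compression(path)
  opener <- switch(compression,
    plain = function() file(path, "rt", encoding = "UTF-8"),
    gzip = ,
    bgzf = function() gzfile(path, "rt", encoding = "UTF-8"),
    bzip2 = function() bzfile(path, "rt", encoding = "UTF-8"))
  list(path = path, compression = compression,
       splittable = compression %in% c("plain", "bzip2", "bgzf"),
       open = opener)
}

read_source_lines <- function(path, n = -1L) {
  src <- open_source(path)
  con <- src$open()
  on.exit(close(con))
  lines <- readLines(con, n = n, warn = FALSE)
  sub("\r$", "", lines)
}

# ---- BGZF block machinery -------------------------------------------------

# Byte offsets of every BGZF block (gzip member) in the file, plus the
# block sizes, obtained by walking the BC extra subfields.
bgzf_block_starts <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  starts <- integer(0)
  sizes <- integer(0)
  pos <- 0
  while (pos < sz) {
    seek(con, pos)
    hdr <- readBin(con, "raw", 12L)
    if (length(hdr) < 12L || hdr[1L] != as.raw(0x1f) ||
        hdr[2L] != as.raw(0x8b) || as.integer(hdr[4L]) %% 8L < 4L) {
      abort_airr(sprintf("'%s': malformed BGZF block at offset %.0f",
                         path, pos), "airr_io_error")
    }
    xlen <- as.integer(hdr[11L]) + 256L * as.integer(hdr[12L])
    extra <- readBin(con, "raw", xlen)
    bsize <- NA_integer_
    i <- 1L
    while (i + 3L <= xlen) {
      si <- rawToChar(extra[i:(i + 1L)])
      slen <- as.integer(extra[i + 2L]) + 256L * as.integer(extra[i + 3L])
      if (si == "BC" && slen == 2L) {
        bsize <- as.integer(extra[i + 4L]) + 256L * as.integer(extra[i + 5L]) + 1L
        break
      }
      i <- i + 4L + slen
    }
    if (is.na(bsize)) {
      abort_airr(sprintf("'%s': BGZF block at offset %.0f lacks a BC subfield",
                         path, pos), "airr_io_error")
    }
    starts <- c(starts, pos)
    sizes <- c(sizes, bsize)
    pos <- pos + bsize
  }
  list(starts = starts, sizes = sizes)
}

# Decompress all BGZF blocks from block index `from` to the end of file
# and return the concatenated payload bytes.  memDecompress handles one
# gzip member at a time, so blocks are inflated individually.
bgzf_payload_from <- function(path, blocks, from) {
  if (from > length(blocks$starts)) return(raw(0))
  con <- file(path, "rb")
  on.exit(close(con))
  parts <- vector("list", length(blocks$starts) - from + 1L)
  for (k in from:length(blocks$starts)) {
    seek(con, blocks$starts[k])
    blk <- readBin(con, "raw", blocks$sizes[k])
    parts[[k - from + 1L]] <- memDecompress(blk, type = "gzip")
  }
  do.call(c, parts)
}

# ---- offset reads ---------------------------------------------------------

# Raw data lines (header excluded) from the given byte offset to end of
# file: skip to the first newline at/after `offset`, then take complete
# lines.  Offset 0 therefore skips the header line.
lines_from_offset <- function(path, offset) {
  compression <- detect_compression(path)
  if (compression == "gzip") {
    abort_airr(paste0(
      "'", path, "' is compressed with standard gzip, which is not ",
      "splittable; offset reads need a splittable container ",
      "(plain text, BGZF, or bzip2) - consider recompressing with bgzip"),
      "airr_offset_unsupported", compression = "gzip")
  }
  if (compression == "bzip2") {
    abort_airr(paste0(
      "offset reads from bzip2 streams are not implemented by this ",
      "reader; use plain text or BGZF for split access"),
      "airr_offset_unsupported", compression = "bzip2")
  }
  txt <- if (compression == "plain") {
    sz <- file.size(path)
    if (offset >= sz) return(character(0))
    con <- file(path, "rb")
    on.exit(close(con))
    seek(con, offset)
    rawToChar(readBin(con, "raw", sz - offset))
  } else { # bgzf
    blocks <- bgzf_block_starts(path)
    from <- which(blocks$starts >= offset)
    if (length(from) == 0L) return(character(0))
    payload <- bgzf_payload_from(path, blocks, from[1L])
    if (length(payload) == 0L) return(character(0))
    rawToChar(payload)
  }
  nl <- regexpr("\n", txt, fixed = TRUE)
  if (nl < 0L) return(character(0))
  body <- substr(txt, nl + 1L, nchar(txt))
  if (!nzchar(body)) return(character(0))
  lines <- strsplit(body, "\n", fixed = TRUE)[[1L]]
  sub("\r$", "", lines[nzchar(lines)])
}

#' Read records starting at an arbitrary byte offset
#'
#' Seeks to `offset` (a position in the file's compressed byte space),
#' skips forward to the first record boundary (newline), and reads all
#' complete records from there to the end of the file.  With `offset =
#' 0` the header line is skipped and the whole file is read.  For BGZF
#' input the reader resynchronises at the first block boundary at or
#' after `offset` and then applies the same newline rule to the
#' decompressed text.
#'
#' Because the set of records returned for offset `b` is always a
#' suffix of the set returned for offset `a < b`, the records whose
#' boundary falls in a half-open byte segment `[a, b)` are exactly
#' `read_from_offset(a)` minus `read_from_offset(b)` — the property
#' that makes partitioned (parallel) reading lossless.
#'
#' @param path a plain or BGZF-compressed rearrangement TSV.
#' @param offset byte offset (>= 0) into the file as stored.
#' @param schema an `airr_schema`.
#' @param strict abort on malformed cells instead of reporting them.
#' @return a typed data frame of records (possibly empty); column set
#'   and typing as in [read_rearrangements()].
#' @export
read_from_offset <- function(path, offset, schema = default_schema(),
                             strict = FALSE) {
  stopifnot(offset >= 0)
  header <- parse_header_line(read_source_lines(path, n = 1L), path)
  lines <- lines_from_offset(path, offset)
  res <- parse_record_lines(lines, header, schema, strict = strict)
  res$records
}
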