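#' @title Coordinate-convention transforms
#' @description
#' All positions in the format are 1-based closed intervals, the
#' convention shared with SAM, VCF, GFF, IMGT, and the INSDC flat
#' files.  Internal/array arithmetic and several legacy dialects use
#' 0-based half-open coordinates or start+length encodings instead;
#' these helpers are the bijections between the conventions.
#' @name intervals
NULL

check_interval <- function(start, end) {
  bad <- !is.na(start) & !is.na(end) & (start < 1L | start > end)
  if (any(bad)) {
    abort_airr(sprintf("invalid 1-based closed interval [%s, %s]",
                       start[bad][1L], end[bad][1L]), "airr_domain_error")
  }
}

#' Convert a 1-based closed interval to 0-based half-open
#'
#' @param start,end 1-based closed endpoints (`1 <= start <= end`);
#'   vectorized, `NA` passes through.
#' @return a list with `lo` (= start - 1) and `hi` (= end); the
#'   interval length equals `hi - lo` equals `end - start + 1`.
#' @examples
#' interval_to_zero_based(1, 10)   # lo 0, hi 10
#' @export
interval_to_zero_based <- function(start, end) {
  check_interval(start, end)
  list(lo = start - 1L, hi = end)
}

#' @rdname interval_to_zero_based
#' @param lo,hi 0-based half-open endpoints (`0 <= lo < hi`).
#' @export
zero_based_to_interval <- function(lo, hi) {
  bad <- !is.na(lo) & !is.na(hi) & (lo < 0L | lo >= hi)
  if (any(bad)) {
    abort_airr(sprintf("invalid 0-based half-open interval [%s, %s)",
                       lo[bad][1L], hi[bad][1L]), "airr_domain_error")
  }
  list(start = lo + 1L, end = hi)
}

#' Closed-interval end from start and length (and back)
#'
#' Legacy dialects often store a start plus a length where this format
#' stores a closed interval.  A feature of length 0 has no closed
#' interval, so `end_from_length(start, 0)` is null (`NA`).
#'
#' @param start 1-based start coordinate(s), >= 1.
#' @param length non-negative feature length(s).
#' @return `end_from_length()`: `start + length - 1`, or `NA` for
#'   length 0; `length_from_end()`: `end - start + 1`.
#' @examples
#' end_from_length(21, 1)   # 21
#' end_from_length(7, 0)    # NA: empty feature
#' @export
end_from_length <- function(start, length) {
  if (any(!is.na(length) & length < 0)) {
    abort_airr("feature lengths must be non-negative", "airr_domain_error")
  }
  if (any(!is.na(start) & start < 1)) {
    abort_airr("start coordinates must be >= 1", "airr_domain_error")
  }
  out <- ifelse(is.na(start) | is.na(length) | length == 0L,
                NA_integer_, as.integer(start + length - 1L))
  out
}

#' @rdname end_from_length
#' @param end 1-based closed end coordinate(s).
#' @export
length_from_end <- function(start, end) {
  check_interval(start, end)
  ifelse(is.na(start) | is.na(end), NA_integer_,
         as.integer(end - start + 1L))
}
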