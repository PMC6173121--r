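#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed airrkit error
#'
#' All errors raised by the package carry the class `airr_error` plus a
#' more specific subclass so callers (and the CLI) can branch on the
#' failure mode rather than on message text.
#' @noRd
abort_airr <- function(message, class, ...) {
  stop(structure(
    class = c(class, "airr_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Write a file atomically: build in a temp file in the same directory,
#' then rename into place, so readers never observe partial output.
#' @param path destination path
#' @param writer function(tmp_path) that produces the file content
#' @noRd
write_atomic <- function(path, writer) {
  dir <- dirname(path)
  tmp <- tempfile(pattern = paste0(".", basename(path), "."), tmpdir = dir)
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    # cross-device fallback
    ok <- file.copy(tmp, path, overwrite = TRUE)
    if (!ok) abort_airr(sprintf("cannot write '%s'", path), "airr_io_error")
  }
  invisible(path)
}

# vapply shorthands
vcharacter <- function(x, f, ...) vapply(x, f, character(1L), ...)
vinteger <- function(x, f, ...) vapply(x, f, integer(1L), ...)
vlogical <- function(x, f, ...) vapply(x, f, logical(1L), ...)
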