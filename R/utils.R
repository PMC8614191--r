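#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Package-level logging
#'
#' Stage functions report counts, skips and seeds through `ts_log()`, which
#' emits a `message()` unless logging has been silenced for the session.
#'
#' @param fmt `sprintf` format string.
#' @param ... Values interpolated into `fmt`.
#' @return Invisibly, the formatted string.
#' @export
ts_log <- function(fmt, ...) {
  txt <- sprintf(fmt, ...)
  if (isTRUE(getOption("thermosens.verbose", TRUE))) message("[thermosens] ", txt)
  invisible(txt)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

as_date <- function(x) {
  d <- as.Date(x)
  if (anyNA(d)) stopf("unparseable date(s): %s", paste(x[is.na(d)], collapse = ", "))
  d
}

# Derive a reproducible child seed from a base seed and a stream label.
# Keeps results independent across stages while driven by one user seed.
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) * 1009L + as.integer(h %% 100003L)) %% 2147483587L
}
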