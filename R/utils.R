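# Shared helpers: datetimes are POSIXct, timezone-naive local clock stored
# as UTC; all intervals are half-open [start, end).

#' @noRd
po_tz <- "UTC"

#' Parse an ISO 8601 datetime string into the package's canonical POSIXct.
#' @noRd
po_dt <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- po_tz
    return(x)
  }
  as.POSIXct(x, tz = po_tz)
}

#' Format a datetime for delimited-text export (second resolution).
#' @noRd
po_fmt_dt <- function(x) {
  out <- format(x, "%Y-%m-%d %H:%M:%S", tz = po_tz)
  out[is.na(x)] <- ""
  out
}

#' readr-based CSV reading with quiet column inference.
#' @noRd
po_read_csv <- function(path, col_types = NULL) {
  readr::read_csv(path, col_types = col_types, progress = FALSE,
                  show_col_types = FALSE, locale = readr::locale(tz = po_tz))
}

#' @noRd
po_write_csv <- function(x, path) {
  dtcols <- vapply(x, inherits, logical(1), what = "POSIXct")
  x[dtcols] <- lapply(x[dtcols], po_fmt_dt)
  readr::write_csv(x, path, na = "", progress = FALSE)
}

#' Stop with a classed condition carrying structured data.
#' @noRd
po_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "periomop_error"), ...)
}

#' Half-open interval membership: start <= x < end.
#' @noRd
po_within <- function(x, start, end) {
  x >= start & x < end
}
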