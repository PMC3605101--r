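#' Emit a pipeline log line
#'
#' All stages report input/output dimensions and active thresholds through
#' this helper. Messages go to standard error via [message()] so they never
#' contaminate tabular output on stdout. Silence with
#' `options(phenosam.verbose = FALSE)`.
#'
#' @param fmt [sprintf()] format string.
#' @param ... values interpolated into `fmt`.
#' @param level log level tag, `"INFO"` by default.
#' @return Invisibly, the formatted string.
#' @keywords internal
ps_log <- function(fmt, ..., level = "INFO") {
  txt <- sprintf("[%s] %s", level, sprintf(fmt, ...))
  if (isTRUE(getOption("phenosam.verbose", TRUE))) message(txt)
  invisible(txt)
}

ps_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
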