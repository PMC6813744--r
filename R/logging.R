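#' Structured pipeline logging
#'
#' Every stage of the pipeline reports dropped or coerced records through a
#' single structured logger: timestamped `level [code] message` lines written
#' to `stderr` and, when configured, appended to a log file. Verbosity is a
#' package option so the command-line wrapper can raise it per invocation.
#'
#' @param code short machine-readable reason code, e.g. `"DROP_GENE"`.
#' @param msg human-readable message.
#' @param level one of `"INFO"`, `"WARN"`, `"ERROR"`.
#' @return the formatted line, invisibly.
#' @keywords internal
stx_log <- function(code, msg, level = "INFO") {
  line <- sprintf("%s %s [%s] %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), level, code, msg)
  if (isTRUE(getOption("steatox.verbose", TRUE))) {
    message(line)
  }
  logfile <- getOption("steatox.logfile", NULL)
  if (!is.null(logfile)) {
    cat(line, "\n", file = logfile, append = TRUE, sep = "")
  }
  invisible(line)
}

#' Toggle pipeline logging verbosity
#'
#' @param verbose logical; emit log lines to stderr?
#' @param logfile optional path; when set, log lines are appended there too.
#' @return previous option values, invisibly.
#' @export
stx_set_logging <- function(verbose = TRUE, logfile = NULL) {
  old <- options(steatox.verbose = verbose, steatox.logfile = logfile)
  invisible(old)
}
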