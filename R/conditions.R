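# Condition system: every user-facing failure is classed so that callers
# (and the CLI exit-code mapping) can distinguish bad input (validation),
# unreadable/unwritable artifacts (io) and broken computational invariants.

qpia_condition <- function(message, class, call = sys.call(-1)) {
  structure(
    class = c(class, "qpia_error", "error", "condition"),
    list(message = message, call = call)
  )
}

stop_validation <- function(...) {
  stop(qpia_condition(paste0(...), "qpia_validation_error", call = sys.call(-1)))
}

stop_io <- function(...) {
  stop(qpia_condition(paste0(...), "qpia_io_error", call = sys.call(-1)))
}

stop_invariant <- function(...) {
  stop(qpia_condition(paste0(...), "qpia_invariant_error", call = sys.call(-1)))
}

#' Map a caught qpia condition to a process exit status
#'
#' Exit codes follow the pipeline convention: 0 success, 2 validation
#' failure, 3 I/O failure, 4 computational invariant breach.
#'
#' @param cond a condition object.
#' @return integer exit status.
#' @keywords internal
exit_status_for <- function(cond) {
  if (inherits(cond, "qpia_validation_error")) return(2L)
  if (inherits(cond, "qpia_io_error")) return(3L)
  if (inherits(cond, "qpia_invariant_error")) return(4L)
  1L
}
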