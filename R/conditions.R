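# Classed conditions used across the package. Every error raised by rtshift
# inherits from "rtshift_error"; the subclasses below are part of the API
# contract (the CLI maps them onto exit codes).

rt_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "rtshift_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

# frame/sign confusion is the error class this package exists to eliminate,
# so mixing coordinate frames is always a hard, distinct error
abort_frame <- function(message) rt_abort(message, "rtshift_frame_error")

abort_parse <- function(message) rt_abort(message, "rtshift_parse_error")

abort_value <- function(message) rt_abort(message, "rtshift_value_error")

# marker missing/ambiguous: the origin check cannot run. Deliberately
# distinct from a FLAG verdict -- a safety check must fail loudly.
abort_not_evaluable <- function(message) {
  rt_abort(message, c("rtshift_not_evaluable", "rtshift_marker_error"))
}

abort_ambiguous <- function(message) {
  rt_abort(message, c("rtshift_ambiguous_marker", "rtshift_marker_error"))
}
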