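# Structured condition classes. Every error raised by the package carries
# both a specific class (e.g. "locked_error") and the umbrella class
# "trajspace_error", so callers can catch narrowly or broadly.

ts_condition <- function(class, message, ...) {
  structure(
    class = c(class, "trajspace_error", "error", "condition"),
    list(message = message, ...)
  )
}

ts_abort <- function(class, message, ...) {
  stop(ts_condition(class, message, ...))
}

#' @title Error classes used by trajspace
#' @description All errors signalled by the package are classed conditions
#' inheriting from `trajspace_error`. The specific classes are:
#' `locked_error`, `unsupported_type_error`, `heterogeneous_range_error`,
#' `empty_range_error`, `index_error`, `duplicate_tag_error`,
#' `unknown_tag_error`, `run_phase_error`, `name_collision_error`,
#' `not_found_error`, `ambiguous_name_error`, `link_depth_error`,
#' `length_mismatch_error`, `exploration_mismatch_error`,
#' `space_mismatch_error`, `no_exploration_error`, `serialization_error`,
#' `unexplored_parameter_error`, `unsupported_operation_error`,
#' `run_failed_error` and `io_error`.
#' @name trajspace-errors
NULL
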