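# Classed conditions so callers (and the CLI) can distinguish user error from
# data problems. All inherit from "rnm_error".

rnm_abort <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "rnm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

format_error     <- function(msg, ...) rnm_abort("rnm_format_error", msg, ...)
validation_error <- function(msg, ...) rnm_abort("rnm_validation_error", msg, ...)
conflict_error   <- function(msg, ...) rnm_abort("rnm_conflict_error", msg, ...)
lookup_error     <- function(msg, ...) rnm_abort("rnm_lookup_error", msg, ...)
config_error     <- function(msg, ...) rnm_abort("rnm_config_error", msg, ...)
usage_error      <- function(msg, ...) rnm_abort("rnm_usage_error", msg, ...)
numerical_error  <- function(msg, ...) rnm_abort("rnm_numerical_error", msg, ...)
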