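# Condition classes used across the package. Every error raised here inherits
# from "rr_error" so callers can distinguish package failures from R errors.

rr_abort <- function(class, msg, data = NULL) {
  cond <- structure(
    class = c(class, "rr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), data = data)
  )
  stop(cond)
}

rr_parse_error      <- function(msg, data = NULL) rr_abort("rr_parse_error", msg, data)
rr_mapping_error    <- function(msg, data = NULL) rr_abort("rr_mapping_error", msg, data)
rr_format_error     <- function(msg, data = NULL) rr_abort("rr_format_error", msg, data)
rr_usage_error      <- function(msg, data = NULL) rr_abort("rr_usage_error", msg, data)
rr_schema_error     <- function(msg, data = NULL) rr_abort("rr_schema_error", msg, data)
rr_generation_error <- function(msg, data = NULL) rr_abort("rr_generation_error", msg, data)

# Skip signal raised by perturbation operators when a decoy cannot be built on
# the given record (e.g. no alternative disconnection site); the generator
# catches it and picks another operator.
rr_skip <- function(msg = "operator not applicable") {
  cond <- structure(
    class = c("rr_skip_signal", "rr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}
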