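# Classed conditions so callers (pipeline, CLI) can react programmatically.

gd_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "gaitdmo_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

gd_warn <- function(class, msg) {
  warning(structure(
    class = c(class, "gaitdmo_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_format <- function(msg, ...) gd_stop("gaitdmo_format_error", msg, ...)
stop_data <- function(msg, ...) gd_stop("gaitdmo_data_error", msg, ...)
stop_bounds <- function(msg) gd_stop("gaitdmo_bounds_error", msg)
stop_insufficient <- function(msg) gd_stop("gaitdmo_insufficient_events", msg)
stop_protocol <- function(msg) gd_stop("gaitdmo_protocol_error", msg)
stop_pairing <- function(msg) gd_stop("gaitdmo_pairing_error", msg)
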