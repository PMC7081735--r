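# Classed conditions so callers (and the CLI) can react to error categories.

stop_octseg <- function(msg, class) {
  stop(structure(
    class = c(class, "octseg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_format <- function(msg) stop_octseg(msg, "octseg_format_error")
stop_config <- function(msg) stop_octseg(msg, "octseg_config_error")
stop_param  <- function(msg) stop_octseg(msg, "octseg_param_error")
stop_io     <- function(msg) stop_octseg(msg, "octseg_io_error")
stop_spec   <- function(msg) stop_octseg(msg, "octseg_spec_error")
stop_analysis <- function(msg) stop_octseg(msg, "octseg_analysis_error")
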