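# Condition constructors used across the package. Each error carries a
# dedicated class so callers (notably the CLI) can map failures to distinct
# exit codes without string matching.

stop_io <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("msadiff_io_error", "msadiff_error"),
                      call = call))
}

stop_format <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("msadiff_format_error", "msadiff_error"),
                      call = call))
}

stop_validation <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg,
                      class = c("msadiff_validation_error", "msadiff_error"),
                      call = call))
}

stop_usage <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("msadiff_usage_error", "msadiff_error"),
                      call = call))
}
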