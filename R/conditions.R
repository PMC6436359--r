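# Structured conditions so callers (and the CLI exit-code mapping) can tell
# validation problems from I/O problems.

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("scaspd_validation_error", "scaspd_error")))
}

stop_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("scaspd_io_error", "scaspd_error")))
}
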