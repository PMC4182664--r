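# Classed conditions used throughout the package.  All inherit from
# "saberlever_error" so callers (and the CLI) can map them to exit codes.

stop_domain <- function(msg, class = character()) {
  stop(errorCondition(msg, class = c(class, "saberlever_domain_error",
                                     "saberlever_error", "error")))
}

stop_lookup <- function(msg) {
  stop_domain(msg, class = "saberlever_lookup_error")
}

stop_validation <- function(msg) {
  stop_domain(msg, class = "saberlever_validation_error")
}

stop_usage <- function(msg) {
  stop(errorCondition(msg, class = c("saberlever_usage_error",
                                     "saberlever_error", "error")))
}
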