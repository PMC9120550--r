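# Classed error conditions so callers can distinguish failure modes
# programmatically (testthat matches on the class).

zap_abort <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "zap_error"),
                      call = sys.call(-1)))
}
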