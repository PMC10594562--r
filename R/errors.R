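# Classed errors so callers/tests can discriminate failure modes.
ts_error <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("thermoshift_", class), "thermoshift_error", "error", "condition"),
    list(message = message, call = call)
  ))
}
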