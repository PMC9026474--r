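# Condition helpers: input/validation problems are signalled with a dedicated
# class so the CLI can map them to exit status 2 (internal errors exit 1).

pm_input_error <- function(...) {
  msg <- paste0(...)
  stop(structure(
    class = c("peakmap_input_error", "error", "condition"),
    list(message = msg, call = sys.call(-1L))
  ))
}

is_input_error <- function(e) inherits(e, "peakmap_input_error")
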