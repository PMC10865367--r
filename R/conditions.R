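# Classed conditions so callers (and the CLI) can react to specific failures
# without string matching.

sf_abort <- function(message, class) {
  stop(structure(
    class = c(class, "segfuse_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

sf_warn <- function(message, class = "segfuse_warning") {
  warning(structure(
    class = c(class, "segfuse_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}
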