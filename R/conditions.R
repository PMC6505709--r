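# Condition classes used throughout the package so callers (notably the CLI)
# can map failures to stable exit codes: validation problems vs. I/O problems.

abort_validation <- function(..., call. = FALSE) {
  stop(structure(
    class = c("adascreen_validation_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

abort_io <- function(..., call. = FALSE) {
  stop(structure(
    class = c("adascreen_io_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}
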