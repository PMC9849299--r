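## Classed conditions so callers (and the CLI) can distinguish configuration
## mistakes, malformed input files and data-integrity violations.

stopConfig <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("qtap_config_error", "qtap_error")))
}

stopFormat <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("qtap_format_error", "qtap_error")))
}

stopData <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("qtap_data_error", "qtap_error")))
}

warnQtap <- function(...) {
  warning(warningCondition(paste0(...), class = "qtap_warning"))
}
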