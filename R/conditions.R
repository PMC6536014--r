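# Classed conditions so callers (and the CLI) can map failures to exit codes.
ppis_stop <- function(message, class) {
  stop(errorCondition(message, class = c(class, "ppiscreen_error", "error")))
}

ppis_parse_error <- function(message) ppis_stop(message, "ppiscreen_parse_error")
ppis_config_error <- function(message) ppis_stop(message, "ppiscreen_config_error")
ppis_io_error <- function(message) ppis_stop(message, "ppiscreen_io_error")
ppis_degenerate_error <- function(message) ppis_stop(message, "ppiscreen_degenerate_error")
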