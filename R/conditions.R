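# Structured error conditions. The CLI maps these onto exit codes:
# usage -> 2, data/parse -> 3, out-of-range -> 4.

stop_usage <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("fluoarea_usage_error", "fluoarea_error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("fluoarea_data_error", "fluoarea_error")))
}

stop_range <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("fluoarea_range_error", "fluoarea_error")))
}

# round-half-up, used wherever integer gray levels are produced (base round()
# is round-half-even, which would bias conversions at .5 boundaries)
round_half_up <- function(x) floor(x + 0.5)

cli_log <- function(msg, ...) {
  message(sprintf("[fluoarea] %s", sprintf(msg, ...)))
}
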