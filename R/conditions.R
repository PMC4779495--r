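## Classed conditions so callers (and the CLI) can map failures to exit codes:
## usage -> 2, data/parse -> 3, numerical/physical domain -> 4.

stop_usage <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("nirsim_usage_error", "nirsim_error", "error", "condition")))
}

stop_data <- function(fmt, ..., class = character()) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "nirsim_data_error", "nirsim_error", "error", "condition")))
}

stop_domain <- function(fmt, ..., class = character()) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "nirsim_domain_error", "nirsim_error", "error", "condition")))
}

## Grid mismatch is a data error with its own class so tests can target it.
stop_grid <- function(fmt, ...) {
  stop_data(fmt, ..., class = "nirsim_grid_error")
}

stop_fit <- function(fmt, ...) {
  stop_domain(fmt, ..., class = "nirsim_fit_error")
}

stop_degenerate <- function(fmt, ...) {
  stop_domain(fmt, ..., class = "nirsim_degeneracy_error")
}
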