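#' @keywords internal
"_PACKAGE"

# Single-line structured logging used across the pipeline. Messages go
# through message() so callers can suppressMessages() them.
gs_log <- function(stage, ...) {
  message(sprintf("[gutscaling:%s] %s", stage, sprintf(...)))
}

# Equal-tailed credible interval from a vector of draws.
ci_quantile <- function(x, level) {
  a <- (1 - level) / 2
  stats::quantile(x, c(a, 1 - a), names = FALSE, type = 7)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
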