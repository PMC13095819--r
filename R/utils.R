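#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Round half away from zero to `digits` decimals ("half-up" in the table sense:
# 0.125 -> 0.13, -0.125 -> -0.13). base::round() rounds half to even.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# All stochastic operations funnel through this so a single integer seed
# reproduces any output without touching the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop2(msg)
  invisible(TRUE)
}
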