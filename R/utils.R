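#' @keywords internal
"_PACKAGE"

## Trapezoidal integral with absolute spacing, so the value is independent of
## axis direction.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) stop("trapezoidal integration needs at least 2 points")
  sum(abs(diff(x)) * (y[-n] + y[-1L]) / 2)
}

is_uniform_axis <- function(x, rel_tol = 1e-6) {
  d <- diff(x)
  span <- abs(mean(d))
  span > 0 && max(abs(d - mean(d))) <= rel_tol * span
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic per-sample / per-replicate seed derivation. Keeps every seed
## inside the 32-bit integer range and leaves earlier samples untouched when
## class sizes grow.
derive_seed <- function(base_seed, ...) {
  ids <- c(...)
  m <- 2147483647; a <- 48271   # Lehmer/Park-Miller modulus and multiplier
  h <- as.double(base_seed) %% m
  for (id in ids) h <- (h * a + as.double(id) + 1) %% m
  h <- (h * a) %% m
  as.integer(h)
}
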