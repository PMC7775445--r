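# Internal helpers: seeded evaluation, seed fan-out, trapezoid integration,
# 1/f noise synthesis.

# Derive a per-stage / per-unit child seed from a base seed.  Documented
# scheme (also in the manifest): child = (base + 7919 * stage + unit) mod
# (2^31 - 1), kept strictly positive.  7919 is just a prime large enough to
# keep stage streams apart for any realistic unit count.
child_seed <- function(base, stage, unit = 0L) {
  as.integer((as.numeric(base) + 7919 * as.numeric(stage) + as.numeric(unit)) %%
               (2^31 - 1)) + 1L
}

with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Trapezoid integral of y over x (both numeric vectors, x increasing).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Cumulative trapezoid integral, same length as x, starting at 0.
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) * diff(x) / 2))
}

# 1/f ("pink") noise, unit standard deviation, length n.  Shaped in the
# frequency domain: amplitude ~ f^(-exponent/2) so power ~ 1/f^exponent.
pink_noise <- function(n, exponent = 1) {
  if (n < 2L) return(stats::rnorm(n))
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))            # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)              # fold to two-sided frequency index
  scale <- f^(-exponent / 2)
  scale[1] <- 0                        # remove DC
  x <- Re(stats::fft(spec * scale, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s
}

# Matrix of independent pink-noise columns (n x m), unit SD per column.
pink_noise_matrix <- function(n, m, exponent = 1) {
  if (m == 0L) return(matrix(0, n, 0))
  white <- matrix(stats::rnorm(n * m), n, m)
  if (n < 2L) return(white)
  spec <- stats::mvfft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)
  scale <- f^(-exponent / 2)
  scale[1] <- 0
  x <- Re(stats::mvfft(spec * scale, inverse = TRUE)) / n
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1
  sweep(x, 2, sds, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
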