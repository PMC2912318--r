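# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministically mix integers into a single RNG seed
#'
#' Linear-congruential mixing of an arbitrary tuple of integers into one
#' 31-bit seed. Used to derive independent, reproducible sub-streams
#' (per slice, per condition) from a single base seed.
#'
#' @param ... integers (or values coercible to numeric) to mix.
#' @return a single integer in \[0, 2^31 - 1).
#' @keywords internal
#' @export
mix_seed <- function(...) {
  parts <- as.numeric(c(...))
  if (length(parts) == 0L || anyNA(parts)) {
    stop("mix_seed() needs at least one non-missing value", call. = FALSE)
  }
  s <- 0
  m <- 2147483647  # 2^31 - 1; 69069 * m stays exactly representable in doubles
  for (p in parts) {
    s <- (s * 69069 + (abs(p) %% m) + 1) %% m
  }
  as.integer(s)
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
# Every stochastic operation in the package funnels through this: nothing
# touches the global RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("an explicit integer seed is required (no silent global randomness)",
         call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# 1/f-shaped ("pink") Gaussian noise, unit SD, generated by spectral shaping
# of white noise. Consumes the ambient RNG stream (call inside with_seed()).
pink_noise <- function(n) {
  stopifnot(n >= 2L)
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  # frequency index of each FFT bin (0, 1, ..., n/2, ..., 1)
  k <- c(0L, seq_len(n - 1L))
  k <- pmin(k, n - k)
  scale <- c(0, 1 / sqrt(k[-1L]))  # kill DC, 1/sqrt(f) amplitude elsewhere
  x <- Re(stats::fft(W * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Population (n-denominator) standard deviation.
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

fmt_num <- function(x) format(x, digits = 6)
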