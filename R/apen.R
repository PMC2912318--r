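# Approximate entropy (ApEn), the classical Pincus regularity statistic.
#
# ApEn(m, r, N) = Phi^m(r) - Phi^{m+1}(r), where Phi^m is the average log
# fraction of template pairs (length-m delay vectors) whose Chebyshev
# distance is <= r. Conventions fixed here and shared by routine and oracle:
#   * self-matches included (C > 0 always, finite logs; ApEn >= 0 at
#     practical N, though marginally negative values can occur for very
#     short fully-irregular signals because Phi^m and Phi^(m+1) average
#     over different template counts);
#   * match predicate is <= r;
#   * Phi at embedding length L averages over all N - L + 1 templates
#     (so Phi^{m+1} uses N - m vectors);
#   * r defaults to r_coeff x population SD of the analyzed signal itself.

#' ApEn parameters
#'
#' @param m embedding dimension (template length), >= 1.
#' @param r absolute tolerance in signal units, or `NULL` to derive it as
#'   `r_coeff * SD(x)` at computation time.
#' @param r_coeff tolerance coefficient applied to the signal SD when `r`
#'   is not given.
#' @return an object of class `apen_params`.
#' @export
apen_params <- function(m = 2L, r = NULL, r_coeff = 0.1) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (!is.null(r) && r < 0) stop("r must be >= 0", call. = FALSE)
  if (r_coeff < 0) stop("r_coeff must be >= 0", call. = FALSE)
  structure(list(m = as.integer(m), r = r, r_coeff = as.numeric(r_coeff)),
            class = "apen_params")
}

#' Chebyshev (maximum) distance between two template vectors
#'
#' @param u,v numeric vectors of equal length.
#' @return `max(|u - v|)`.
#' @export
chebyshev_distance <- function(u, v) {
  if (length(u) != length(v) || length(u) < 1L) {
    stop("u and v must have equal length >= 1", call. = FALSE)
  }
  max(abs(u - v))
}

#' Correlation count C^m_r(i)
#'
#' Fraction of the N - m + 1 template vectors within Chebyshev distance r of
#' template i (1-based), self-match included, so the result lies in (0, 1].
#'
#' @param x numeric signal.
#' @param i template index, 1-based.
#' @param m embedding dimension.
#' @param r tolerance (absolute).
#' @return a fraction in (0, 1].
#' @export
correlation_count <- function(x, i, m, r) {
  n <- length(x)
  n_templates <- n - m + 1L
  if (n_templates < 1L) stop("signal shorter than one template", call. = FALSE)
  if (i < 1L || i > n_templates) {
    stop(sprintf("template index %d out of range 1..%d", i, n_templates),
         call. = FALSE)
  }
  dmax <- rep(0, n_templates)
  for (k in 0L:(m - 1L)) {
    dmax <- pmax(dmax, abs(x[i + k] - x[(1L + k):(n_templates + k)]))
  }
  sum(dmax <= r) / n_templates
}

#' Phi^m(r): mean log correlation count
#'
#' Average of `ln C^m_r(i)` over all `N - m + 1` templates. Finite for any
#' r >= 0 because self-matches force every count above zero.
#'
#' @param x numeric signal of length N > m.
#' @param m embedding dimension.
#' @param r tolerance (absolute).
#' @return a nonpositive real.
#' @export
phi <- function(x, m, r) {
  n <- length(x)
  if (n <= m) stop("need N > m samples", call. = FALSE)
  nt <- n - m + 1L
  # Chebyshev distance matrix between all template pairs, built by running
  # max over the lagged absolute-difference matrices.
  A <- abs(outer(x, x, "-"))
  D <- A[1:nt, 1:nt, drop = FALSE]
  if (m > 1L) {
    for (k in 1L:(m - 1L)) {
      D <- pmax(D, A[(1L + k):(nt + k), (1L + k):(nt + k), drop = FALSE])
    }
  }
  C <- rowMeans(D <= r)
  mean(log(C))
}

#' Tolerance from the signal's standard deviation
#'
#' `r = r_coeff * SD(x)` with the population (n-denominator) SD, computed on
#' the signal actually analyzed. Returns 0 with a warning for a constant
#' signal, which feeds the degenerate path of [approximate_entropy()].
#'
#' @param x numeric signal, length >= 2.
#' @param r_coeff tolerance coefficient.
#' @return tolerance in signal units.
#' @export
tolerance_from_sd <- function(x, r_coeff = 0.1) {
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  s <- pop_sd(x)
  if (s == 0) {
    warning("constant signal: SD-derived tolerance is 0 (degenerate)",
            call. = FALSE)
  }
  r_coeff * s
}

#' Approximate entropy of a signal
#'
#' Computes `ApEn(m, r, N) = Phi^m(r) - Phi^{m+1}(r)` with self-matches
#' included. If `params$r` is `NULL` the tolerance is derived from the
#' signal's own SD via [tolerance_from_sd()]. A zero tolerance on a
#' non-constant signal yields a result flagged `degenerate` (it then counts
#' only exact template repeats) plus a warning.
#'
#' @param x numeric signal (or an `lfp_segment`), length >= m + 2.
#' @param params an [apen_params()].
#' @return an object of class `apen_result`: fields `apen`, `phi_m`,
#'   `phi_m1`, `n`, `r_used`, `params`, `degenerate`.
#' @export
approximate_entropy <- function(x, params = apen_params()) {
  if (inherits(x, "lfp_segment")) x <- x$samples
  x <- as.numeric(x)
  m <- params$m
  n <- length(x)
  if (n < m + 2L) {
    stop(sprintf("need at least m + 2 = %d samples, got %d", m + 2L, n),
         call. = FALSE)
  }
  r <- params$r %||% tolerance_from_sd(x, params$r_coeff)
  degenerate <- FALSE
  if (r == 0 && pop_sd(x) > 0) {
    degenerate <- TRUE
    warning("r = 0 on a non-constant signal: ApEn counts exact repeats only",
            call. = FALSE)
  }
  phi_m <- phi(x, m, r)
  phi_m1 <- phi(x, m + 1L, r)
  structure(
    list(apen = phi_m - phi_m1, phi_m = phi_m, phi_m1 = phi_m1,
         n = n, r_used = r, params = params, degenerate = degenerate),
    class = "apen_result"
  )
}

#' @export
print.apen_result <- function(x, ...) {
  cat(sprintf("ApEn(m = %d, r = %s, N = %d) = %.4f%s\n",
              x$params$m, fmt_num(x$r_used), x$n, x$apen,
              if (x$degenerate) "  [degenerate]" else ""))
  cat(sprintf("  Phi^m = %.6f, Phi^(m+1) = %.6f\n", x$phi_m, x$phi_m1))
  invisible(x)
}

#' Brute-force ApEn oracle
#'
#' Literal O(N^2) double-loop transcription of the defining equations, kept
#' free of vectorization so it can serve as ground truth for the main
#' routine. Same conventions (self-match, <= r, N - L + 1 templates at
#' embedding length L). Intended for N <= 2000.
#'
#' @param x numeric signal.
#' @param params an [apen_params()].
#' @return the ApEn value (bare numeric).
#' @export
approximate_entropy_oracle <- function(x, params = apen_params()) {
  if (inherits(x, "lfp_segment")) x <- x$samples
  x <- as.numeric(x)
  m <- params$m
  n <- length(x)
  if (n < m + 2L) stop("need at least m + 2 samples", call. = FALSE)
  r <- params$r %||% tolerance_from_sd(x, params$r_coeff)
  phi_loop <- function(mm) {
    nt <- n - mm + 1L
    logs <- numeric(nt)
    for (i in seq_len(nt)) {
      count <- 0L
      for (j in seq_len(nt)) {
        dmax <- 0
        for (k in 0L:(mm - 1L)) {
          dk <- abs(x[i + k] - x[j + k])
          if (dk > dmax) dmax <- dk
        }
        if (dmax <= r) count <- count + 1L
      }
      logs[i] <- log(count / nt)
    }
    mean(logs)
  }
  phi_loop(m) - phi_loop(m + 1L)
}
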