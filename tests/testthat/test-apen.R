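test_that("chebyshev_distance is the componentwise max difference", {
  expect_equal(chebyshev_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(chebyshev_distance(c(1, 5), c(2, 3)), 2)
  expect_equal(chebyshev_distance(0, -3), 3)
  expect_error(chebyshev_distance(1:2, 1:3), "equal length")
})

test_that("correlation_count matches exhaustive enumeration", {
  # x = [0,10,0,10,0], m = 2, r = 1: templates (0,10),(10,0),(0,10),(10,0);
  # template 1 matches itself and template 3 -> 2/4
  x <- c(0, 10, 0, 10, 0)
  expect_equal(correlation_count(x, 1, 2, 1), 0.5)
  # constant signal: everything matches
  expect_equal(correlation_count(rep(7, 20), 5, 2, 0), 1.0)
  # r below the smallest gap on a distinct-valued signal: self-match only
  y <- c(1, 3, 9, 27, 81)
  expect_equal(correlation_count(y, 2, 2, 0.5), 1 / 4)
  expect_error(correlation_count(x, 5, 2, 1), "out of range")
})

test_that("phi matches direct counting on analytic signals", {
  # constant signal: every C = 1, so phi = 0 at any m, r
  expect_equal(phi(rep(2, 100), 2, 0.1), 0)
  # alternating 1,2 of length 50 at m = 3: 48 templates, 24 copies each of
  # (1,2,1) and (2,1,2), each matching exactly half
  alt <- rep(c(1, 2), 25)
  expect_equal(phi(alt, 3, 0.2), log(0.5))
  expect_error(phi(1:3, 3, 0.1), "N > m")
})

test_that("approximate_entropy handles analytic and degenerate cases", {
  # constant signal with SD-derived r: warns (r = 0) but ApEn is exactly 0
  expect_warning(res_const <- approximate_entropy(rep(5, 100), apen_params(m = 2)),
                 "constant")
  expect_equal(res_const$apen, 0)

  alt <- rep(c(1, 2), 25)
  res <- approximate_entropy(alt, apen_params(m = 2, r = 0.2))
  expect_lt(res$apen, 0.01)
  expect_gte(res$apen, 0)
  expect_equal(res$apen, res$phi_m - res$phi_m1)

  expect_error(approximate_entropy(1:3, apen_params(m = 2)), "at least")

  # r = 0 on a non-constant signal: degenerate flag + warning, not an error
  expect_warning(
    res0 <- approximate_entropy(c(1, 2, 1, 2, 1, 2, 3), apen_params(m = 1, r = 0)),
    "r = 0")
  expect_true(res0$degenerate)
})

test_that("tolerance_from_sd scales with the signal", {
  x <- c(-2, 0, 2, 0, -2, 0, 2, 0)  # population SD = sqrt(2)
  expect_equal(tolerance_from_sd(x, 0.1), 0.1 * sqrt(2))
  expect_equal(tolerance_from_sd(5 * x, 0.1), 5 * tolerance_from_sd(x, 0.1))
  expect_warning(r0 <- tolerance_from_sd(rep(1, 10), 0.1), "constant")
  expect_equal(r0, 0)
})

test_that("main routine equals the brute-force oracle over a seeded sweep", {
  set.seed(101)
  for (n in c(50, 120)) {
    for (m in 1:3) {
      x <- rnorm(n)
      for (rc in c(0.1, 0.2, 0.5)) {
        p <- apen_params(m = m, r = rc * sd(x) * sqrt((n - 1) / n))
        expect_equal(approximate_entropy(x, p)$apen,
                     approximate_entropy_oracle(x, p),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("ApEn is deterministic, and nonnegative at analysis length", {
  # Nonnegativity is guaranteed in practice but not in the extreme short-N
  # limit: Phi^m averages over N-m+1 templates while Phi^(m+1) averages over
  # N-m, and for fully irregular signals of a few dozen samples the
  # mismatched denominators can push the difference slightly below zero
  # (e.g. -0.027 at N = 39; confirmed identically by the brute-force oracle
  # and an independent implementation). At the pipeline's segment length
  # (N = 200) it holds with wide margin.
  set.seed(77)
  for (i in 1:20) {
    x <- rnorm(200)
    res <- approximate_entropy(x, apen_params())
    expect_gte(res$apen, 0)
    expect_identical(res$apen, approximate_entropy(x, apen_params())$apen)
  }
  # the short-N counterexample stays put and stays oracle-consistent
  set.seed(77)
  invisible(rnorm(sample(30:200, 1)))
  x_short <- rnorm(sample(30:200, 1))
  res <- approximate_entropy(x_short, apen_params())
  expect_lt(res$apen, 0)
  expect_equal(res$apen, approximate_entropy_oracle(x_short, apen_params()),
               tolerance = 1e-12)
})

test_that("offset invariance (absolute r) and scale invariance (SD r)", {
  set.seed(55)
  x <- rnorm(150)
  p_abs <- apen_params(m = 2, r = 0.25)
  expect_equal(approximate_entropy(x + 100, p_abs)$apen,
               approximate_entropy(x, p_abs)$apen, tolerance = 1e-9)
  p_rel <- apen_params(m = 2, r_coeff = 0.1)
  expect_equal(approximate_entropy(7 * x, p_rel)$apen,
               approximate_entropy(x, p_rel)$apen, tolerance = 1e-9)
})

test_that("ApEn rises with noise on the resolvable flank, then saturates", {
  # At N = 200, r = 0.1 x SD, ApEn is an increasing function of irregularity
  # only up to a finite-sample ceiling (~0.5-0.7): beyond it, template
  # matches other than self-matches vanish and the statistic declines. Both
  # halves of that shape are asserted here.
  mean_apen <- function(s) {
    mean(sapply(1:20, function(i) {
      set.seed(9000 + i)  # common noise seeds across sigma levels
      x <- make_sine(60, 2000, 200) + s * rnorm(200)
      approximate_entropy(x, apen_params(m = 2, r_coeff = 0.1))$apen
    }))
  }
  m <- vapply(c(0, 0.02, 0.05, 0.1), mean_apen, numeric(1))
  expect_true(all(diff(m) > 0))            # rising flank
  expect_lt(mean_apen(1.0), mean_apen(0.1))  # saturation / decline
})

test_that("cross-check: matches a third-party ApEn implementation", {
  # Expected values computed once with antropy 0.2.1 (app_entropy, order 2,
  # Chebyshev metric, tolerance 0.2 x population SD) on these exact seeded
  # signals; antropy is not a dependency and is not present at test time.
  ref <- c(0.741035221712596, 0.816398904242223, 0.764988038051603,
           0.700624324285493, 0.841714954585899, 0.787716280873509,
           0.784071847218603, 0.759022771950737, 0.650820719371924,
           0.697943237615924, 0.823674887180684, 0.638361934972127,
           0.687727008146586, 0.847279236521884, 0.773688597040077,
           0.739864665768197, 0.698278373044372, 0.712575573361754,
           0.791246675954646, 0.738203492692213)
  set.seed(424242)
  sigs <- lapply(1:20, function(i) {
    rnorm(150) + make_sine(60, 2000, 150) * (i %% 3)
  })
  mine <- vapply(sigs, function(x) {
    r <- 0.2 * sqrt(mean((x - mean(x))^2))
    approximate_entropy(x, apen_params(m = 2, r = r))$apen
  }, numeric(1))
  expect_equal(mine, ref, tolerance = 1e-9)
})
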