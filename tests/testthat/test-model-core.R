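test_that("phase-type validation accepts proper specs and names the broken invariant", {
  expect_s3_class(phase_type(1, 0.05), "phase_type")
  # phase 1 exits only by moving on: still valid (total exit rate > 0)
  expect_s3_class(tmpl_erlang(1), "phase_type")

  expect_error(phase_type(c(1, 0), c(0, 1)), "zero total exit rate")
  expect_error(phase_type(c(0.5, 0.6), c(1, 1)), "sum to 1")
  expect_error(phase_type(1, -0.1), "non-negative")
  expect_error(phase_type(c(0.5, 0.5), c(1, 1),
                          matrix(c(0, 0, 1, 0), 2, byrow = TRUE)),
               "upper triangular")
  expect_error(phase_type(c(0.5, 0.5), c(1, 1),
                          matrix(c(0, -1, 0, 0), 2, byrow = TRUE)),
               "non-negative")
})

test_that("a model family without PA pins tau at zero", {
  expect_error(pa_model(phase_type(1, 1), tau = 0.1, pa = FALSE),
               "tau = 0 exactly")
  expect_error(pa_model(phase_type(1, 1), tau = -0.1), "non-negative")
  expect_true(pa_model(phase_type(1, 1), tau = 0.1)$pa)
})

test_that("PGF matches hand values and boundary cases", {
  # normalisation at s = 1 and degenerate t = 0, across the tau range
  for (tau in c(0, 0.02, 1)) {
    expect_equal(pgf_conditional(tau, 3.7, 1), 1)
    expect_equal(pgf_conditional(tau, 0, c(0, 0.3, 1)), c(1, 1, 1))
  }
  # hand evaluation at tau = 1, t = log 2, s = 1/2
  expect_equal(pgf_conditional(1, log(2), 0.5), 2 / 3, tolerance = 1e-12)
  # the tau -> 0 limit joins the Poisson PGF continuously
  expect_equal(pgf_conditional(1e-12, 2, 0.4), exp(2 * (0.4 - 1)),
               tolerance = 1e-9)
})

test_that("conditional pmf reduces to Poisson and geometric special cases", {
  expect_equal(pmf_conditional(0, 2.5, 0:40), dpois(0:40, 2.5))
  t <- 1.3
  expect_equal(pmf_conditional(1, t, 0:40),
               exp(-t) * (1 - exp(-t))^(0:40), tolerance = 1e-12)
})

test_that("conditional pmf equals the Taylor coefficients of the PGF", {
  for (tau in c(0, 0.02, 0.5, 1)) {
    for (t in c(0.5, 5)) {
      expect_equal(pmf_conditional(tau, t, 0:30),
                   taylor_coefs_fft(tau, t, 30),
                   tolerance = 1e-8)
    }
  }
})

test_that("conditional pmf is normalised after adaptive truncation", {
  for (tau in c(0, 0.02, 0.5, 1, 2)) {
    for (t in c(0.5, 5, 50)) {
      if (tau == 0) {
        K <- qpois(1e-12, t, lower.tail = FALSE)
        expect_equal(sum(pmf_conditional(tau, t, 0:K)), 1,
                     tolerance = 1e-10)
      } else if (tau * t < 12) {
        K <- qnbinom(1e-12, 1 / tau, exp(-tau * t), lower.tail = FALSE)
        expect_equal(sum(pmf_conditional(tau, t, 0:K)), 1,
                     tolerance = 1e-10)
      } else {
        # the 1 - 1e-12 quantile is astronomically large here; check the
        # partial sum against the negative-binomial CDF instead
        K <- 200000L
        expect_equal(sum(pmf_conditional(tau, t, 0:K)),
                     pnbinom(K, 1 / tau, exp(-tau * t)),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("conditional moments match closed forms and truncated sums", {
  for (tau in c(0.02, 0.5)) {
    for (t in c(0.5, 5)) {
      m1 <- if (tau == 0) t else expm1(tau * t) / tau
      expect_equal(moment_conditional(tau, t, 1), m1, tolerance = 1e-12)
      expect_equal(moment_conditional(tau, t, 2),
                   m1 + (tau + 1) * m1^2, tolerance = 1e-12)
      # r >= 3 against the truncated-sum oracle
      K <- qnbinom(1e-13, 1 / tau, exp(-tau * t), lower.tail = FALSE) + 50
      k <- 0:K
      for (r in 3:4)
        expect_equal(moment_conditional(tau, t, r),
                     sum(k^r * pmf_conditional(tau, t, k)),
                     tolerance = 1e-6)
    }
  }
  # Poisson limit
  expect_equal(moment_conditional(0, 3.2, 1), 3.2)
  expect_equal(moment_conditional(1e-12, 3.2, 1), 3.2, tolerance = 1e-9)
})

test_that("holding-time density matches exponential and Erlang forms and integrates to 1", {
  t <- c(0.1, 0.7, 3, 10)
  expect_equal(holding_time_pdf(phase_type(1, 0.3), t),
               0.3 * exp(-0.3 * t), tolerance = 1e-12)
  # Erlang(2, lambda): convolution of two exponentials, lambda^2 t e^(-lt)
  expect_equal(holding_time_pdf(tmpl_erlang(2), t),
               4 * t * exp(-2 * t), tolerance = 1e-10)
  # normalisation for a generic 3-phase spec with distinct exit rates
  sp <- tmpl_m3_pa()$phases
  expect_equal(stats::integrate(function(x) holding_time_pdf(sp, x),
                                0, Inf, rel.tol = 1e-10)$value,
               1, tolerance = 1e-8)
  expect_true(all(holding_time_pdf(sp, t) >= 0))
  # cdf consistent with pdf
  expect_equal(holding_time_cdf(sp, 2),
               stats::integrate(function(x) holding_time_pdf(sp, x),
                                0, 2, rel.tol = 1e-10)$value,
               tolerance = 1e-8)
})
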