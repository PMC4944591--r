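test_that("zero-truncated log-likelihood matches hand arithmetic", {
  # m = 1, tau = 0, mu = 1: d_k = 2^-(k+1), zero-truncated d~_k = 2^-k
  mod <- pa_model(phase_type(1, 1), pa = FALSE)
  y <- degree_counts(degrees = c(1, 2), counts = c(3, 1))
  expect_equal(log_likelihood(mod, y),
               3 * log(1 / 2) + log(1 / 4), tolerance = 1e-12)
  # single-cell multinomial: all respondents at k = 1
  y1 <- degree_counts(degrees = 1, counts = 17)
  d1 <- censor_zero(degree_pmf(mod, kmax = 1, tail_warn = Inf))$d[2]
  expect_equal(log_likelihood(mod, y1), 17 * log(d1))
  # categories with zero count do not change the value (they are dropped
  # at construction)
  y2 <- degree_counts(degrees = c(1, 2, 5), counts = c(3, 1, 0))
  expect_equal(log_likelihood(mod, y2), log_likelihood(mod, y))
})

test_that("log-likelihood is the multinomial log-pmf minus the data constant", {
  mod <- tmpl_m2_pa()
  y <- degree_counts(degrees = c(1, 2, 3, 7), counts = c(5, 3, 2, 1))
  kmax <- max(y$degree)
  dt <- censor_zero(degree_pmf(mod, kmax = kmax, tail_warn = Inf))
  # four observed cells plus a catch-all for all remaining mass
  probs <- c(dt$d[y$degree + 1L], 1 - sum(dt$d[y$degree + 1L]))
  full <- dmultinom(c(y$count, 0), prob = probs, log = TRUE)
  const <- lgamma(y$n + 1) - sum(lgamma(y$count + 1))
  expect_equal(log_likelihood(mod, y), full - const, tolerance = 1e-10)
})

test_that("likelihood guards: truncation below the data errors, impossible data sinks", {
  mod <- pa_model(phase_type(1, 1), pa = FALSE)
  y <- degree_counts(degrees = c(1, 30), counts = c(5, 1))
  expect_error(log_likelihood(mod, y, kmax = 10), "largest observed")
})

test_that("single-phase fit recovers the stopping rate and matches a constrained optimiser", {
  y <- simulate_counts(tmpl_m1_tau0(), 5000, seed = 3)
  f <- fit_mle(y, 1, FALSE, fast_settings(seed = 2))
  muhat <- f$model$phases$mu
  expect_lt(abs(muhat - 0.05) / 0.05, 0.10)
  # same maximised loglik as a direct 1-d constrained search over mu
  ll <- function(mu) log_likelihood(pa_model(phase_type(1, mu),
                                             pa = FALSE), y)
  o <- optimize(ll, c(1e-4, 2), maximum = TRUE, tol = 1e-10)
  expect_equal(f$loglik, o$objective, tolerance = 1e-6)
  expect_true(f$converged)
  expect_equal(f$n_params, 1L)
})

test_that("fits are deterministic given a seed and MLE dominates the truth", {
  mod <- tmpl_m2_pa()
  y <- simulate_counts(mod, 2000, seed = 8)
  s <- fast_settings(seed = 5)
  f1 <- fit_mle(y, 2, TRUE, s)
  f2 <- fit_mle(y, 2, TRUE, s)
  expect_identical(f1$par, f2$par)
  # the fitted optimum beats the generating parameters on the same data
  expect_gte(f1$loglik, log_likelihood(mod, y) - 1e-8)
})

test_that("warm starts never worsen the fit", {
  y <- simulate_counts(tmpl_m2_pa(), 2000, seed = 9)
  s <- fast_settings(seed = 6)
  cold <- fit_mle(y, 2, TRUE, s)
  warm <- fit_mle(y, 2, TRUE, s, init = list(cold$model))
  expect_gte(warm$loglik, cold$loglik - 1e-6)
})

test_that("bootstrap intervals: degenerate at B = 1, cover the truth, widen with less data", {
  mod <- tmpl_m2_pa()
  y <- simulate_counts(mod, 5000, seed = 1)
  s <- fast_settings(seed = 2, B = 1L)
  f <- fit_mle(y, 2, TRUE, s)
  b1 <- bootstrap_ci(y, 2, TRUE, s, fit = f)
  expect_equal(unname(b1$ci[, "lower"]), unname(b1$ci[, "upper"]))
  expect_equal(unname(b1$ci[, "lower"]), unname(b1$replicates[1, ]))

  # a seeded recovery run at the study size covers the generating tau
  s40 <- fast_settings(seed = 2, B = 40L)
  b <- bootstrap_ci(y, 2, TRUE, s40, fit = f)
  expect_gte(0.05, b$ci["tau", "lower"])
  expect_lte(0.05, b$ci["tau", "upper"])

  # tenfold less data gives wider tau intervals on average (individual
  # datasets fluctuate, so compare means over replicate seeds)
  width_at <- function(n) mean(vapply(1:3, function(i) {
    yn <- simulate_counts(mod, n, seed = 40 + i)
    sn <- fast_settings(seed = i, B = 40L)
    fn <- fit_mle(yn, 2, TRUE, sn)
    diff(bootstrap_ci(yn, 2, TRUE, sn, fit = fn)$ci["tau", ])
  }, numeric(1)))
  expect_gt(width_at(300), width_at(3000))
})

test_that("parametric bootstrap band collapses at B = 1 and brackets the truth", {
  mod <- tmpl_m1_pa()
  y <- simulate_counts(mod, 5000, seed = 1)
  s <- fast_settings(seed = 3)
  f <- fit_mle(y, 1, TRUE, s)
  band1 <- parametric_bootstrap_band(f, B = 1, kmax = 30)
  expect_equal(band1$lower, band1$upper)
  # calibration: the envelope should bracket the generating pmf at
  # almost every degree, on average over replicate study datasets
  truth <- censor_zero(degree_pmf(mod, kmax = 30, tail_warn = Inf))$d
  inside <- vapply(1:3, function(i) {
    yi <- simulate_counts(mod, 5000, seed = i)
    fi <- fit_mle(yi, 1, TRUE, fast_settings(seed = i))
    band <- parametric_bootstrap_band(fi, B = 15, kmax = 30)
    expect_true(all(band$lower <= band$upper))
    mean(truth >= band$lower & truth <= band$upper)
  }, numeric(1))
  expect_gte(mean(inside), 0.9)
})
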