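test_that("single-phase solver matches the geometric and Beta-integral laws", {
  k <- 0:50
  mu <- 0.8
  d <- degree_pmf(pa_model(phase_type(1, mu), pa = FALSE), kmax = 50,
                  tail_warn = Inf)$d
  expect_equal(d, mu / (1 + mu)^(k + 1), tolerance = 1e-12)

  mu <- 0.05; tau <- 0.02
  d <- degree_pmf(pa_model(phase_type(1, mu), tau = tau), kmax = 50,
                  tail_warn = Inf)$d
  beta_law <- (mu / tau) * exp(lgamma(k + 1 / tau) - lgamma(1 / tau) -
                                 lgamma(k + 1) +
                                 lbeta((mu + 1) / tau, k + 1))
  expect_equal(d, beta_law, tolerance = 1e-12)
})

test_that("solver agrees with direct quadrature of the mixture integral", {
  for (mod in list(tmpl_m1_pa(), tmpl_m2_pa(), tmpl_m3_pa())) {
    k <- 0:40
    d <- degree_pmf(mod, kmax = 40, tail_warn = Inf)$d
    expect_equal(d, quadrature_pmf(mod, k), tolerance = 1e-8)
  }
})

test_that("probability is conserved and the tail is monotone in kmax", {
  mod <- tmpl_m2_pa()
  prev_tail <- Inf
  for (K in c(100, 400, 1600, 6400)) {
    dist <- degree_pmf(mod, kmax = K, tail_warn = Inf)
    expect_true(all(dist$d >= 0))
    expect_equal(sum(dist$d) + dist$tail_mass, 1, tolerance = 1e-12)
    expect_lte(dist$tail_mass, prev_tail)
    prev_tail <- dist$tail_mass
  }
  # adaptive truncation reaches the requested tail tolerance on a model
  # whose tail decays fast enough to get there before the hard cap
  dist <- degree_pmf(tmpl_m3_pa(), tail_tol = 1e-10)
  expect_lt(dist$tail_mass, 1e-10)
})

test_that("zero-truncation renormalises, is idempotent, and rejects the degenerate case", {
  mod <- pa_model(phase_type(1, 1), pa = FALSE)  # d = (1/2, 1/4, ...)
  dist <- degree_pmf(mod, kmax = 10, tail_warn = Inf)
  cz <- censor_zero(dist)
  expect_equal(cz$d[1], 0)
  expect_equal(cz$d[-1], dist$d[-1] / (1 - dist$d[1]), tolerance = 1e-14)
  expect_equal(censor_zero(cz), cz)
  # hand arithmetic on a two-cell distribution
  toy <- structure(list(d = c(0.2, 0.8), kmax = 1L, tail_mass = 0,
                        censored = FALSE), class = "degree_distribution")
  expect_equal(censor_zero(toy)$d, c(0, 1))
  toy0 <- structure(list(d = c(0, 0.7, 0.3), kmax = 2L, tail_mass = 0,
                         censored = FALSE), class = "degree_distribution")
  expect_equal(censor_zero(toy0)$d, toy0$d)
  degen <- structure(list(d = c(1, 0), kmax = 1L, tail_mass = 0,
                          censored = FALSE), class = "degree_distribution")
  expect_error(censor_zero(degen), "zero-truncated")
})

test_that("degree moments match closed forms and truncated sums", {
  # m = 1, tau = 0: Poisson mixed over Exp(mu) time has mean 1/mu
  expect_equal(moment_degree(tmpl_m1_tau0(), 1), 20, tolerance = 1e-12)
  # m = 1 with PA: mean 1/(mu - tau)
  expect_equal(moment_degree(tmpl_m1_pa(), 1), 1 / (0.05 - 0.02),
               tolerance = 1e-12)
  # convergent cases agree with sums over the solver pmf
  for (mod in list(tmpl_m1_pa(), tmpl_m2_pa(), tmpl_m3_pa())) {
    # heavy-tailed fixtures hit the truncation cap before 1e-12
    dist <- suppressWarnings(degree_pmf(mod, tail_tol = 1e-12))
    k <- 0:dist$kmax
    expect_equal(moment_degree(mod, 1), sum(k * dist$d),
                 tolerance = 1e-4)
  }
  # second moment on a model whose tail truncates quickly
  mild <- pa_model(phase_type(1, 0.3), tau = 0.02)
  dist <- degree_pmf(mild, tail_tol = 1e-13)
  expect_equal(moment_degree(mild, 2), sum((0:dist$kmax)^2 * dist$d),
               tolerance = 1e-8)
  expect_error(moment_degree(mild, 3), "must be 1 or 2")
})

test_that("divergence classification follows the attachment/exit-rate condition", {
  # tau = 0: nothing diverges
  expect_true(is.na(lowest_divergent_moment(tmpl_m1_tau0(),
                                            10)$lowest_divergent))
  # m = 1, mu = 0.05, tau = 0.02: 2 tau < mu <= 3 tau, so r = 3 is first
  expect_identical(lowest_divergent_moment(tmpl_m1_pa(),
                                           10)$lowest_divergent, 3L)
  # scan bounded below the first divergent order reports none
  rep2 <- lowest_divergent_moment(tmpl_m1_pa(), 2)
  expect_true(is.na(rep2$lowest_divergent))
  expect_false(any(rep2$per_moment))
  # boundary r tau = M_a counts as divergent
  expect_identical(lowest_divergent_moment(pa_model(phase_type(1, 0.1),
                                                    tau = 0.05),
                                           5)$lowest_divergent, 2L)
  expect_equal(moment_degree(pa_model(phase_type(1, 0.1), tau = 0.05), 2),
               Inf)
  # an unreachable slow phase must not drive the classification
  unreach <- pa_model(phase_type(c(1, 0), c(0.5, 0.01),
                                 matrix(0, 2, 2)), tau = 0.05)
  expect_true(is.na(lowest_divergent_moment(unreach,
                                            5)$lowest_divergent))
})

test_that("divergent truncated moments keep growing under a doubling kmax scan", {
  grid <- c(2000, 4000, 8000, 16000)
  trunc_m2 <- function(mod) vapply(grid, function(K) {
    d <- degree_pmf(mod, kmax = K, tail_warn = Inf)$d
    sum((0:K)^2 * d)
  }, numeric(1))
  s_div <- trunc_m2(tmpl_heavy())     # second moment divergent
  ratios <- s_div[-1] / s_div[-length(s_div)]
  expect_true(all(ratios > 1.2))
  s_conv <- trunc_m2(pa_model(phase_type(1, 0.08), tau = 0.02))
  expect_lt(s_conv[4] / s_conv[3], 1.01)
  expect_equal(s_conv[4], moment_degree(pa_model(phase_type(1, 0.08),
                                                 tau = 0.02), 2),
               tolerance = 1e-2)
})
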