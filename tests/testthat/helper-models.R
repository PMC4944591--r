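# Template models used across the suite. These are the study conditions:
# rates are on the scale of the base contact-making rate, chosen so mean
# degrees sit in the range contact surveys report (a handful to a few
# tens of contacts per day).

# single phase, no attachment: geometric degrees with mean 20
tmpl_m1_tau0 <- function() pa_model(phase_type(1, 0.05), pa = FALSE)

# single phase with mild attachment; third moment divergent
tmpl_m1_pa <- function() pa_model(phase_type(1, 0.05), tau = 0.02)

# two phases with attachment (the recovery-study generator);
# second moment finite, third divergent
tmpl_m2_pa <- function(tau = 0.05)
  pa_model(phase_type(c(0.6, 0.4), c(0.3, 0.12),
                      matrix(c(0, 0.2, 0, 0), 2, byrow = TRUE)),
           tau = tau, pa = TRUE)

# three phases, mild attachment, all template moments up to r = 4 finite
tmpl_m3_pa <- function()
  pa_model(phase_type(c(0.5, 0.3, 0.2), c(0.4, 0.25, 0.1),
                      upper_tri_matrix(c(0.3, 0.1, 0.15), 3)),
           tau = 0.02)

# single phase tuned so the second moment diverges (2 tau >= mu) while
# the mean stays finite
tmpl_heavy <- function() pa_model(phase_type(1, 0.08), tau = 0.05)

# Erlang(2) holding time: repeated exit rates exercise the matrix-
# exponential fallback of the holding-time density
tmpl_erlang <- function(lambda = 2)
  phase_type(c(1, 0), c(0, lambda),
             matrix(c(0, lambda, 0, 0), 2, byrow = TRUE))

fast_settings <- function(seed = 1L, ...)
  fit_settings(n_starts = 3L, sann_iter = 500L, boot_starts = 1L,
               boot_sann_iter = 200L, seed = seed, ...)

# independent PGF Taylor-coefficient oracle: coefficients of g(t, s) on
# the complex unit circle via the FFT (the PGF is analytic in a disk of
# radius exp(tau t) / (exp(tau t) - 1) > 1)
taylor_coefs_fft <- function(tau, t, K, N = 8192L) {
  s <- exp(2i * pi * (0:(N - 1)) / N)
  g <- if (tau < 1e-8) exp(t * (s - 1))
       else (s - (s - 1) * exp(tau * t))^(-1 / tau)
  Re(stats::fft(g) / N)[1:(K + 1)]
}

# direct quadrature of the mixture integral d_k = int rho(t) p_k(t) dt,
# an oracle independent of the triangular recursion
quadrature_pmf <- function(model, k) {
  sp <- model$phases
  vapply(k, function(kk)
    stats::integrate(function(tv)
      holding_time_pdf(sp, tv) *
        vapply(tv, function(t) pmf_conditional(model$tau, t, kk),
               numeric(1)),
      0, Inf, rel.tol = 1e-12, abs.tol = 1e-14)$value,
    numeric(1))
}
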