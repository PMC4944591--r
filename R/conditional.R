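# Conditional-on-time law of the contact count K(t).
#
# With contact rate f_k = 1 + tau k and K(0) = 0, the probability
# generating function is
#   g(t, s) = (s - (s - 1) exp(tau t))^(-1/tau)
#           = exp(-t) * (1 - (1 - exp(-tau t)) s)^(-1/tau),
# a negative binomial with size 1/tau and success probability exp(-tau t)
# (number of failures before 1/tau successes). tau -> 0 gives the Poisson
# limit exp(t (s - 1)). All 1/tau expressions switch to their analytic
# limits below TAU_EPS to avoid catastrophic cancellation.

TAU_EPS <- 1e-8

#' Probability generating function of the contact count at fixed time
#'
#' `g(t, s) = E[s^K(t)]` for the pure-birth contact process with rate
#' `1 + tau * k`. At `tau = 0` the analytic Poisson limit
#' `exp(t (s - 1))` is returned.
#'
#' @param tau attachment coefficient, `>= 0`.
#' @param t elapsed time, `>= 0`.
#' @param s PGF argument in `[0, 1]` (vectorised).
#' @return `g(t, s)`, same length as `s`.
#' @examples
#' pgf_conditional(1, log(2), 0.5)  # 2/3
#' @export
pgf_conditional <- function(tau, t, s) {
  if (tau < 0) stop("'tau' must be non-negative")
  if (t < 0) stop("'t' must be non-negative")
  if (any(s < 0 | s > 1)) stop("'s' must lie in [0, 1]")
  if (tau < TAU_EPS) return(exp(t * (s - 1)))
  # log g = -(1/tau) * log(1 + (1 - s) expm1(tau t)), stable near s = 1
  exp(-log1p((1 - s) * expm1(tau * t)) / tau)
}

#' Conditional degree distribution at fixed time
#'
#' Probability that an individual holds `k` contacts after `t` time units
#' of activity: the `k`-th Taylor coefficient of the PGF, a negative
#' binomial with size `1/tau` and success probability `exp(-tau t)`
#' (Poisson with mean `t` in the `tau -> 0` limit). Evaluated in log space
#' with the rising-factorial sum `sum_j log(1/tau + j)` so that small `tau`
#' and large `k` stay accurate.
#'
#' @inheritParams pgf_conditional
#' @param k non-negative integer degree(s) (vectorised).
#' @param log logical; return log probabilities?
#' @return `P(K(t) = k)`, same length as `k`.
#' @examples
#' pmf_conditional(1, 2, 0:3)   # geometric: exp(-t) (1 - exp(-t))^k
#' pmf_conditional(0, 2, 0:3)   # Poisson mean 2
#' @export
pmf_conditional <- function(tau, t, k, log = FALSE) {
  if (tau < 0) stop("'tau' must be non-negative")
  if (t < 0) stop("'t' must be non-negative")
  if (any(k < 0 | k != round(k))) stop("'k' must be non-negative integers")
  if (tau < TAU_EPS) return(stats::dpois(k, t, log = log))
  if (t == 0) {
    lp <- ifelse(k == 0, 0, -Inf)
    return(if (log) lp else exp(lp))
  }
  kmax <- max(k)
  # log Gamma(k + 1/tau) - log Gamma(1/tau) = sum_{j=0}^{k-1} log(1/tau + j),
  # computed as -k log tau + cumsum log(1 + j tau): no large-argument
  # cancellation even when 1/tau is huge
  lcum <- if (kmax > 0) c(0, cumsum(log1p(tau * (0:(kmax - 1))))) else 0
  lrise <- lcum[k + 1] - k * base::log(tau)
  lq <- base::log(-expm1(-tau * t))  # log(1 - exp(-tau t))
  lp <- lrise - lgamma(k + 1) - t + k * lq
  if (log) lp else exp(lp)
}

#' Raw moments of the conditional degree distribution
#'
#' The `r`-th raw moment `E[K(t)^r]` of the contact count at fixed time,
#' obtained from the closed-form factorial moments of the negative-binomial
#' law: `E[K (K-1) ... (K-r+1)] = m1^r * prod_{j=0}^{r-1} (1 + j tau)` with
#' `m1 = (exp(tau t) - 1)/tau`, converted to raw moments via Stirling
#' numbers of the second kind. For `r = 1, 2` this reduces to
#' `m1` and `m1 + (tau + 1) m1^2`.
#'
#' @inheritParams pgf_conditional
#' @param r moment order, a positive integer.
#' @return The moment value (finite for all finite `t`).
#' @examples
#' moment_conditional(0.5, 2, 1)  # (exp(1) - 1) / 0.5
#' @export
moment_conditional <- function(tau, t, r) {
  if (tau < 0) stop("'tau' must be non-negative")
  if (t < 0) stop("'t' must be non-negative")
  if (r < 1 || r != round(r)) stop("'r' must be a positive integer")
  m1 <- if (tau == 0) t else expm1(tau * t) / tau
  fact <- vapply(1:r, function(j) m1^j * prod(1 + tau * (0:(j - 1))),
                 numeric(1))
  sum(stirling2(r)[-1] * fact)  # drop j = 0 term (S(r,0) = 0 for r >= 1)
}

# Row r of the Stirling-second-kind triangle: S(r, 0..r), by the standard
# recurrence S(n, j) = j S(n-1, j) + S(n-1, j-1).
stirling2 <- function(r) {
  S <- 1
  for (n in seq_len(r)) S <- c(0, S) + (0:n) * c(S, 0)
  S
}
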