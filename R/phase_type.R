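#' Phase-type specification of the contact-making period
#'
#' Describes the random time an individual spends making new contacts as the
#' absorption time of a continuous-time Markov chain over `m` activity
#' phases. An individual starts in phase `a` with probability `nu[a]`, stops
#' making contacts at rate `mu[a]` while in phase `a`, and moves from phase
#' `a` to a later phase `b > a` at rate `Q[a, b]`. Phases are visited in
#' increasing order only, so `Q` is strictly upper triangular; the resulting
#' holding-time density is a phase-type distribution, a family dense in the
#' positive continuous distributions.
#'
#' The total exit rate of phase `a` is `M_a = mu[a] + sum(Q[a, a < b])`.
#' Every phase must have `M_a > 0`, otherwise the process could stay in a
#' phase forever and the holding time would not be a proper random variable.
#'
#' @param nu numeric vector of initial-phase probabilities; must be
#'   non-negative and sum to 1.
#' @param mu numeric vector of per-phase stopping rates (per unit time,
#'   where one time unit is `1 /` the base contact-making rate).
#' @param Q strictly upper-triangular `m x m` matrix of phase-transition
#'   rates, or `NULL` for the single-phase case / no transitions.
#' @return An object of class `"phase_type"` with fields `m`, `nu`, `mu`,
#'   `Q` and the per-phase total exit rates `M`.
#' @examples
#' # a single exponential phase with mean 20 time units
#' phase_type(nu = 1, mu = 0.05)
#'
#' # an Erlang(2) chain: phase 1 can only move on to phase 2
#' phase_type(nu = c(1, 0), mu = c(0, 1), Q = matrix(c(0, 1, 0, 0), 2,
#'            byrow = TRUE))
#' @seealso [pa_model()], [holding_time_pdf()]
#' @export
phase_type <- function(nu, mu, Q = NULL) {
  m <- length(nu)
  if (is.null(Q)) Q <- matrix(0, m, m)
  Q <- as.matrix(Q)
  spec <- structure(
    list(m = m, nu = as.numeric(nu), mu = as.numeric(mu), Q = Q,
         M = as.numeric(mu) + rowSums(Q)),
    class = "phase_type")
  validate_phase_type(spec)
}

#' Validate a phase-type specification
#'
#' Checks the structural invariants of a [phase_type()] object and returns
#' it unchanged if they all hold; otherwise stops with a message naming the
#' violated invariant.
#'
#' @param spec a `"phase_type"` object (or a bare list with the same
#'   fields).
#' @return `spec`, invisibly unchanged, if valid.
#' @export
validate_phase_type <- function(spec) {
  m <- spec$m
  nu <- spec$nu; mu <- spec$mu; Q <- spec$Q
  if (!is.numeric(m) || m < 1 || m != round(m))
    stop("number of phases 'm' must be a positive integer")
  if (length(nu) != m || length(mu) != m)
    stop("'nu' and 'mu' must each have one entry per phase")
  if (!all(is.finite(nu)) || any(nu < 0))
    stop("initial probabilities 'nu' must be finite and non-negative")
  if (abs(sum(nu) - 1) > 1e-8)
    stop("initial probabilities 'nu' must sum to 1 (got ",
         format(sum(nu)), ")")
  if (!all(is.finite(mu)) || any(mu < 0))
    stop("stopping rates 'mu' must be finite and non-negative")
  if (!is.matrix(Q) || any(dim(Q) != m))
    stop("'Q' must be an ", m, " x ", m, " matrix")
  if (!all(is.finite(Q)) || any(Q < 0))
    stop("transition rates 'Q' must be finite and non-negative")
  if (any(Q[lower.tri(Q, diag = TRUE)] != 0))
    stop("'Q' must be strictly upper triangular: phases are visited in ",
         "increasing order and a phase cannot transition to itself")
  M <- mu + rowSums(Q)
  if (any(M <= 0)) {
    bad <- which(M <= 0)[1L]
    stop("phase ", bad, " has zero total exit rate: the contact-making ",
         "period would never end")
  }
  spec$M <- M
  spec
}

#' @export
#' @method print phase_type
print.phase_type <- function(x, ...) {
  cat("Phase-type holding-time specification (", x$m, " phase",
      if (x$m > 1) "s", ")\n", sep = "")
  cat("  nu:", format(x$nu, digits = 4), "\n")
  cat("  mu:", format(x$mu, digits = 4), "\n")
  if (any(x$Q > 0)) {
    idx <- which(x$Q > 0, arr.ind = TRUE)
    for (i in seq_len(nrow(idx)))
      cat("  Q[", idx[i, 1], "->", idx[i, 2], "]: ",
          format(x$Q[idx[i, 1], idx[i, 2]], digits = 4), "\n", sep = "")
  }
  invisible(x)
}

# Sub-generator of the phase process written so that the column vector of
# phase occupancy probabilities p(t) solves dp/dt = G p, p(0) = nu:
# G[a, a] = -M_a and G[b, a] = Q[a, b] for a < b.
phase_generator <- function(spec) {
  G <- t(spec$Q)
  diag(G) <- -spec$M
  G
}

# rho(t) = sum_a mu_a p_a(t) evaluated either spectrally (distinct exit
# rates) or via the matrix exponential (repeated exit rates make the
# triangular generator defective, e.g. Erlang chains).
phase_density_eval <- function(spec, t, what = c("pdf", "survival")) {
  what <- match.arg(what)
  G <- phase_generator(spec)
  w <- if (what == "pdf") spec$mu else rep(1, spec$m)
  if (spec$m == 1L) {
    z <- exp(-spec$M * t)
    return(w * z * spec$nu)
  }
  rates <- sort(spec$M)
  if (min(diff(rates)) > 1e-8 * max(rates)) {
    eg <- eigen(G)
    coef <- as.vector((w %*% eg$vectors) * solve(eg$vectors, spec$nu))
    return(as.vector(vapply(t, function(ti)
      Re(sum(coef * exp(eg$values * ti))), numeric(1))))
  }
  vapply(t, function(ti)
    sum(w * as.vector(Matrix::expm(G * ti) %*% spec$nu)), numeric(1))
}

#' Holding-time density of a phase-type specification
#'
#' Evaluates the probability density function of the contact-making period,
#' `rho(t) = mu' exp(G t) nu`, where `G` is the sub-generator of the phase
#' process (diagonal `-M_a`, off-diagonal the transition rates into each
#' phase). For distinct exit rates the triangular structure gives an exact
#' spectral form; with repeated exit rates (e.g. Erlang chains) the matrix
#' exponential is used directly.
#'
#' @param spec a [phase_type()] specification.
#' @param t numeric vector of non-negative times.
#' @return Density values, same length as `t`.
#' @examples
#' sp <- phase_type(1, 0.05)
#' holding_time_pdf(sp, c(0, 10, 20))  # 0.05 * exp(-0.05 t)
#' @export
holding_time_pdf <- function(spec, t) {
  spec <- validate_phase_type(spec)
  if (any(t < 0)) stop("'t' must be non-negative")
  phase_density_eval(spec, t, "pdf")
}

#' Holding-time cumulative distribution function
#'
#' `P(T <= t)` for the phase-type contact-making period; the complement of
#' the total probability still occupying some phase at time `t`.
#'
#' @inheritParams holding_time_pdf
#' @return CDF values, same length as `t`.
#' @export
holding_time_cdf <- function(spec, t) {
  spec <- validate_phase_type(spec)
  if (any(t < 0)) stop("'t' must be non-negative")
  1 - phase_density_eval(spec, t, "survival")
}

# Phases that can be occupied with positive probability: directly via nu or
# through a chain of positive-rate transitions (topological order = index
# order because Q is strictly upper triangular).
reachable_phases <- function(spec) {
  reach <- spec$nu > 0
  if (spec$m > 1) {
    for (a in 2:spec$m)
      reach[a] <- reach[a] || any(reach[1:(a - 1)] & spec$Q[1:(a - 1), a] > 0)
  }
  reach
}
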