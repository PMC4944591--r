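#' Unconditional degree distribution of the contact-formation model
#'
#' Computes the probability mass function `d_k` of the final number of
#' contacts, mixing the pure-birth contact process over the phase-type
#' contact-making period. The computation uses the triangular spectral
#' recursion obtained by Laplace-transforming the phase/degree master
#' equation at frequency zero: the linear system for the time-integrated
#' occupancies is triangular in both phase and degree, so the full pmf up
#' to `kmax` costs `O(m^2 kmax)` with no matrix inversion.
#'
#' When `kmax = NULL` the truncation index is chosen adaptively: it is
#' doubled until the residual tail mass drops below `tail_tol` or the hard
#' cap of `1e5` is reached (a warning reports the tail mass in the latter
#' case, or whenever a user-supplied `kmax` leaves more than `tail_warn`
#' unaccounted for). Heavy-tailed models — attachment coefficient close to
#' a phase exit rate — genuinely need very large `kmax`; see
#' [lowest_divergent_moment()] for the diagnostic.
#'
#' @param model a [pa_model()].
#' @param kmax truncation degree, or `NULL` for adaptive selection.
#' @param tail_tol adaptive-truncation target for the residual tail mass.
#' @param tail_warn tail mass above which a warning is issued for a fixed
#'   `kmax`.
#' @return An object of class `"degree_distribution"`: a list with `d`
#'   (probabilities for degrees `0..kmax`), `kmax`, `tail_mass`
#'   (`1 - sum(d)`), and `censored = FALSE`.
#' @examples
#' mod <- pa_model(phase_type(1, 1), pa = FALSE)
#' degree_pmf(mod, kmax = 5)$d  # geometric: 1/2^(k+1)
#' @export
degree_pmf <- function(model, kmax = NULL, tail_tol = 1e-10,
                       tail_warn = 1e-6) {
  stopifnot(inherits(model, "pa_model"))
  sp <- validate_phase_type(model$phases)
  hard_cap <- 100000L
  if (is.null(kmax)) {
    k <- 256L
    repeat {
      d <- cpp_degree_pmf(sp$nu, sp$mu, sp$Q, model$tau, k)
      tail <- max(0, 1 - sum(d))
      if (tail < tail_tol || k >= hard_cap) break
      k <- min(2L * k, hard_cap)
    }
    if (tail >= tail_tol)
      warning("tail mass ", format(tail, digits = 3),
              " remains above ", format(tail_tol),
              " at the truncation cap kmax = ", k)
  } else {
    if (kmax < 0 || kmax != round(kmax)) stop("'kmax' must be >= 0")
    k <- as.integer(kmax)
    d <- cpp_degree_pmf(sp$nu, sp$mu, sp$Q, model$tau, k)
    tail <- max(0, 1 - sum(d))
    if (tail > tail_warn)
      warning("tail mass ", format(tail, digits = 3),
              " beyond kmax = ", k,
              "; increase 'kmax' or use adaptive truncation")
  }
  new_degree_distribution(d, tail, censored = FALSE)
}

new_degree_distribution <- function(d, tail_mass, censored) {
  structure(list(d = as.numeric(d), kmax = length(d) - 1L,
                 tail_mass = tail_mass, censored = censored),
            class = "degree_distribution")
}

#' @export
#' @method print degree_distribution
print.degree_distribution <- function(x, ...) {
  cat("Degree distribution", if (x$censored) "(zero-truncated)",
      "up to kmax =", x$kmax, "\n")
  cat("  tail mass beyond kmax:", format(x$tail_mass, digits = 4), "\n")
  show <- min(x$kmax, 8L)
  cat("  d[0..", show, "]: ", paste(format(x$d[1:(show + 1)], digits = 4),
                                    collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Zero-truncate a degree distribution
#'
#' Survey respondents reporting zero contacts are censored, so the model
#' pmf is conditioned on at least one contact: `d~_0 = 0` and
#' `d~_k = d_k / (1 - d_0)` for `k > 0`. Idempotent.
#'
#' @param dist a `"degree_distribution"` from [degree_pmf()].
#' @return The censored `"degree_distribution"`.
#' @export
censor_zero <- function(dist) {
  stopifnot(inherits(dist, "degree_distribution"))
  if (dist$censored) return(dist)
  d0 <- dist$d[1]
  if (d0 >= 1)
    stop("d_0 = 1: no individual ever makes a contact, so the ",
         "zero-truncated distribution is undefined")
  d <- dist$d / (1 - d0)
  d[1] <- 0
  new_degree_distribution(d, dist$tail_mass / (1 - d0), censored = TRUE)
}

#' Moments of the unconditional degree distribution
#'
#' The `r`-th moment mixes the closed-form conditional moments over the
#' phase-type holding time. Writing `I_r` for the integral of
#' `exp(r tau t)` against the holding-time density — available exactly as
#' `mu' (-(G + r tau I))^{-1} nu` because the phase generator is triangular
#' — the first two moments are `(I_1 - 1)/tau` and
#' `(I_1 - 1)/tau + (tau + 1)(I_2 - 2 I_1 + 1)/tau^2`; at `tau = 0` they
#' reduce to `E[T]` and `E[T] + E[T^2]`. The moment is infinite whenever
#' some reachable phase has total exit rate `M_a <= r tau`, in which case
#' `Inf` is returned.
#'
#' @param model a [pa_model()].
#' @param r moment order, 1 or 2.
#' @return The moment, or `Inf` when divergent.
#' @examples
#' moment_degree(pa_model(phase_type(1, 0.05), pa = FALSE), 1)  # 20
#' @export
moment_degree <- function(model, r) {
  stopifnot(inherits(model, "pa_model"))
  if (!r %in% c(1, 2)) stop("'r' must be 1 or 2")
  sp <- validate_phase_type(model$phases)
  tau <- model$tau
  if (divergent_at(model, r)) return(Inf)
  G <- phase_generator(sp)
  if (tau < TAU_EPS) {
    # E[T^j] = j! mu' (-G)^{-(j+1)} nu
    x1 <- solve(-G, sp$nu)
    ET <- sum(sp$mu * solve(-G, x1))
    if (r == 1) return(ET)
    ET2 <- 2 * sum(sp$mu * solve(-G, solve(-G, x1)))
    return(ET + ET2)
  }
  I1 <- sum(sp$mu * solve(-(G + tau * diag(sp$m)), sp$nu))
  m1 <- (I1 - 1) / tau
  if (r == 1) return(m1)
  I2 <- sum(sp$mu * solve(-(G + 2 * tau * diag(sp$m)), sp$nu))
  m1 + (tau + 1) * (I2 - 2 * I1 + 1) / tau^2
}

# is the r-th moment divergent? Boundary r tau = M_a counts as divergent
# (the integrand of I_r is asymptotically constant there). Only phases
# occupied with positive probability matter.
divergent_at <- function(model, r) {
  sp <- model$phases
  reach <- reachable_phases(sp)
  any(reach & (r * model$tau >= sp$M))
}

#' Moment-divergence diagnostic
#'
#' Scans moment orders `r = 1..r_max` and reports which are infinite. The
#' `r`-th degree moment diverges exactly when some phase reachable with
#' positive probability has total exit rate `M_a <= r tau`: the attachment
#' gain then outruns the fastest the individual can stop. The boundary
#' case `r tau = M_a` is classified divergent. Epidemiologically, a
#' divergent second moment would mean no amount of untargeted vaccination
#' could control an epidemic on the contact network.
#'
#' @param model a [pa_model()].
#' @param r_max highest moment order scanned.
#' @return An object of class `"divergence_report"`: list with
#'   `per_moment` (logical vector, `TRUE` = divergent) and
#'   `lowest_divergent` (smallest divergent order, or `NA` if none up to
#'   `r_max`).
#' @examples
#' mod <- pa_model(phase_type(1, 0.05), tau = 0.02)
#' lowest_divergent_moment(mod, 5)  # first divergent moment is r = 3
#' @export
lowest_divergent_moment <- function(model, r_max = 10L) {
  stopifnot(inherits(model, "pa_model"))
  if (r_max < 1 || r_max != round(r_max)) stop("'r_max' must be >= 1")
  per <- vapply(seq_len(r_max), function(r) divergent_at(model, r),
                logical(1))
  structure(list(per_moment = per,
                 lowest_divergent = if (any(per)) which(per)[1L]
                                    else NA_integer_),
            class = "divergence_report")
}

#' @export
#' @method print divergence_report
print.divergence_report <- function(x, ...) {
  if (is.na(x$lowest_divergent))
    cat("All degree moments up to r =", length(x$per_moment),
        "are finite\n")
  else
    cat("Lowest divergent degree moment: r =", x$lowest_divergent, "\n")
  invisible(x)
}
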