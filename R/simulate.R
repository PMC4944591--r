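#' Exact simulation of the contact-formation process
#'
#' Event-driven (Gillespie) simulation of individuals accumulating
#' contacts: each individual starts with zero contacts in a phase drawn
#' from the initial distribution, then competing exponential clocks drive
#' new contacts (rate `1 + tau k`), moves to later phases (the `Q` rates)
#' and stopping (rate `mu_a`). The simulation is exact — the total rate is
#' sampled, then the event chosen categorically — so it serves as an
#' independent oracle for the spectral solver. Randomness flows through
#' R's RNG: call `set.seed()` (or pass `seed`) for reproducibility.
#'
#' @param model a [pa_model()].
#' @param n number of individuals.
#' @param seed optional integer seed applied before simulating.
#' @return `simulate_degrees()`: a data frame with one row per individual,
#'   columns `degree` (final contact count) and `time` (stopping time).
#' @examples
#' mod <- pa_model(phase_type(1, 0.05), pa = FALSE)
#' head(simulate_degrees(mod, 5, seed = 1))
#' @export
simulate_degrees <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "pa_model"))
  sp <- validate_phase_type(model$phases)
  if (n < 1 || n != round(n)) stop("'n' must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_simulate(as.integer(n), sp$nu, sp$mu, sp$Q, model$tau)
  data.frame(degree = res$degree, time = res$time)
}

#' @rdname simulate_degrees
#' @return `simulate_individual()`: a single final degree (integer).
#' @export
simulate_individual <- function(model) {
  simulate_degrees(model, 1L)$degree
}

#' Simulate a contact-count dataset
#'
#' Runs [simulate_degrees()] for `n` individuals and tabulates the result
#' as a [degree_counts()] object. With `censor_zero = TRUE` (the default,
#' matching how contact surveys only contain respondents who reported at
#' least one contact) individuals with zero contacts are discarded after
#' the fact and the respondent total reflects those retained.
#'
#' @inheritParams simulate_degrees
#' @param censor_zero drop zero-degree individuals?
#' @return A [degree_counts()] object; the attribute `"n_simulated"`
#'   records the pre-censoring population size.
#' @examples
#' simulate_counts(pa_model(phase_type(1, 0.1), pa = FALSE), 100, seed = 1)
#' @export
simulate_counts <- function(model, n, seed = NULL, censor_zero = TRUE) {
  k <- simulate_degrees(model, n, seed = seed)$degree
  if (censor_zero) k <- k[k > 0]
  if (length(k) == 0)
    stop("all simulated individuals had zero contacts; nothing left ",
         "after censoring")
  if (!censor_zero && any(k == 0))
    stop("zero degrees present: 'degree_counts' is zero-truncated by ",
         "construction; use censor_zero = TRUE")
  y <- degree_counts(k)
  attr(y, "n_simulated") <- as.integer(n)
  y
}
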