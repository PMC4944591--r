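#' Contact-formation model with optional preferential attachment
#'
#' Combines a phase-type specification of the contact-making period with a
#' linear preferential-attachment rule for the contact process itself: an
#' individual currently holding `k` contacts gains a new one at rate
#' `f_k = 1 + tau * k`. Time is measured in units of the base contact rate,
#' so the only contact-process parameter is the attachment coefficient
#' `tau >= 0`; `tau = 0` recovers contact formation at constant rate
#' (no preferential attachment), while `tau > 0` means better-connected
#' individuals accumulate contacts faster.
#'
#' @param phases a [phase_type()] specification (or the arguments `nu`,
#'   `mu`, `Q` given directly via `...`).
#' @param tau attachment coefficient, a non-negative dimensionless
#'   multiplier per existing contact. Must be exactly 0 when `pa = FALSE`.
#' @param pa logical; is the attachment coefficient a free parameter of the
#'   model? Distinguishes the model family (used in parameter counting and
#'   nesting) from the value of `tau` itself.
#' @param ... passed to [phase_type()] when `phases` is not already a
#'   `"phase_type"` object.
#' @return An object of class `"pa_model"` with fields `phases`, `tau`,
#'   `pa`.
#' @examples
#' # single phase, no preferential attachment: geometric degrees
#' pa_model(phase_type(1, 0.05), tau = 0, pa = FALSE)
#'
#' # two phases with moderate attachment
#' pa_model(phase_type(c(0.7, 0.3), c(0.3, 0.12),
#'                     matrix(c(0, 0.2, 0, 0), 2, byrow = TRUE)),
#'          tau = 0.05)
#' @export
pa_model <- function(phases, tau = 0, pa = tau > 0, ...) {
  if (!inherits(phases, "phase_type")) phases <- phase_type(phases, ...)
  phases <- validate_phase_type(phases)
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau < 0)
    stop("'tau' must be a single non-negative number")
  if (!pa && tau != 0)
    stop("a model without preferential attachment must have tau = 0 exactly")
  structure(list(phases = phases, tau = as.numeric(tau), pa = isTRUE(pa)),
            class = "pa_model")
}

#' @export
#' @method print pa_model
print.pa_model <- function(x, ...) {
  cat("Contact-formation model: ", x$phases$m, " phase",
      if (x$phases$m > 1) "s", ", ",
      if (x$pa) paste0("preferential attachment (tau = ",
                       format(x$tau, digits = 4), ")")
      else "no preferential attachment", "\n", sep = "")
  print(x$phases)
  invisible(x)
}

#' Number of free parameters of a contact-formation model
#'
#' Counts the independently estimable parameters: `m - 1` initial-phase
#' probabilities (the simplex constraint removes one), `m` stopping rates,
#' `m (m - 1) / 2` strictly upper-triangular transition rates, and one more
#' for the attachment coefficient when the model family includes
#' preferential attachment. Used as the complexity penalty in AIC/BIC and
#' as the degrees of freedom bookkeeping for likelihood ratio tests.
#'
#' @param model a [pa_model()] (or a `"pa_fit"` result, whose fitted model
#'   is used).
#' @return Integer parameter count.
#' @examples
#' count_parameters(pa_model(phase_type(1, 1), pa = FALSE))           # 1
#' count_parameters(pa_model(phase_type(c(1, 0, 0, 0, 0), rep(1, 5),
#'   upper_tri_matrix(rep(1, 10), 5)), tau = 0.1, pa = TRUE))         # 20
#' @export
count_parameters <- function(model) {
  if (inherits(model, "pa_fit")) model <- model$model
  if (!inherits(model, "pa_model")) stop("'model' must be a pa_model")
  m <- model$phases$m
  (m - 1L) + m + (m * (m - 1L)) %/% 2L + as.integer(model$pa)
}

#' Build a strictly upper-triangular matrix from its free entries
#'
#' Convenience for constructing phase-transition rate matrices: fills the
#' strictly upper triangle of an `m x m` matrix row by row from a vector of
#' `m (m - 1) / 2` rates.
#'
#' @param x numeric vector of length `m (m - 1) / 2` (row-major upper
#'   triangle).
#' @param m matrix dimension.
#' @return An `m x m` matrix, zero on and below the diagonal.
#' @export
upper_tri_matrix <- function(x, m) {
  Q <- matrix(0, m, m)
  if (m > 1) {
    Qt <- t(Q)
    Qt[lower.tri(Qt)] <- x  # column-major lower of t(Q) = row-major upper of Q
    Q <- t(Qt)
  }
  Q
}

# row-major strictly-upper-triangular entries of Q as a vector
upper_tri_vec <- function(Q) t(Q)[lower.tri(Q)]
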