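#' Information criteria
#'
#' `aic()` returns `2 p - 2 loglik`; `bic()` returns
#' `p log(n) - 2 loglik`, with `p` the free-parameter count and `n` the
#' number of respondents. Both use the truncated-multinomial log-likelihood
#' with its data-only combinatorial constant dropped, which cancels in all
#' within-data comparisons.
#'
#' @param loglik maximised log-likelihood.
#' @param n_params free-parameter count.
#' @param n number of observations.
#' @return The criterion value.
#' @export
aic <- function(loglik, n_params) 2 * n_params - 2 * loglik

#' @rdname aic
#' @export
bic <- function(loglik, n_params, n) n_params * base::log(n) - 2 * loglik

# is fit_null nested in fit_alt? Same data required. Informative pairs:
# same m with PA added, or more phases with the same PA status (an extra
# phase collapses to the null by zeroing its inbound rates).
check_nested <- function(fit_null, fit_alt) {
  if (!identical(fit_null$y$degree, fit_alt$y$degree) ||
      !identical(fit_null$y$count, fit_alt$y$count))
    stop("likelihood ratio test requires both models fitted to the ",
         "same data")
  m0 <- fit_null$model$phases$m; m1 <- fit_alt$model$phases$m
  p0 <- fit_null$model$pa; p1 <- fit_alt$model$pa
  ok <- (m0 == m1 && !p0 && p1) || (m0 < m1 && p0 == p1)
  if (!ok)
    stop("models are not nested in an informative way: the test applies ",
         "to adding preferential attachment at fixed phase count, or ",
         "adding phases at fixed PA status")
  if (fit_alt$n_params <= fit_null$n_params)
    stop("the alternative must have strictly more parameters")
  invisible(TRUE)
}

#' Likelihood ratio test between nested contact-formation models
#'
#' Computes `2 (loglik_alt - loglik_null)` (clamped at zero, since finite
#' optimisation can leave the richer model a hair below the null) and
#' refers it to a chi-square with degrees of freedom equal to the
#' parameter-count difference. Only informative nestings are accepted:
#' adding preferential attachment at fixed phase count, or adding phases
#' at fixed PA status.
#'
#' When testing for preferential attachment, the null value `tau = 0` lies
#' on the boundary of the parameter space, so the plain chi-square
#' reference is conservative; the asymptotic null is really a 50:50
#' mixture of a point mass at zero and a chi-square with one degree of
#' freedom. The default follows the plain chi-square for comparability
#' with standard workflows; `boundary = TRUE` applies the mixture
#' correction (halving the tail probability).
#'
#' @param fit_null,fit_alt [fit_mle()] results on the same data, null
#'   nested in alternative.
#' @param boundary apply the boundary mixture correction? Only meaningful
#'   for the single-parameter PA test; ignored with a warning otherwise.
#' @return A list of class `"pa_lrt"`: `statistic`, `df`, `p_value`,
#'   `boundary`.
#' @export
lrt <- function(fit_null, fit_alt, boundary = FALSE) {
  stopifnot(inherits(fit_null, "pa_fit"), inherits(fit_alt, "pa_fit"))
  check_nested(fit_null, fit_alt)
  df <- fit_alt$n_params - fit_null$n_params
  stat <- max(0, 2 * (fit_alt$loglik - fit_null$loglik))
  pa_pair <- fit_null$model$phases$m == fit_alt$model$phases$m &&
    !fit_null$model$pa && fit_alt$model$pa
  if (boundary && !(pa_pair && df == 1L)) {
    warning("boundary correction only applies to the one-parameter PA ",
            "test; using the plain chi-square reference")
    boundary <- FALSE
  }
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  if (boundary) p <- if (stat == 0) 1 else p / 2
  structure(list(statistic = stat, df = df, p_value = p,
                 boundary = boundary),
            class = "pa_lrt")
}

#' @export
#' @method print pa_lrt
print.pa_lrt <- function(x, ...) {
  cat("Likelihood ratio test: statistic = ",
      format(x$statistic, digits = 5), ", df = ", x$df,
      ", p = ", format.pval(x$p_value, digits = 4),
      if (x$boundary) " (boundary-corrected)", "\n", sep = "")
  invisible(x)
}

#' Fit and compare the grid of contact-formation models
#'
#' Fits every model with `1..m_max` phases, with and without preferential
#' attachment, and tabulates parameter counts, log-likelihoods, AIC and
#' BIC differences from the grid minima, and the lowest divergent degree
#' moment for the PA models. Richer models are warm-started from the
#' optima of the models nested in them (the simpler fit's parameters,
#' padded with small rates for the extra phase, or with a small attachment
#' coefficient), alongside fresh random starts, which keeps the
#' log-likelihood monotone along nesting chains up to optimiser tolerance.
#'
#' @param y a [degree_counts()] object.
#' @param m_max largest phase count.
#' @param settings a [fit_settings()] list.
#' @param r_max highest moment order scanned for divergence.
#' @return An object of class `"selection_table"`: a data frame with one
#'   row per `(m, pa)` cell (columns `m`, `pa`, `n_params`, `loglik`,
#'   `AIC`, `BIC`, `dAIC`, `dBIC`, `diverge`, `converged`,
#'   `preferred_aic`, `preferred_bic`) carrying the fits as attribute
#'   `"fits"` and the respondent count as attribute `"n"`.
#' @export
selection_grid <- function(y, m_max, settings = fit_settings(),
                           r_max = 10L) {
  stopifnot(inherits(y, "degree_counts"), m_max >= 1)
  fits <- list()
  key <- function(m, pa) paste0(m, if (pa) "Y" else "N")
  for (m in seq_len(m_max)) {
    for (pa in c(FALSE, TRUE)) {
      init <- list()
      if (m > 1) {
        prev <- fits[[key(m - 1L, pa)]]
        if (!is.null(prev) && prev$converged)
          init <- c(init, list(grow_phase(prev$model)))
      }
      if (pa) {
        base_fit <- fits[[key(m, FALSE)]]
        if (!is.null(base_fit) && base_fit$converged)
          init <- c(init, list(add_pa(base_fit$model)))
      }
      cs <- settings
      cs$seed <- settings$seed + 7L * m + as.integer(pa)
      fits[[key(m, pa)]] <- tryCatch(
        suppressWarnings(fit_mle(y, m, pa, settings = cs, init = init)),
        error = function(e) e)
    }
  }
  rows <- do.call(rbind, lapply(seq_len(m_max), function(m) {
    do.call(rbind, lapply(c(FALSE, TRUE), function(pa) {
      f <- fits[[key(m, pa)]]
      if (inherits(f, "error"))
        return(data.frame(m = m, pa = pa, n_params = n_free_params(m, pa),
                          loglik = NA_real_, AIC = NA_real_,
                          BIC = NA_real_, diverge = NA_integer_,
                          converged = FALSE))
      data.frame(m = m, pa = pa, n_params = f$n_params, loglik = f$loglik,
                 AIC = aic(f$loglik, f$n_params),
                 BIC = bic(f$loglik, f$n_params, y$n),
                 diverge = if (pa)
                   lowest_divergent_moment(f$model, r_max)$lowest_divergent
                 else NA_integer_,
                 converged = f$converged)
    }))
  }))
  rows$dAIC <- rows$AIC - min(rows$AIC, na.rm = TRUE)
  rows$dBIC <- rows$BIC - min(rows$BIC, na.rm = TRUE)
  rows$preferred_aic <- !is.na(rows$dAIC) & rows$dAIC == 0
  rows$preferred_bic <- !is.na(rows$dBIC) & rows$dBIC == 0
  structure(rows, class = c("selection_table", "data.frame"),
            fits = fits, n = y$n)
}

# extend a fitted model by one phase: the new final phase starts with
# negligible probability, small inbound and stopping rates, so the
# likelihood starts where the nested optimum left it
grow_phase <- function(model) {
  sp <- model$phases
  m <- sp$m + 1L
  nu <- c(sp$nu * (1 - 1e-4), 1e-4)
  mu <- c(sp$mu, mean(pmax(sp$mu, 0.01)))
  Q <- matrix(0, m, m)
  Q[seq_len(sp$m), seq_len(sp$m)] <- sp$Q
  Q[seq_len(sp$m), m] <- 0.01
  pa_model(phase_type(nu, mu, Q), tau = model$tau, pa = model$pa)
}

# enable PA with a negligible attachment coefficient
add_pa <- function(model) {
  pa_model(model$phases, tau = 1e-6, pa = TRUE)
}

#' @export
#' @method print selection_table
print.selection_table <- function(x, ...) {
  cat("Model selection over (phases, PA); n =", attr(x, "n"),
      "respondents\n")
  tab <- data.frame(
    `(Phases,PA)` = sprintf("(%d,%s)", x$m, ifelse(x$pa, "Yes", "No")),
    Params = x$n_params,
    logLik = formatC(x$loglik, format = "f", digits = 2),
    dAIC = formatC(x$dAIC, format = "f", digits = 2),
    dBIC = formatC(x$dBIC, format = "f", digits = 2),
    Diverge = ifelse(is.na(x$diverge), "-", x$diverge),
    check.names = FALSE)
  tab$dAIC[x$preferred_aic] <- paste0("[", tab$dAIC[x$preferred_aic], "]")
  tab$dBIC[x$preferred_bic] <- paste0("[", tab$dBIC[x$preferred_bic], "]")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Share of contacts attributable to preferential attachment
#'
#' Counterfactual: switch the attachment coefficient off (`tau = 0`) while
#' keeping the fitted phase parameters, and compare mean contacts. Returns
#' the ratio of the counterfactual mean degree to the fitted mean degree —
#' e.g. a ratio of 0.6 means removing preferential attachment would cut
#' the average number of contacts to 60% of its fitted value, attributing
#' the remaining 40% to the attachment mechanism.
#'
#' @param fit a [fit_mle()] result (or a [pa_model()]) with a convergent
#'   first moment.
#' @return The ratio in `(0, 1]`.
#' @export
pa_contribution <- function(fit) {
  model <- if (inherits(fit, "pa_fit")) fit$model else fit
  stopifnot(inherits(model, "pa_model"))
  m1 <- moment_degree(model, 1)
  if (!is.finite(m1))
    stop("the fitted model has a divergent mean degree; the contribution ",
         "ratio is undefined")
  m1_0 <- moment_degree(pa_model(model$phases, tau = 0, pa = FALSE), 1)
  m1_0 / m1
}
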