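#' Optimiser and bootstrap settings
#'
#' Controls for maximum-likelihood fitting. The likelihood surface is
#' multimodal in the phase parameters, so each fit runs simulated
#' annealing from `n_starts` random starting points (rates drawn
#' log-uniform on `[1e-3, 10]`, initial-phase probabilities uniform on the
#' simplex), each followed by a derivative-free Nelder-Mead polish; the
#' best polished optimum is returned. Bootstrap refits reuse the original
#' optimum as a warm start with a reduced budget (`boot_starts`,
#' `boot_sann_iter`).
#'
#' All randomness descends from `seed` through a fixed splitting scheme,
#' so fits, bootstrap replicates and simulated datasets are individually
#' reproducible.
#'
#' @param n_starts number of annealing starts per fit.
#' @param sann_iter simulated-annealing objective evaluations per start.
#' @param sann_temp initial annealing temperature.
#' @param polish_iter Nelder-Mead iteration cap for the polish stage.
#' @param polish_reltol Nelder-Mead relative convergence tolerance.
#' @param seed integer seed for all randomness in the fit.
#' @param B bootstrap replicate count.
#' @param boot_starts annealing starts per bootstrap refit (warm start
#'   included).
#' @param boot_sann_iter annealing evaluations per bootstrap refit start.
#' @return A list of class `"fit_settings"`.
#' @export
fit_settings <- function(n_starts = 20L, sann_iter = 20000L,
                         sann_temp = 1, polish_iter = 5000L,
                         polish_reltol = 1e-10, seed = 1L, B = 200L,
                         boot_starts = 2L, boot_sann_iter = 500L) {
  stopifnot(n_starts >= 1, B >= 1, sann_iter >= 1, boot_starts >= 1)
  structure(list(n_starts = as.integer(n_starts),
                 sann_iter = as.integer(sann_iter),
                 sann_temp = sann_temp,
                 polish_iter = as.integer(polish_iter),
                 polish_reltol = polish_reltol,
                 seed = as.integer(seed), B = as.integer(B),
                 boot_starts = as.integer(boot_starts),
                 boot_sann_iter = as.integer(boot_sann_iter)),
            class = "fit_settings")
}

# all randomness descends from one seed: stream 1 = fit starts, stream 2 =
# nonparametric bootstrap, stream 3 = parametric bootstrap, stream 4 =
# simulation helpers
derive_seeds <- function(seed, n, stream = 1L) {
  set.seed(seed)
  roots <- sample.int(2147483646L, 8L)
  set.seed(roots[stream])
  sample.int(2147483646L, n)
}

# ---- unconstrained parameterisation -----------------------------------
# layout: [log tau (if pa)] [log mu (m)] [log Q upper triangle, row-major]
# [softmax logits eta_2..eta_m for nu, eta_1 pinned at 0]

n_free_params <- function(m, pa) {
  as.integer(pa) + m + (m * (m - 1L)) %/% 2L + (m - 1L)
}

RATE_FLOOR <- 1e-8

par_pack <- function(model) {
  sp <- model$phases
  m <- sp$m
  nu <- pmax(sp$nu, 1e-12)
  c(if (model$pa) base::log(max(model$tau, RATE_FLOOR)),
    base::log(pmax(sp$mu, RATE_FLOOR)),
    if (m > 1) base::log(pmax(upper_tri_vec(sp$Q), RATE_FLOOR)),
    if (m > 1) base::log(nu[-1] / nu[1]))
}

par_unpack <- function(par, m, pa) {
  idx <- 0L
  tau <- 0
  if (pa) { tau <- exp(par[1L]); idx <- 1L }
  mu <- exp(par[idx + seq_len(m)]); idx <- idx + m
  nq <- (m * (m - 1L)) %/% 2L
  Q <- upper_tri_matrix(exp(par[idx + seq_len(nq)]), m); idx <- idx + nq
  eta <- c(0, par[idx + seq_len(m - 1L)])
  nu <- exp(eta - max(eta)); nu <- nu / sum(nu)
  pa_model(phase_type(nu, mu, Q), tau = tau, pa = pa)
}

random_start <- function(m, pa) {
  lo <- base::log(1e-3); hi <- base::log(10)
  nu <- stats::rexp(m); nu <- nu / sum(nu)            # uniform on simplex
  nu <- pmax(nu, 1e-12)
  c(if (pa) stats::runif(1, lo, hi),
    stats::runif(m, lo, hi),
    if (m > 1) stats::runif((m * (m - 1L)) %/% 2L, lo, hi),
    if (m > 1) base::log(nu[-1] / nu[1]))
}

polish_optim <- function(par, obj, settings) {
  if (length(par) == 1L)
    stats::optim(par, obj, method = "Brent", lower = -30, upper = 10)
  else
    stats::optim(par, obj, method = "Nelder-Mead",
                 control = list(maxit = settings$polish_iter,
                                reltol = settings$polish_reltol))
}

#' Maximum-likelihood fit of a contact-formation model
#'
#' Maximises the zero-truncated multinomial log-likelihood of the observed
#' contact counts over the parameters of an `m`-phase model, with or
#' without preferential attachment. Optimisation works in an unconstrained
#' space (log rates; softmax for the initial-phase probabilities with the
#' first logit pinned at zero) via multi-start simulated annealing plus
#' Nelder-Mead polish; see [fit_settings()]. The solver truncation is the
#' largest observed degree. Parameter values that make an observed degree
#' impossible score a large penalty rather than erroring, so the annealer
#' can move away from them.
#'
#' @param y a [degree_counts()] object.
#' @param m number of phases.
#' @param pa logical; estimate the attachment coefficient?
#' @param settings a [fit_settings()] list.
#' @param init optional list of warm starts, each a `pa_model` (matching
#'   `m` and `pa`) or an unconstrained parameter vector; used in addition
#'   to (and before) the random starts, within the same total `n_starts`.
#' @return An object of class `"pa_fit"`: list with `model` (the fitted
#'   [pa_model()]), `loglik`, `n_params`, `converged`, `ci` (`NULL` until
#'   [bootstrap_ci()] is run), the data `y`, `settings` and the optimal
#'   unconstrained parameter vector `par`.
#' @examples
#' y <- simulate_counts(pa_model(phase_type(1, 0.2), pa = FALSE), 500,
#'                      seed = 1)
#' fit_mle(y, m = 1, pa = FALSE,
#'         settings = fit_settings(n_starts = 2, sann_iter = 200))
#' @export
fit_mle <- function(y, m, pa, settings = fit_settings(), init = NULL) {
  stopifnot(inherits(y, "degree_counts"), m >= 1, m == round(m))
  if (y$n < 1) stop("no respondents in the data")
  m <- as.integer(m)
  kmax <- max(y$degree)
  obj <- function(par) cpp_negloglik(par, m, pa, y$degree,
                                     as.numeric(y$count), kmax)
  npar <- n_free_params(m, pa)

  starts <- list()
  if (!is.null(init)) {
    starts <- lapply(init, function(ini) {
      if (inherits(ini, "pa_model")) {
        if (ini$phases$m != m || ini$pa != pa)
          stop("warm start does not match the requested (m, pa)")
        par_pack(ini)
      } else {
        if (length(ini) != npar) stop("warm start has wrong length")
        as.numeric(ini)
      }
    })
  }
  seeds <- derive_seeds(settings$seed, settings$n_starts + 1L, stream = 1L)
  for (i in seq_len(max(0L, settings$n_starts - length(starts)))) {
    set.seed(seeds[i])
    starts[[length(starts) + 1L]] <- random_start(m, pa)
  }

  best <- NULL
  set.seed(seeds[settings$n_starts + 1L])  # SANN proposal randomness
  for (par0 in starts) {
    r1 <- stats::optim(par0, obj, method = "SANN",
                       control = list(maxit = settings$sann_iter,
                                      temp = settings$sann_temp))
    r2 <- polish_optim(r1$par, obj, settings)
    if (is.null(best) || r2$value < best$value) best <- r2
  }
  converged <- best$value < 1e11 &&
    (length(best$par) == 1L || best$convergence == 0L)
  if (!converged)
    warning("fit did not converge cleanly (m = ", m, ", pa = ", pa, ")")
  structure(list(model = par_unpack(best$par, m, pa),
                 loglik = -best$value,
                 n_params = npar,
                 converged = converged,
                 ci = NULL,
                 y = y,
                 settings = settings,
                 par = best$par),
            class = "pa_fit")
}

#' @export
#' @method print pa_fit
print.pa_fit <- function(x, ...) {
  cat("Maximum-likelihood fit (", x$model$phases$m, " phase",
      if (x$model$phases$m > 1) "s", ", ",
      if (x$model$pa) "PA" else "no PA", ")\n", sep = "")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      " parameters:", x$n_params,
      " converged:", x$converged, "\n")
  if (x$model$pa) cat("  tau-hat:", format(x$model$tau, digits = 4), "\n")
  if (!is.null(x$ci)) {
    cat("  bootstrap 95% CIs (B = ", x$ci$B, "):\n", sep = "")
    print(round(x$ci$ci, 4))
  }
  invisible(x)
}

# named natural-scale parameter vector for reporting
param_vector <- function(model) {
  sp <- model$phases
  m <- sp$m
  out <- c(tau = model$tau,
           stats::setNames(sp$mu, paste0("mu", seq_len(m))))
  if (m > 1) {
    ij <- which(upper.tri(sp$Q), arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
    out <- c(out, stats::setNames(sp$Q[ij],
                                  paste0("Q", ij[, 1], ".", ij[, 2])))
  }
  c(out, stats::setNames(sp$nu, paste0("nu", seq_len(m))))
}

refit_once <- function(y, m, pa, settings, warm_par) {
  boot_settings <- settings
  boot_settings$n_starts <- settings$boot_starts
  boot_settings$sann_iter <- settings$boot_sann_iter
  fit_mle(y, m, pa, settings = boot_settings, init = list(warm_par))
}

#' Nonparametric bootstrap confidence intervals
#'
#' Resamples the `n` respondents' degrees with replacement `B` times,
#' refits the model to each resample (warm-started at the original
#' optimum), and returns percentile intervals for every natural-scale
#' parameter. Phase labels are only weakly ordered by the triangular
#' transition structure, so multi-phase parameter intervals should be read
#' with label switching in mind; the attachment coefficient `tau` is not
#' affected.
#'
#' @inheritParams fit_mle
#' @param fit optional existing [fit_mle()] result for `(y, m, pa)`; fitted
#'   afresh when omitted.
#' @param level confidence level.
#' @return A list of class `"pa_boot"`: `estimate` (named vector), `ci`
#'   (matrix with `lower`/`upper` columns), `replicates` (`B` x n-params
#'   matrix), `B`, `level`, and `failed` (indices of replicates whose refit
#'   did not converge; their estimates are still included).
#' @export
bootstrap_ci <- function(y, m, pa, settings = fit_settings(), fit = NULL,
                         level = 0.95) {
  if (is.null(fit)) fit <- fit_mle(y, m, pa, settings)
  raw <- expand_degrees(y)
  seeds <- derive_seeds(settings$seed, settings$B, stream = 2L)
  est <- param_vector(fit$model)
  reps <- matrix(NA_real_, settings$B, length(est),
                 dimnames = list(NULL, names(est)))
  failed <- integer(0)
  for (b in seq_len(settings$B)) {
    set.seed(seeds[b])
    yb <- degree_counts(sample(raw, length(raw), replace = TRUE))
    bs <- settings; bs$seed <- seeds[b]
    fb <- tryCatch(refit_once(yb, m, pa, bs, fit$par),
                   warning = function(w) {
                     failed <<- c(failed, b)
                     suppressWarnings(refit_once(yb, m, pa, bs, fit$par))
                   })
    reps[b, ] <- param_vector(fb$model)
  }
  alpha <- (1 - level) / 2
  ci <- t(apply(reps, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE))
  colnames(ci) <- c("lower", "upper")
  structure(list(estimate = est, ci = ci, replicates = reps,
                 B = settings$B, level = level, failed = failed),
            class = "pa_boot")
}

#' @export
#' @method print pa_boot
print.pa_boot <- function(x, ...) {
  cat("Nonparametric bootstrap (B = ", x$B, ", level = ", x$level,
      ")\n", sep = "")
  print(cbind(estimate = round(x$estimate, 5), round(x$ci, 5)))
  if (length(x$failed))
    cat("  replicates with non-converged refits:", length(x$failed), "\n")
  invisible(x)
}

#' Parametric bootstrap envelope for the predicted degree distribution
#'
#' Simulates `B` datasets from the fitted model, refits each, and returns
#' the pointwise envelope of the refitted zero-truncated pmfs over degrees
#' `0..kmax` — the uncertainty band to draw around the model's predicted
#' degree distribution.
#'
#' @param fit a [fit_mle()] result.
#' @param n number of individuals per simulated dataset (pre-censoring);
#'   defaults to the respondent count of the fitted data.
#' @param B number of parametric replicates; defaults to the fit settings.
#' @param settings optimiser settings for the refits.
#' @param kmax degree grid upper end; defaults to the largest degree
#'   observed in the fitted data.
#' @return A list of class `"pa_band"`: `k` (degree grid), `point`
#'   (fitted-model pmf), `lower`/`upper` (pointwise envelope), `pmfs`
#'   (`B` x (kmax+1) matrix), `B`.
#' @export
parametric_bootstrap_band <- function(fit, n = fit$y$n, B = NULL,
                                      settings = fit$settings,
                                      kmax = max(fit$y$degree)) {
  stopifnot(inherits(fit, "pa_fit"))
  if (is.null(B)) B <- settings$B
  m <- fit$model$phases$m
  pa <- fit$model$pa
  seeds <- derive_seeds(settings$seed, B, stream = 3L)
  point <- censor_zero(degree_pmf(fit$model, kmax = kmax,
                                  tail_warn = Inf))$d
  pmfs <- matrix(NA_real_, B, kmax + 1L)
  for (b in seq_len(B)) {
    yb <- simulate_counts(fit$model, n, seed = seeds[b])
    bs <- settings; bs$seed <- seeds[b]
    fb <- suppressWarnings(refit_once(yb, m, pa, bs, fit$par))
    db <- censor_zero(degree_pmf(fb$model, kmax = kmax,
                                 tail_warn = Inf))$d
    pmfs[b, ] <- db
  }
  structure(list(k = 0:kmax, point = point,
                 lower = apply(pmfs, 2, min),
                 upper = apply(pmfs, 2, max),
                 pmfs = pmfs, B = B),
            class = "pa_band")
}

#' @export
#' @method print pa_band
print.pa_band <- function(x, ...) {
  cat("Parametric bootstrap pmf envelope (B = ", x$B, ", degrees 0..",
      max(x$k), ")\n", sep = "")
  invisible(x)
}
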