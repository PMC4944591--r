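#' Observed contact-count data
#'
#' Tabulated survey degrees: `count[i]` respondents reported `degree[i]`
#' contacts. Zero degrees are not allowed — respondents reporting no
#' contacts are censored from such surveys, and the likelihood is
#' zero-truncated to match.
#'
#' @param degrees either a vector of raw per-respondent degrees (positive
#'   integers, one per respondent) or, with `counts` supplied, the distinct
#'   degree values.
#' @param counts optional vector of respondent counts aligned with
#'   `degrees`.
#' @return An object of class `"degree_counts"`: list with sorted `degree`,
#'   `count` and the total respondent count `n`.
#' @examples
#' degree_counts(c(1, 1, 2, 5))
#' degree_counts(degrees = c(1, 2), counts = c(3, 1))
#' @export
degree_counts <- function(degrees, counts = NULL) {
  if (is.null(counts)) {
    tab <- table(degrees)
    degrees <- as.integer(names(tab))
    counts <- as.integer(tab)
  }
  degrees <- as.integer(degrees)
  counts <- as.integer(counts)
  if (length(degrees) != length(counts))
    stop("'degrees' and 'counts' must have the same length")
  if (any(is.na(degrees)) || any(degrees != round(degrees)))
    stop("degrees must be integers")
  if (any(degrees == 0))
    stop("degree 0 found: zero-contact respondents are censored and must ",
         "not appear in the data")
  if (any(degrees < 0)) stop("degrees must be positive")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative integers")
  keep <- counts > 0
  degrees <- degrees[keep]; counts <- counts[keep]
  if (anyDuplicated(degrees)) {
    counts <- as.integer(tapply(counts, degrees, sum))
    degrees <- sort(unique(degrees))
  }
  o <- order(degrees)
  structure(list(degree = degrees[o], count = counts[o],
                 n = sum(counts)),
            class = "degree_counts")
}

#' @export
#' @method print degree_counts
print.degree_counts <- function(x, ...) {
  cat("Contact-count data: n =", x$n, "respondents,",
      length(x$degree), "distinct degrees, max degree", max(x$degree),
      "\n")
  invisible(x)
}

#' @export
as.data.frame.degree_counts <- function(x, ...) {
  data.frame(degree = x$degree, count = x$count)
}

# one raw degree per respondent
expand_degrees <- function(y) rep(y$degree, y$count)

#' Zero-truncated multinomial log-likelihood
#'
#' Log-likelihood of observed contact counts under a contact-formation
#' model: `sum_k y_k log d~_k`, with `d~` the zero-truncated model pmf.
#' The multinomial combinatorial factor depends only on the data and is
#' dropped. Returns `-Inf` when the model assigns zero probability to an
#' observed degree.
#'
#' @param model a [pa_model()].
#' @param y a [degree_counts()] object.
#' @param kmax solver truncation; defaults to the largest observed degree.
#' @return The log-likelihood (constant term dropped).
#' @examples
#' y <- degree_counts(degrees = c(1, 2), counts = c(3, 1))
#' log_likelihood(pa_model(phase_type(1, 1), pa = FALSE), y)
#' @export
log_likelihood <- function(model, y, kmax = max(y$degree)) {
  stopifnot(inherits(model, "pa_model"), inherits(y, "degree_counts"))
  if (kmax < max(y$degree))
    stop("'kmax' is below the largest observed degree")
  dist <- censor_zero(degree_pmf(model, kmax = kmax, tail_warn = Inf))
  dk <- dist$d[y$degree + 1L]
  if (any(dk <= 0)) return(-Inf)
  sum(y$count * base::log(dk))
}
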