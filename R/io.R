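#' Read contact-count data from a text file
#'
#' Two dialects are accepted, matching how survey extracts circulate:
#' a CSV with header `degree,count`, or a raw file with one positive
#' integer degree per respondent per line. With `format = "auto"` the
#' dialect is detected by sniffing the first line for the header. Zero
#' degrees are rejected in both dialects: zero-contact respondents are
#' censored from the data these models are fitted to, and the likelihood
#' is zero-truncated accordingly.
#'
#' @param path file path.
#' @param format `"auto"`, `"counts"` (CSV) or `"raw"`.
#' @return A [degree_counts()] object.
#' @export
read_counts <- function(path, format = c("auto", "counts", "raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty input file: ", path)
  if (format == "auto")
    format <- if (grepl("^\\s*degree\\s*,\\s*count\\s*$", lines[1],
                        ignore.case = TRUE)) "counts" else "raw"
  if (format == "counts") {
    if (grepl("^\\s*degree", lines[1], ignore.case = TRUE))
      lines <- lines[-1]
    parts <- strsplit(lines, ",")
    bad <- which(vapply(parts, length, 0L) != 2L |
                   vapply(parts, function(p)
                     anyNA(suppressWarnings(as.numeric(p))), TRUE))
    if (length(bad))
      stop("malformed degree,count line(s): ",
           paste(bad + 1L, collapse = ", "), " in ", path)
    deg <- as.numeric(vapply(parts, `[[`, "", 1L))
    cnt <- as.numeric(vapply(parts, `[[`, "", 2L))
    if (any(deg != round(deg) | deg < 0) ||
        any(cnt != round(cnt) | cnt < 0))
      stop("degrees and counts must be non-negative integers")
    if (any(deg == 0 & cnt > 0))
      stop("degree 0 with a positive count found: zero-contact ",
           "respondents are censored and the model pmf is ",
           "zero-truncated; remove the k = 0 row")
    degree_counts(degrees = deg[cnt > 0], counts = cnt[cnt > 0])
  } else {
    val <- suppressWarnings(as.numeric(lines))
    bad <- which(is.na(val) | val != round(val) | val < 0)
    if (length(bad))
      stop("malformed degree line(s): ", paste(bad, collapse = ", "),
           " in ", path)
    if (any(val == 0))
      stop("degree 0 found on line(s) ",
           paste(which(val == 0), collapse = ", "),
           ": zero-contact respondents are censored and the model pmf ",
           "is zero-truncated")
    degree_counts(val)
  }
}

#' Write contact-count data as degree,count CSV
#'
#' Canonical serialisation: header `degree,count`, one sorted row per
#' distinct degree. `read_counts()` followed by `write_counts()` is
#' byte-identical for files already in this form.
#'
#' @param y a [degree_counts()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(y, path) {
  stopifnot(inherits(y, "degree_counts"))
  writeLines(c("degree,count", paste0(y$degree, ",", y$count)), path)
  invisible(path)
}

report_meta <- function(seed, settings = NULL) {
  meta <- list(package = "patest",
               version = as.character(utils::packageVersion("patest")),
               seed = seed)
  if (!is.null(settings)) meta$settings <- unclass(settings)
  meta
}

write_report <- function(report, out, schema) {
  validate_report(report, schema)
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(report)
}

#' Validate a JSON report against a shipped schema
#'
#' Each report the package writes (`fit`, `select`, `simulate`,
#' `diagnose`) has a minimal JSON schema under
#' `system.file("schema", package = "patest")` listing its required
#' fields and their types. This checks a report (an R list, or a path to
#' a JSON file) against the named schema and errors on missing fields or
#' type mismatches.
#'
#' @param report list or path to a JSON file.
#' @param schema one of `"fit"`, `"select"`, `"simulate"`, `"diagnose"`.
#' @return `TRUE`, invisibly, if valid.
#' @export
validate_report <- function(report,
                            schema = c("fit", "select", "simulate",
                                       "diagnose")) {
  schema <- match.arg(schema)
  if (is.character(report) && length(report) == 1L)
    report <- jsonlite::read_json(report, simplifyVector = FALSE)
  sch <- jsonlite::read_json(system.file("schema",
                                         paste0(schema, ".json"),
                                         package = "patest"),
                             simplifyVector = FALSE)
  missing <- setdiff(unlist(sch$required), names(report))
  if (length(missing))
    stop("report is missing required field(s): ",
         paste(missing, collapse = ", "))
  for (fld in names(sch$properties)) {
    if (is.null(report[[fld]])) next
    want <- sch$properties[[fld]]$type
    got <- report[[fld]]
    ok <- switch(want,
                 number = is.numeric(got) ||
                   (is.list(got) && all(vapply(got, is.numeric, TRUE))),
                 integer = is.numeric(got),
                 string = is.character(got),
                 boolean = is.logical(got),
                 object = is.list(got),
                 array = is.list(got) || is.vector(got),
                 TRUE)
    if (!ok)
      stop("report field '", fld, "' should have JSON type '", want, "'")
  }
  invisible(TRUE)
}

model_to_list <- function(model) {
  sp <- model$phases
  list(m = sp$m, pa = model$pa, tau = model$tau, nu = sp$nu, mu = sp$mu,
       Q = upper_tri_vec(sp$Q))
}

list_to_model <- function(x) {
  pa_model(phase_type(unlist(x$nu), unlist(x$mu),
                      upper_tri_matrix(unlist(x$Q), x$m)),
           tau = x$tau, pa = isTRUE(x$pa))
}

#' Run a maximum-likelihood fit end to end
#'
#' Reads a contact-count file, fits the requested model, optionally adds
#' bootstrap confidence intervals, and writes a JSON report embedding the
#' seed and the full resolved settings so the run can be replayed.
#'
#' @param input path to a contact-count file (see [read_counts()]).
#' @param m number of phases.
#' @param pa fit preferential attachment?
#' @param settings a [fit_settings()] list.
#' @param bootstrap number of bootstrap replicates for CIs, or 0 for none
#'   (overrides `settings$B` when positive).
#' @param out optional path for the JSON report.
#' @return The report list, invisibly. The `"fit"` attribute carries the
#'   [fit_mle()] object.
#' @export
run_fit <- function(input, m, pa, settings = fit_settings(),
                    bootstrap = 0L, out = NULL) {
  y <- if (inherits(input, "degree_counts")) input else read_counts(input)
  fit <- fit_mle(y, m, pa, settings)
  report <- c(report_meta(settings$seed, settings),
              list(command = "fit", m = as.integer(m), pa = pa,
                   n = y$n,
                   estimate = as.list(param_vector(fit$model)),
                   model = model_to_list(fit$model),
                   loglik = fit$loglik, n_params = fit$n_params,
                   aic = aic(fit$loglik, fit$n_params),
                   bic = bic(fit$loglik, fit$n_params, y$n),
                   converged = fit$converged))
  if (bootstrap > 0) {
    bs <- settings; bs$B <- as.integer(bootstrap)
    bt <- bootstrap_ci(y, m, pa, bs, fit = fit)
    report$ci <- list(level = bt$level, B = bt$B,
                      lower = as.list(stats::setNames(bt$ci[, "lower"],
                                                      rownames(bt$ci))),
                      upper = as.list(stats::setNames(bt$ci[, "upper"],
                                                      rownames(bt$ci))))
    fit$ci <- bt
  }
  out_report <- write_report(report, out, "fit")
  attr(out_report, "fit") <- fit
  invisible(out_report)
}

#' Run model selection over the (phases, PA) grid
#'
#' @inheritParams run_fit
#' @param m_max largest phase count in the grid.
#' @param format `"json"` writes the report to `out`; `"text"` prints the
#'   aligned selection table as well.
#' @return The report list, invisibly, with the `"table"` attribute
#'   carrying the [selection_grid()] result.
#' @export
run_select <- function(input, m_max, settings = fit_settings(),
                       out = NULL, format = c("json", "text")) {
  format <- match.arg(format)
  y <- if (inherits(input, "degree_counts")) input else read_counts(input)
  tab <- selection_grid(y, m_max, settings)
  rows <- lapply(seq_len(nrow(tab)), function(i)
    list(m = tab$m[i], pa = tab$pa[i], n_params = tab$n_params[i],
         loglik = tab$loglik[i], aic = tab$AIC[i], bic = tab$BIC[i],
         dAIC = tab$dAIC[i], dBIC = tab$dBIC[i],
         diverge = tab$diverge[i], converged = tab$converged[i],
         preferred_aic = tab$preferred_aic[i],
         preferred_bic = tab$preferred_bic[i]))
  report <- c(report_meta(settings$seed, settings),
              list(command = "select", m_max = as.integer(m_max),
                   n = y$n, table = rows))
  if (format == "text") print(tab)
  report <- write_report(report, out, "select")
  attr(report, "table") <- tab
  invisible(report)
}

#' Simulate a dataset and write it with a provenance sidecar
#'
#' Writes the simulated counts in the same `degree,count` CSV dialect the
#' readers accept, plus a JSON sidecar (`<out>.json`) recording the model
#' parameters and seed so the dataset can be regenerated.
#'
#' @param model a [pa_model()].
#' @param n individuals to simulate (pre-censoring).
#' @param seed integer seed.
#' @param out output CSV path.
#' @param censor_zero drop zero-degree individuals (see
#'   [simulate_counts()]).
#' @return The sidecar report list, invisibly, with attribute `"counts"`.
#' @export
run_simulate <- function(model, n, seed, out, censor_zero = TRUE) {
  y <- simulate_counts(model, n, seed = seed, censor_zero = censor_zero)
  write_counts(y, out)
  report <- c(report_meta(seed),
              list(command = "simulate", n_requested = as.integer(n),
                   n = y$n, censor_zero = censor_zero,
                   model = model_to_list(model), data_file = out))
  invisible(write_report(report, paste0(out, ".json"), "simulate"))
}

#' Diagnostic report for given model parameters
#'
#' Computes the degree pmf (censored and not), the first two degree
#' moments and the moment-divergence scan for a fully specified model —
#' no data involved.
#'
#' @param model a [pa_model()].
#' @param kmax pmf truncation (`NULL` for adaptive).
#' @param r_max highest moment order scanned for divergence.
#' @param out optional path for the JSON report.
#' @return The report list, invisibly.
#' @export
run_diagnose <- function(model, kmax = NULL, r_max = 10L, out = NULL) {
  dist <- degree_pmf(model, kmax = kmax)
  div <- lowest_divergent_moment(model, r_max)
  report <- list(package = "patest",
                 version = as.character(utils::packageVersion("patest")),
                 command = "diagnose",
                 model = model_to_list(model),
                 kmax = dist$kmax, tail_mass = dist$tail_mass,
                 d = dist$d, d_censored = censor_zero(dist)$d,
                 mean_degree = moment_degree(model, 1),
                 second_moment = moment_degree(model, 2),
                 divergent_moments = which(div$per_moment),
                 lowest_divergent = div$lowest_divergent)
  # JSON has no Inf: encode divergent moments as null
  json_report <- report
  if (!is.finite(json_report$mean_degree))
    json_report$mean_degree <- NULL
  if (!is.finite(json_report$second_moment))
    json_report$second_moment <- NULL
  write_report(json_report, out, "diagnose")
  invisible(report)
}
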