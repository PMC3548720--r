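#' Read and validate a survival table
#'
#' Reads a rectangular CSV with one row per subject: a follow-up time, a
#' 0/1 event indicator and named covariate columns.  Structural problems
#' (missing columns, non-numeric fields, non-positive times, event codes
#' outside \{0, 1\}) are errors naming the offending data line; rows with
#' missing values are dropped with a warning listing their lines.
#'
#' @param path CSV file path.
#' @param time_col,event_col column names holding the follow-up time and
#'   event indicator.
#' @param covariates covariate columns to keep (default: every other
#'   column).
#' @param time_unit unit of the time column; \code{"days"} and
#'   \code{"months"} are converted to years (\eqn{/365.25}, \eqn{/12}).
#' @return data frame with columns \code{time} (years), \code{event} and
#'   the covariates; subject and event counts are reported via
#'   \code{message()}.
#' @export
read_survival_table <- function(path, time_col = "time",
                                event_col = "event", covariates = NULL,
                                time_unit = c("years", "months", "days")) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("empty input: ", path, call. = FALSE)
  need <- c(time_col, event_col)
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(covariates))
    covariates <- setdiff(names(raw), c(need, "id"))
  miss <- setdiff(covariates, names(raw))
  if (length(miss))
    stop("missing covariate column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  keep <- c(need, covariates)
  line_no <- seq_len(nrow(raw)) + 1L        # header is line 1
  for (cn in keep) {
    v <- raw[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad))
        stop("non-numeric value in column '", cn, "' on line ",
             paste(line_no[bad], collapse = ", "), call. = FALSE)
      raw[[cn]] <- vn
    }
  }
  na_rows <- which(!stats::complete.cases(raw[keep]))
  if (length(na_rows)) {
    warning("dropping ", length(na_rows), " row(s) with missing values ",
            "(line ", paste(line_no[na_rows], collapse = ", "), ")",
            call. = FALSE)
    raw <- raw[-na_rows, , drop = FALSE]
    line_no <- line_no[-na_rows]
    if (nrow(raw) == 0) stop("no complete rows in ", path, call. = FALSE)
  }
  bad <- which(raw[[time_col]] <= 0)
  if (length(bad))
    stop("non-positive time on line ", paste(line_no[bad], collapse = ", "),
         call. = FALSE)
  bad <- which(!raw[[event_col]] %in% c(0, 1))
  if (length(bad))
    stop("event indicator outside {0,1} on line ",
         paste(line_no[bad], collapse = ", "), call. = FALSE)
  scale <- switch(time_unit, years = 1, months = 1 / 12, days = 1 / 365.25)
  out <- data.frame(time = raw[[time_col]] * scale, event = raw[[event_col]])
  out <- cbind(out, raw[covariates])
  message("read ", nrow(out), " subjects (", sum(out$event), " events) from ",
          path)
  out
}

#' Structured report of a fitted model
#'
#' Collects the fit's inference tables into a plain nested list suitable
#' for JSON serialisation: estimates, standard errors, Wald statistics,
#' p-values, hazard ratios, log-likelihood, AIC, covariance and
#' convergence diagnostics.
#'
#' @param fit a \code{\link{hypertab_ph}} fit.
#' @return a named list.
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "hypertab_ph"))
  list(
    family = fit$family,
    n = fit$n, n_events = fit$n_events,
    baseline = as.list(fit$spec$baseline),
    coefficients = as.list(fit$spec$coef),
    estimate = as.list(fit$estimate),
    se = as.list(fit$se),
    wald = as.list(fit$wald),
    p_value = as.list(fit$p_value),
    hazard_ratio = as.list(fit$hazard_ratio),
    covariance = unname(apply(fit$covariance, 1, as.list)),
    loglik = fit$loglik,
    minus_two_loglik = fit$minus_two_loglik,
    aic = fit$aic,
    n_params = fit$n_params,
    converged = fit$converged,
    se_defined = fit$se_defined,
    n_iter = fit$n_iter
  )
}

#' Write a fit report as JSON
#'
#' @inheritParams fit_report
#' @param path output file.
#' @param extra optional named list merged into the report (e.g. dynamics
#'   results).
#' @return the report list, invisibly.
#' @export
write_fit_report <- function(fit, path, extra = NULL) {
  rep <- fit_report(fit)
  if (!is.null(extra)) rep <- c(rep, extra)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(rep)
}
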