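#' Configuration for a synthetic breast-cancer-style cohort
#'
#' Describes a cohort with the covariate structure the analysis assumes: an
#' age at diagnosis (years), a binary gene-signature indicator (\code{G70};
#' 0 = good, 1 = poor prognosis), and two continuous gene-expression
#' correlation scores on \eqn{[-1, 1]} (\code{CSR}, \code{CERBB}) with
#' controllable pairwise correlation, plus two-part right censoring
#' (administrative horizon + random exponential drop-out).
#'
#' The defaults emulate a 295-patient validation-cohort design: age
#' N(45, 8\eqn{^2}) clamped to \eqn{[25, 75]}, poor-signature prevalence
#' 0.61, scores bivariate N(0, 0.2\eqn{^2}) with correlation 0.3 (kept
#' below the 0.5 pairwise-correlation screen) clamped to \eqn{[-1, 1]},
#' administrative censoring at 20 years and random censoring at rate
#' 0.02/year.
#'
#' @param n cohort size.
#' @param age_mean,age_sd age distribution (years) before clamping to
#'   \eqn{[25, 75]}.
#' @param signature_prevalence probability of a poor (\code{G70 = 1})
#'   signature.
#' @param score_mean,score_sd length-2 numeric: means and SDs of
#'   (\code{CSR}, \code{CERBB}) before clamping to \eqn{[-1, 1]}.
#' @param score_correlation correlation of the two scores, in \eqn{(-1, 1)}.
#' @param admin_horizon administrative censoring time in years
#'   (\code{Inf} disables it).
#' @param censor_rate rate (per year) of the exponential random-censoring
#'   component (0 disables it).
#' @param seed integer seed used by \code{\link{simulate_cohort}} and
#'   \code{\link{generate_covariates}}; \code{NULL} leaves the RNG state
#'   alone.
#' @return a list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n = 295, age_mean = 45, age_sd = 8,
                          signature_prevalence = 0.61,
                          score_mean = c(0, 0), score_sd = c(0.2, 0.2),
                          score_correlation = 0.3,
                          admin_horizon = 20, censor_rate = 0.02,
                          seed = NULL) {
  stopifnot(n >= 1, age_sd > 0,
            signature_prevalence >= 0, signature_prevalence <= 1,
            length(score_mean) == 2, length(score_sd) == 2,
            all(score_sd > 0),
            score_correlation > -1, score_correlation < 1,
            admin_horizon > 0, censor_rate >= 0)
  structure(list(n = as.integer(n), age_mean = age_mean, age_sd = age_sd,
                 signature_prevalence = signature_prevalence,
                 score_mean = score_mean, score_sd = score_sd,
                 score_correlation = score_correlation,
                 admin_horizon = admin_horizon, censor_rate = censor_rate,
                 seed = seed),
            class = "cohort_config")
}

#' Generating model for synthetic cohorts
#'
#' The default "truth" used by the simulation and recovery experiments: a
#' hypertabastic baseline with \eqn{\alpha = 0.7247}, \eqn{\beta = 0.6205}
#' and coefficients \eqn{\theta} = (AGE \eqn{-0.0735}, G70 1.199,
#' CSR 2.661, CERBB 1.561), i.e. the combined clinical/gene-signature
#' model the cohort design emulates.
#'
#' @return a \code{\link{ph_spec}}.
#' @export
default_truth <- function() {
  ph_spec("hypertabastic", c(alpha = 0.7247, beta = 0.6205),
          coef = c(AGE = -0.0735, G70 = 1.199, CSR = 2.661, CERBB = 1.561))
}

#' Draw the covariate matrix of a synthetic cohort
#'
#' @param config a \code{\link{cohort_config}}.
#' @param seed integer seed (default: the config's); \code{NULL} draws from
#'   the current RNG state.
#' @return data frame with columns \code{AGE}, \code{G70}, \code{CSR},
#'   \code{CERBB}.
#' @export
generate_covariates <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd), 25), 75)
  g70 <- stats::rbinom(n, 1, config$signature_prevalence)
  z <- matrix(stats::rnorm(2 * n), ncol = 2)
  rho <- config$score_correlation
  z[, 2] <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
  csr <- config$score_mean[1] + config$score_sd[1] * z[, 1]
  cerbb <- config$score_mean[2] + config$score_sd[2] * z[, 2]
  data.frame(AGE = age, G70 = g70,
             CSR = pmin(pmax(csr, -1), 1),
             CERBB = pmin(pmax(cerbb, -1), 1))
}

#' Simulate event times under a proportional-hazards truth
#'
#' Inverse-transform sampling of \eqn{S(t \mid x) = S_0(t)^{g(x)}}: for each
#' subject draw \eqn{U \sim} Uniform(0,1) and solve
#' \eqn{S_0(t)^{g(x_i)} = U}, i.e. \eqn{\log S_0(t) = \log(U)/g(x_i)},
#' worked in log space so extreme tails keep full precision.
#'
#' @param X covariate data frame/matrix whose columns include the truth's
#'   covariates.
#' @param truth a \code{\link{ph_spec}} (see \code{\link{default_truth}}).
#' @param seed integer seed; \code{NULL} draws from the current RNG state.
#' @return vector of positive event times (years).
#' @export
simulate_event_times <- function(X, truth, seed = NULL) {
  truth <- as_ph_spec(truth)
  if (!is.null(seed)) set.seed(seed)
  if (length(truth$coef)) {
    Xm <- as.matrix(as.data.frame(X)[, names(truth$coef), drop = FALSE])
    g <- relative_risk(Xm, truth$coef)
  } else g <- rep(1, if (is.null(nrow(X))) 1 else nrow(X))
  u <- stats::runif(length(g))
  log_u <- log(u) / g                     # target log S0(t)
  p <- truth$baseline
  t <- switch(truth$family,
    hypertabastic = qhypertab(log_u, p[1], p[2],
                              lower.tail = FALSE, log.p = TRUE),
    weibull = (-log_u / p[1])^(1 / p[2]),
    loglogistic = p[1] * expm1(-log_u)^(1 / p[2])
  )
  if (any(!is.finite(t)) || any(t <= 0))
    stop("event-time inversion failed", call. = FALSE)
  t
}

#' Apply two-part right censoring
#'
#' Each subject is censored at the minimum of the administrative horizon and
#' an Exponential(\code{censor_rate}) drop-out draw; the observed time is
#' the smaller of the event and censoring times.
#'
#' @param times vector of positive latent event times (years).
#' @param config a \code{\link{cohort_config}} (supplies
#'   \code{admin_horizon} and \code{censor_rate}).
#' @param seed integer seed; \code{NULL} draws from the current RNG state.
#' @return data frame with columns \code{time} (observed, years) and
#'   \code{event} (1 = event observed, 0 = censored); the realised
#'   censoring fraction is attached as \code{attr(, "censoring_fraction")}.
#' @export
apply_censoring <- function(times, config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"), all(times > 0))
  if (!is.null(seed)) set.seed(seed)
  n <- length(times)
  cens <- rep(config$admin_horizon, n)
  if (config$censor_rate > 0)
    cens <- pmin(cens, stats::rexp(n, config$censor_rate))
  out <- data.frame(time = pmin(times, cens),
                    event = as.integer(times <= cens))
  attr(out, "censoring_fraction") <- 1 - mean(out$event)
  out
}

#' Simulate a complete synthetic cohort
#'
#' Covariates, latent event times and censoring in one reproducible step:
#' the result is the survival table the fitting functions consume.
#'
#' @inheritParams generate_covariates
#' @param truth generating model, a \code{\link{ph_spec}}.
#' @return data frame with \code{time}, \code{event} and the covariate
#'   columns; censoring fraction in \code{attr(, "censoring_fraction")}.
#' @export
simulate_cohort <- function(config, truth = default_truth(),
                            seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  X <- generate_covariates(config, seed = NULL)
  tt <- simulate_event_times(X, truth, seed = NULL)
  obs <- apply_censoring(tt, config, seed = NULL)
  out <- cbind(obs, X)
  attr(out, "censoring_fraction") <- attr(obs, "censoring_fraction")
  out
}

#' Parameter-recovery experiment
#'
#' For each cohort size in \code{n_values}, simulates \code{replicates}
#' cohorts from \code{truth}, fits the matching proportional-hazards model,
#' and summarises per-parameter bias, empirical SD, RMSE, mean estimated
#' SE, 95\% Wald-interval coverage and the fraction of estimates within 3
#' estimated SE of truth.
#'
#' @param truth generating model, a \code{\link{ph_spec}}.
#' @param config a \code{\link{cohort_config}}; its \code{n} is overridden
#'   by each value of \code{n_values}.
#' @param n_values integer vector of cohort sizes.
#' @param replicates number of replicates per size (\eqn{\ge 2}).
#' @param seed integer seed controlling the whole experiment.
#' @return list with \code{summary} (one row per size \eqn{\times}
#'   parameter) and \code{replicates} (per-replicate estimates, SEs and
#'   convergence status).
#' @export
recovery_experiment <- function(truth = default_truth(),
                                config = cohort_config(),
                                n_values = c(250, 1000),
                                replicates = 50, seed = 1) {
  stopifnot(replicates >= 2)
  truth <- as_ph_spec(truth)
  true_par <- c(truth$baseline, truth$coef)
  par_names <- names(true_par)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(names(truth$coef), collapse = " + ")))
  set.seed(seed)
  rows <- list()
  for (n in n_values) {
    cfg <- config
    cfg$n <- as.integer(n)
    cfg$seed <- NULL
    for (r in seq_len(replicates)) {
      d <- simulate_cohort(cfg, truth, seed = NULL)
      fit <- tryCatch(hypertab_ph(fml, d, family = truth$family),
                      error = function(e) NULL)
      ok <- !is.null(fit) && fit$converged && fit$se_defined
      rows[[length(rows) + 1]] <- data.frame(
        n = n, replicate = r, parameter = par_names,
        truth = unname(true_par),
        estimate = if (ok) unname(fit$estimate[par_names]) else NA_real_,
        se = if (ok) unname(fit$se[par_names]) else NA_real_,
        converged = ok)
    }
  }
  reps <- do.call(rbind, rows)
  ok <- reps[reps$converged & is.finite(reps$estimate) & is.finite(reps$se), ]
  agg <- do.call(rbind, lapply(split(ok, list(ok$n, ok$parameter),
                                     drop = TRUE), function(d) {
    err <- d$estimate - d$truth
    data.frame(n = d$n[1], parameter = d$parameter[1], truth = d$truth[1],
               n_fits = nrow(d), bias = mean(err), sd = stats::sd(d$estimate),
               rmse = sqrt(mean(err^2)), mean_se = mean(d$se),
               coverage95 = mean(abs(err) <= stats::qnorm(0.975) * d$se),
               within_3se = mean(abs(err) <= 3 * d$se))
  }))
  agg <- agg[order(agg$n, match(agg$parameter, par_names)), ]
  rownames(agg) <- NULL
  list(summary = agg, replicates = reps)
}
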