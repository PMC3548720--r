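#' Fit a parametric proportional-hazards model by maximum likelihood
#'
#' Maximises the right-censored log-likelihood (\code{\link{ph_loglik}}) over
#' the two baseline parameters and the regression coefficients.  Positivity
#' of the baseline parameters is enforced by optimising on the log scale;
#' the optimiser is quasi-Newton (BFGS) started from a moment-based initial
#' guess and four deterministic perturbations of it, keeping the best
#' maximiser.  Standard errors come from the observed information: the
#' Hessian of the log-likelihood at the MLE is computed by central finite
#' differences on the unconstrained scale, inverted, and mapped to the
#' reporting (natural) scale by the delta method.
#'
#' @param formula a model formula with a \code{survival::Surv(time, event)}
#'   left-hand side and covariate terms on the right (use \code{~ 1} for a
#'   baseline-only fit).  No intercept is fitted: the baseline hazard plays
#'   that role.
#' @param data a data frame with follow-up time in years, a 0/1 event
#'   indicator and the covariates.
#' @param family baseline family, see \code{\link{ph_family}}.
#' @param init optional starting values: list with \code{baseline} (two
#'   positive values) and/or \code{coef}.
#' @param control list: \code{maxit} (default 500), \code{reltol}
#'   (default 1e-10 on the relative log-likelihood change), \code{n_start}
#'   (number of deterministic starts, default 5).
#' @return an object of class \code{"hypertab_ph"}: a list with the fitted
#'   \code{spec}, \code{loglik}, \code{minus_two_loglik}, \code{aic},
#'   \code{estimate}, \code{se}, \code{wald}, \code{p_value},
#'   \code{hazard_ratio} (covariates only), \code{covariance} (natural
#'   scale), \code{converged}, \code{n_iter}, \code{n_params}, \code{n},
#'   \code{n_events}.
#' @examples
#' set.seed(1)
#' d <- simulate_cohort(cohort_config(n = 400, seed = 1))
#' fit <- hypertab_ph(survival::Surv(time, event) ~ AGE + G70 + CSR + CERBB,
#'                    data = d)
#' summary(fit)
#' @export
hypertab_ph <- function(formula, data,
                        family = c("hypertabastic", "weibull", "loglogistic"),
                        init = NULL, control = list()) {
  fam <- ph_family(match.arg(family))
  ctl <- utils::modifyList(list(maxit = 500, reltol = 1e-10, n_start = 5),
                           control)

  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  if (!survival::is.Surv(y) || attr(y, "type") != "right")
    stop("the response must be a right-censored survival::Surv(time, event)",
         call. = FALSE)
  time <- as.numeric(y[, "time"])
  event <- as.numeric(y[, "status"])
  if (any(!is.finite(time)) || any(time <= 0))
    stop("all follow-up times must be positive", call. = FALSE)
  X <- stats::model.matrix(stats::delete.response(stats::terms(mf)), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  p <- ncol(X)
  if (length(time) < 10 || sum(event) < 1)
    stop("need at least 10 subjects and one event", call. = FALSE)
  if (p) {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0))
      stop("constant covariate(s): ", paste(colnames(X)[sds == 0],
                                            collapse = ", "), call. = FALSE)
    if (qr(cbind(X))$rank < p)
      stop("collinear covariates: design matrix is rank deficient",
           call. = FALSE)
  }

  negll <- function(par) {
    if (any(!is.finite(par)) || any(abs(par[1:2]) > 30)) return(1e10)
    bp <- exp(par[1:2])
    theta <- if (p) par[-(1:2)] else numeric(0)
    ls <- fam$logS0(time, bp)
    eta <- if (p) drop(X %*% theta) else numeric(length(time))
    d <- event == 1
    ll <- sum(exp(eta) * ls)
    if (any(d)) ll <- ll + sum(log(fam$h0(time[d], bp)) + eta[d])
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  b0 <- fam$init(time, event)
  if (!is.null(init$baseline)) b0 <- as.numeric(init$baseline)
  th0 <- rep(0, p)
  if (!is.null(init$coef)) th0 <- as.numeric(init$coef)
  base_par <- c(log(b0), th0)

  ## deterministic perturbations of the moment-based start (log-baseline only)
  shifts <- rbind(c(0, 0), c(0.7, 0), c(-0.7, 0), c(0, 0.5), c(0, -0.5),
                  c(0.7, 0.5), c(-0.7, -0.5))
  shifts <- shifts[seq_len(min(nrow(shifts), max(1, ctl$n_start))), ,
                   drop = FALSE]

  best <- NULL
  for (s in seq_len(nrow(shifts))) {
    start <- base_par
    start[1:2] <- start[1:2] + shifts[s, ]
    probe <- stats::optim(start, negll, method = "BFGS",
                          control = list(maxit = 25, reltol = 1e-5))
    if (is.null(best) || probe$value < best$value) best <- probe
  }
  opt <- stats::optim(best$par, negll, method = "BFGS",
                      control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  polish <- stats::optim(opt$par, negll, method = "Nelder-Mead",
                         control = list(maxit = 800,
                                        reltol = ctl$reltol))
  if (polish$value < opt$value) opt <- polish
  converged <- opt$convergence == 0 && is.finite(opt$value)

  par_hat <- opt$par
  bp_hat <- exp(par_hat[1:2])
  theta_hat <- if (p) par_hat[-(1:2)] else numeric(0)
  names(theta_hat) <- colnames(X)
  spec <- ph_spec(fam$name, bp_hat, theta_hat)
  loglik <- -opt$value
  k <- 2 + p

  ## observed information on the unconstrained scale -> natural scale
  est <- c(bp_hat, theta_hat)
  names(est) <- c(fam$par_names, colnames(X))
  H <- tryCatch(pracma::hessian(negll, par_hat), error = function(e) NULL)
  vc <- matrix(NA_real_, k, k, dimnames = list(names(est), names(est)))
  singular <- TRUE
  if (!is.null(H) && all(is.finite(H))) {
    Vu <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vu) && all(is.finite(Vu)) && all(diag(Vu) > 0)) {
      J <- diag(c(bp_hat, rep(1, p)), nrow = k)   # d natural / d unconstrained
      vc <- J %*% Vu %*% J
      dimnames(vc) <- list(names(est), names(est))
      singular <- FALSE
    }
  }
  if (singular)
    warning("observed information is singular or indefinite; ",
            "standard errors are undefined", call. = FALSE)
  se <- sqrt(pmax(diag(vc), 0))
  wald <- wald_statistic(est, se)
  pval <- wald_p(wald)

  structure(list(
    call = match.call(), spec = spec, family = fam$name,
    estimate = est, se = se, wald = wald, p_value = pval,
    hazard_ratio = if (p) hazard_ratio(theta_hat) else numeric(0),
    covariance = vc, loglik = loglik,
    minus_two_loglik = -2 * loglik, aic = aic(loglik, k),
    converged = converged, se_defined = !singular,
    n_iter = unname(opt$counts["function"]), n_params = k,
    n = length(time), n_events = sum(event),
    time = time, event = event, X = X
  ), class = "hypertab_ph")
}

#' Wald statistic and its chi-square p-value
#'
#' \code{wald_statistic} is \eqn{(\hat\theta/\mathrm{se})^2};
#' \code{wald_p} refers it to the upper tail of \eqn{\chi^2_1}.
#'
#' @param estimate,se estimate and its standard error (\code{se > 0}).
#' @param w non-negative Wald statistic.
#' @return numeric vector.
#' @examples
#' wald_statistic(0.6205, 0.1244)   # ~24.88
#' wald_p(wald_statistic(0.7247, 0.2888))
#' @export
wald_statistic <- function(estimate, se) {
  out <- (estimate / se)^2
  out[!is.na(se) & se <= 0] <- NaN
  out
}

#' @rdname wald_statistic
#' @export
wald_p <- function(w) stats::pchisq(w, df = 1, lower.tail = FALSE)

#' Hazard ratio of a log-hazard coefficient
#'
#' @param estimate coefficient(s) \eqn{\theta_k}.
#' @return \eqn{\exp(\theta_k)}.
#' @export
hazard_ratio <- function(estimate) exp(estimate)

#' Akaike information criterion
#'
#' @param loglik maximised log-likelihood.
#' @param n_params number of free parameters.
#' @return \eqn{-2\ell + 2k}.
#' @export
aic <- function(loglik, n_params) {
  stopifnot(n_params >= 1)
  -2 * loglik + 2 * n_params
}

#' @export
print.hypertab_ph <- function(x, ...) {
  cat("Proportional-hazards fit,", x$family, "baseline\n")
  cat("  n =", x$n, " events =", x$n_events,
      " logLik =", format(x$loglik, digits = 7),
      " AIC =", format(x$aic, digits = 7), "\n")
  if (!x$converged) cat("  WARNING: optimiser did not converge\n")
  print(summary(x)$table, digits = 4)
  invisible(x)
}

#' @export
summary.hypertab_ph <- function(object, ...) {
  p <- length(object$spec$coef)
  hr <- c(rep(NA_real_, 2), if (p) object$hazard_ratio)
  tab <- data.frame(
    Estimate = object$estimate,
    `Std.Err` = object$se,
    Wald = object$wald,
    `p.value` = object$p_value,
    `Hazard.ratio` = hr,
    row.names = names(object$estimate), check.names = FALSE
  )
  out <- list(family = object$family, table = tab,
              loglik = object$loglik,
              minus_two_loglik = object$minus_two_loglik,
              aic = object$aic, n = object$n, n_events = object$n_events,
              converged = object$converged)
  class(out) <- "summary.hypertab_ph"
  out
}

#' @export
print.summary.hypertab_ph <- function(x, ...) {
  cat("Family:", x$family, "  n =", x$n, " events =", x$n_events, "\n")
  cat("-2 logLik =", format(x$minus_two_loglik, digits = 7),
      "  AIC =", format(x$aic, digits = 7), "\n\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' @export
coef.hypertab_ph <- function(object, ...) object$estimate

#' @export
vcov.hypertab_ph <- function(object, ...) object$covariance

#' @export
logLik.hypertab_ph <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' @export
nobs.hypertab_ph <- function(object, ...) object$n

#' Compare baseline families on one data set
#'
#' Fits each requested family (with the formula's covariates, and again with
#' no covariates) and tabulates \eqn{-2\log L}, AIC and convergence status,
#' ranked by AIC.  A family that fails outright is kept in the table with
#' \code{converged = FALSE} and \code{NA} scores rather than dropped.
#'
#' @inheritParams hypertab_ph
#' @param families character vector of baseline families to compare.
#' @return a data frame with one row per family: \code{family},
#'   \code{minus_two_loglik}, \code{aic}, \code{n_params},
#'   \code{minus_two_loglik_null} (no covariates), \code{converged}; sorted
#'   by \code{aic}.  The fitted models are attached as
#'   \code{attr(, "fits")}.
#' @export
compare_models <- function(formula, data,
                           families = c("hypertabastic", "weibull",
                                        "loglogistic")) {
  fits <- list()
  rows <- lapply(families, function(f) {
    fit <- tryCatch(hypertab_ph(formula, data, family = f),
                    error = function(e) e)
    null_fit <- tryCatch(
      hypertab_ph(stats::update(formula, . ~ 1), data, family = f),
      error = function(e) NULL)
    if (inherits(fit, "error")) {
      data.frame(family = f, minus_two_loglik = NA_real_, aic = NA_real_,
                 n_params = NA_integer_,
                 minus_two_loglik_null = NA_real_, converged = FALSE)
    } else {
      fits[[f]] <<- fit
      data.frame(family = f, minus_two_loglik = fit$minus_two_loglik,
                 aic = fit$aic, n_params = fit$n_params,
                 minus_two_loglik_null =
                   if (is.null(null_fit)) NA_real_
                   else null_fit$minus_two_loglik,
                 converged = fit$converged)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$aic, na.last = TRUE), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Forward covariate selection with a pairwise-correlation screen
#'
#' Standard stepwise forward selection: at each step every remaining
#' candidate is screened against the already-included covariates (a
#' candidate whose absolute Pearson correlation with any included covariate
#' is at or above \code{correlation_cap} is skipped), each surviving
#' candidate is added provisionally, and the one with the smallest Wald
#' p-value is entered if that p-value is below \code{p_enter} (ties broken
#' by smaller AIC).  Selection stops when no candidate qualifies.
#'
#' @inheritParams hypertab_ph
#' @param time_col,event_col names of the time and event columns in
#'   \code{data}.
#' @param candidates character vector of candidate covariate columns.
#' @param correlation_cap exclude candidates correlated at or above this
#'   absolute value with an included covariate (default 0.5; a value above 1
#'   disables the screen).
#' @param p_enter Wald p-value entry threshold (default 0.05).
#' @return list with \code{trace} (one row per examined step: candidate,
#'   action, p-value, AIC, screened-against variable if any) and \code{fit},
#'   the final model (baseline-only if nothing enters).
#' @export
forward_select <- function(data, candidates, time_col = "time",
                           event_col = "event",
                           family = "hypertabastic",
                           correlation_cap = 0.5, p_enter = 0.05) {
  stopifnot(all(candidates %in% names(data)))
  included <- character(0)
  trace <- list()
  fml <- function(vars) {
    rhs <- if (length(vars)) paste(vars, collapse = " + ") else "1"
    stats::as.formula(paste0("survival::Surv(", time_col, ", ", event_col,
                             ") ~ ", rhs))
  }
  repeat {
    pool <- setdiff(candidates, included)
    if (!length(pool)) break
    step <- lapply(pool, function(v) {
      if (length(included)) {
        r <- abs(stats::cor(data[[v]], data[, included, drop = FALSE]))
        if (any(r >= correlation_cap)) {
          return(data.frame(candidate = v, action = "screened",
                            p_value = NA_real_, aic = NA_real_,
                            against = included[which.max(r)]))
        }
      }
      fit <- tryCatch(hypertab_ph(fml(c(included, v)), data, family = family),
                      error = function(e) NULL)
      if (is.null(fit))
        return(data.frame(candidate = v, action = "failed",
                          p_value = NA_real_, aic = NA_real_,
                          against = NA_character_))
      data.frame(candidate = v, action = "tested",
                 p_value = unname(fit$p_value[v]), aic = fit$aic,
                 against = NA_character_)
    })
    step <- do.call(rbind, step)
    ok <- step$action == "tested" & !is.na(step$p_value) &
      step$p_value < p_enter
    if (!any(ok)) {
      step$entered <- FALSE
      trace[[length(trace) + 1]] <- step
      break
    }
    cand <- step[ok, ]
    cand <- cand[order(cand$p_value, cand$aic), ]
    step$entered <- step$candidate == cand$candidate[1]
    trace[[length(trace) + 1]] <- step
    included <- c(included, cand$candidate[1])
  }
  final <- hypertab_ph(fml(included), data, family = family)
  list(included = included,
       trace = if (length(trace)) do.call(rbind, trace) else NULL,
       fit = final)
}
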