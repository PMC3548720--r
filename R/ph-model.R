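#' Baseline families for proportional-hazards fitting
#'
#' The package fits the proportional-hazards model
#' \deqn{h(t \mid x) = h_0(t)\, g(x \mid \theta), \qquad
#'       S(t \mid x) = S_0(t)^{g(x \mid \theta)},}
#' with \eqn{g(x \mid \theta) = \exp(\sum_k \theta_k x_k)} and one of three
#' parametric baselines:
#' \describe{
#'   \item{hypertabastic}{\eqn{h_0, S_0} as in \code{\link{hhypertab}},
#'     parameters \code{alpha}, \code{beta}.}
#'   \item{weibull}{\eqn{h_0(t) = \lambda k t^{k-1}}, parameters
#'     \code{lambda} (rate) and \code{k} (shape); \eqn{k = 1} is the
#'     exponential model.}
#'   \item{loglogistic}{\eqn{h_0(t) = (k/\lambda)(t/\lambda)^{k-1} /
#'     [1 + (t/\lambda)^k]}, parameters \code{lambda} (scale) and \code{k}
#'     (shape), used directly inside the PH form.}
#' }
#'
#' @param family one of \code{"hypertabastic"}, \code{"weibull"},
#'   \code{"loglogistic"} (partial matching allowed).
#' @return an internal family descriptor list with elements \code{name},
#'   \code{par_names}, \code{h0(t, p)}, \code{logS0(t, p)} and
#'   \code{init(time, event)}.
#' @keywords internal
ph_family <- function(family = c("hypertabastic", "weibull", "loglogistic")) {
  family <- match.arg(family)
  switch(family,
    hypertabastic = list(
      name = "hypertabastic",
      par_names = c("alpha", "beta"),
      h0 = function(t, p) hhypertab(t, unname(p[1]), unname(p[2])),
      logS0 = function(t, p)
        phypertab(t, unname(p[1]), unname(p[2]),
                  lower.tail = FALSE, log.p = TRUE),
      init = function(time, event) {
        tm <- stats::median(time[event == 1])
        if (!is.finite(tm) || tm <= 0) tm <- stats::median(time)
        ## beta = 1, alpha from S0(tm) = 0.5: |W| = acosh(2)
        x <- max(tm, 1e-3)
        a0 <- acosh(2) / max(x * cosh(x) / sinh(x) - 1, 1e-8)
        c(alpha = a0, beta = 1)
      }
    ),
    weibull = list(
      name = "weibull",
      par_names = c("lambda", "k"),
      h0 = function(t, p) unname(p[1] * p[2]) * t^unname(p[2] - 1),
      logS0 = function(t, p) -unname(p[1]) * t^unname(p[2]),
      init = function(time, event)
        c(lambda = max(sum(event), 1) / sum(time), k = 1)
    ),
    loglogistic = list(
      name = "loglogistic",
      par_names = c("lambda", "k"),
      h0 = function(t, p) {
        p <- unname(p)
        z <- (t / p[1])^p[2]
        (p[2] / p[1]) * (t / p[1])^(p[2] - 1) / (1 + z)
      },
      logS0 = function(t, p) -log1p((t / unname(p[1]))^unname(p[2])),
      init = function(time, event) {
        tm <- stats::median(time[event == 1])
        if (!is.finite(tm) || tm <= 0) tm <- stats::median(time)
        c(lambda = tm, k = 1)
      }
    )
  )
}

#' Construct a proportional-hazards model specification
#'
#' Bundles a baseline family, its two positive baseline parameters and the
#' named regression coefficients into an object the dynamics functions
#' (velocities, extrema, conditional survival, surfaces) can evaluate.
#' Fitted models (\code{\link{hypertab_ph}}) carry one in \code{$spec}.
#'
#' @inheritParams ph_family
#' @param baseline numeric vector of the two baseline parameters, in family
#'   order (\code{alpha}, \code{beta} for the hypertabastic family).
#' @param coef named numeric vector of log-hazard-ratio coefficients
#'   \eqn{\theta}; may be empty for a baseline-only model.
#' @return an object of class \code{"ph_spec"}.
#' @examples
#' spec <- ph_spec("hypertabastic", c(alpha = 0.7247, beta = 0.6205),
#'                 coef = c(AGE = -0.0735, G70 = 1.199,
#'                          CSR = 2.661, CERBB = 1.561))
#' ph_survival(spec, t = 10, profile = c(AGE = 45, G70 = 0, CSR = 0, CERBB = 0))
#' @export
ph_spec <- function(family, baseline, coef = numeric(0)) {
  fam <- ph_family(family)
  baseline <- as.numeric(baseline)
  if (length(baseline) != 2 || any(!is.finite(baseline)) || any(baseline <= 0))
    stop("'baseline' must be two positive parameters", call. = FALSE)
  names(baseline) <- fam$par_names
  coef <- unlist(coef)
  if (length(coef) && (is.null(names(coef)) || anyDuplicated(names(coef)) ||
                       any(!nzchar(names(coef)))))
    stop("'coef' must have unique non-empty names", call. = FALSE)
  structure(list(family = fam$name, baseline = baseline,
                 coef = coef, .fam = fam),
            class = "ph_spec")
}

#' @export
print.ph_spec <- function(x, ...) {
  cat("Proportional-hazards model spec (", x$family, " baseline)\n", sep = "")
  cat("  baseline:", paste(names(x$baseline), "=",
                           signif(x$baseline, 5), collapse = ", "), "\n")
  if (length(x$coef))
    cat("  coefficients:", paste(names(x$coef), "=",
                                 signif(x$coef, 5), collapse = ", "), "\n")
  else cat("  (no covariates)\n")
  invisible(x)
}

as_ph_spec <- function(object) {
  if (inherits(object, "ph_spec")) return(object)
  if (inherits(object, "hypertab_ph")) return(object$spec)
  stop("expected a 'ph_spec' or fitted 'hypertab_ph' model", call. = FALSE)
}

## align a covariate profile (named vector) to the spec's coefficients
align_profile <- function(spec, profile) {
  if (!length(spec$coef)) return(numeric(0))
  if (is.null(names(profile)))
    stop("'profile' must be a named covariate vector", call. = FALSE)
  missing <- setdiff(names(spec$coef), names(profile))
  if (length(missing))
    stop("profile is missing covariates: ", paste(missing, collapse = ", "),
         call. = FALSE)
  as.numeric(profile[names(spec$coef)])
}

#' Relative risk g(x | theta)
#'
#' The multiplicative hazard factor \eqn{g(x \mid \theta) =
#' \exp(\sum_k \theta_k x_k)} for a covariate vector (or matrix with one
#' row per subject).
#'
#' @param x numeric covariate vector, or matrix with one row per subject and
#'   columns aligned to \code{theta}.
#' @param theta coefficient vector.
#' @return positive relative risk(s).
#' @export
relative_risk <- function(x, theta) {
  theta <- as.numeric(theta)
  if (is.matrix(x)) {
    if (ncol(x) != length(theta))
      stop("covariate/coefficient dimension mismatch", call. = FALSE)
    return(exp(drop(x %*% theta)))
  }
  if (length(x) != length(theta))
    stop("covariate/coefficient dimension mismatch", call. = FALSE)
  exp(sum(x * theta))
}

spec_g <- function(spec, profile) {
  relative_risk(align_profile(spec, profile), spec$coef)
}

#' Survival and hazard under a proportional-hazards specification
#'
#' \code{ph_survival} evaluates \eqn{S(t \mid x) = S_0(t)^{g(x|\theta)}};
#' \code{ph_hazard} evaluates \eqn{h(t \mid x) = h_0(t) g(x|\theta)}.
#'
#' @param object a \code{\link{ph_spec}} or fitted \code{\link{hypertab_ph}}
#'   model.
#' @param t vector of times (years); non-negative for survival, strictly
#'   positive for hazard.
#' @param profile named covariate vector; may be omitted for a model without
#'   covariates.
#' @param log.p return log survival.
#' @return numeric vector along \code{t}.
#' @export
ph_survival <- function(object, t, profile = NULL, log.p = FALSE) {
  spec <- as_ph_spec(object)
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  g <- spec_g(spec, profile)
  ls <- numeric(length(t))
  pos <- t > 0
  if (any(pos)) ls[pos] <- g * spec$.fam$logS0(t[pos], spec$baseline)
  if (log.p) ls else exp(ls)
}

#' @rdname ph_survival
#' @export
ph_hazard <- function(object, t, profile = NULL) {
  spec <- as_ph_spec(object)
  if (any(t <= 0)) stop("hazard requires t > 0", call. = FALSE)
  spec_g(spec, profile) * spec$.fam$h0(t, spec$baseline)
}

#' Right-censored proportional-hazards log-likelihood
#'
#' \deqn{\ell = \sum_i \delta_i [\log h_0(t_i) + x_i'\theta] +
#'       g(x_i \mid \theta) \log S_0(t_i),}
#' the standard contribution of an event (density) or a right-censored
#' subject (survival).  Baseline quantities are evaluated in log space, so
#' the value stays finite deep into the tail.
#'
#' @inheritParams ph_survival
#' @param time positive follow-up times (years).
#' @param event 0/1 event indicators (1 = event, 0 = right-censored).
#' @param X covariate matrix, one row per subject, columns aligned to the
#'   spec's coefficients (omit for a baseline-only spec).
#' @return the log-likelihood (scalar); \code{-Inf} or \code{NaN} signals an
#'   invalid parameter region and is returned, not clamped.
#' @export
ph_loglik <- function(object, time, event, X = NULL) {
  spec <- as_ph_spec(object)
  p <- length(spec$coef)
  if (p) {
    X <- as.matrix(X)
    if (ncol(X) != p || nrow(X) != length(time))
      stop("covariate matrix does not match data/coefficients", call. = FALSE)
    eta <- drop(X %*% spec$coef)
  } else eta <- numeric(length(time))
  ls <- spec$.fam$logS0(time, spec$baseline)
  d <- event == 1
  ll <- sum(exp(eta) * ls)
  if (any(d)) ll <- ll + sum(log(spec$.fam$h0(time[d], spec$baseline)) + eta[d])
  ll
}
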