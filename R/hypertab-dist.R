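#' The hypertabastic distribution
#'
#' Density, distribution function, quantile function, hazard, cumulative
#' hazard and random generation for the hypertabastic distribution with
#' shape parameters \code{alpha} and \code{beta}.
#'
#' The survival function is
#' \deqn{S_0(t) = \mathrm{sech}\{\alpha [1 - t^\beta \coth(t^\beta)]/\beta\},}
#' the distribution function \eqn{F(t) = 1 - S_0(t)} for \eqn{t > 0} (and 0
#' for \eqn{t \le 0}), and the hazard
#' \deqn{h_0(t) = \alpha [t^{2\beta-1}\mathrm{csch}^2(t^\beta) -
#'   t^{\beta-1}\coth(t^\beta)] \tanh W(t),}
#' with \eqn{W(t) = \alpha[1 - t^\beta \coth(t^\beta)]/\beta}.  Depending on
#' \eqn{(\alpha,\beta)} the hazard can be increasing, decreasing or unimodal,
#' which is the distribution's appeal for lifetime data.  Time is measured in
#' years throughout the package.
#'
#' Evaluation is numerically stable over the whole support: near the origin
#' \eqn{1 - x\coth x} (with \eqn{x = t^\beta}) is computed from its series
#' expansion to avoid catastrophic cancellation, and in the far tail all
#' survival quantities are carried in log space so that probabilities
#' underflow gracefully rather than overflow.
#'
#' @param x,q,t vector of times (years).
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param alpha positive shape parameter \eqn{\alpha}.
#' @param beta positive shape parameter \eqn{\beta}.
#' @param log,log.p logical; if \code{TRUE}, probabilities/densities are
#'   returned (or, for \code{qhypertab}, supplied) on the log scale.
#' @param lower.tail logical; if \code{TRUE} (default) probabilities are
#'   \eqn{P(T \le t)}, otherwise \eqn{P(T > t)}.
#'
#' @return \code{dhypertab} the density, \code{phypertab} the distribution
#'   function, \code{qhypertab} the quantile function, \code{hhypertab} the
#'   hazard, \code{Hhypertab} the cumulative hazard, \code{rhypertab} random
#'   deviates.
#'
#' @examples
#' phypertab(1, alpha = 1, beta = 1)          # F(1) = 1 - sech(1 - coth 1)
#' hhypertab(1, alpha = 1, beta = 1)
#' qhypertab(0.5, alpha = 0.7247, beta = 0.6205)  # baseline median, years
#' @name hypertab-dist
NULL

## series/threshold constants for the stable kernels
.XCOTH_SMALL <- 1e-2   # switch to series for x = t^beta below this
.X_LARGE     <- 350    # beyond this coth(x) = 1, csch^2(x) = 0 in doubles

## 1 - x*coth(x) for x >= 0, computed without cancellation.
## Series: x*coth(x) = 1 + x^2/3 - x^4/45 + 2 x^6/945 - ...
one_minus_xcoth <- function(x) {
  out <- numeric(length(x))
  small <- x < .XCOTH_SMALL
  big <- x > .X_LARGE
  mid <- !small & !big
  if (any(small)) {
    x2 <- x[small]^2
    out[small] <- -x2 / 3 + x2^2 / 45 - 2 * x2^3 / 945
  }
  if (any(mid)) {
    xm <- x[mid]
    e2 <- exp(-2 * xm)
    ## coth(x) = (1 + e^{-2x}) / (1 - e^{-2x})
    out[mid] <- 1 - xm * (1 + e2) / (1 - e2)
  }
  if (any(big)) out[big] <- 1 - x[big]
  out
}

## csch^2(x), underflowing to 0 rather than NaN for large x
csch_sq <- function(x) {
  out <- numeric(length(x))
  ok <- x <= .X_LARGE
  if (any(ok)) {
    e <- exp(-x[ok])
    out[ok] <- (2 * e / (1 - e^2))^2
  }
  out
}

check_shape <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) ||
      any(!is.finite(alpha)) || any(!is.finite(beta)) ||
      any(alpha <= 0) || any(beta <= 0))
    stop("'alpha' and 'beta' must be positive and finite", call. = FALSE)
  invisible(NULL)
}

#' Hypertabastic kernel function W(t)
#'
#' \eqn{W(t) = \alpha [1 - t^\beta \coth(t^\beta)]/\beta}; non-positive and
#' non-increasing in \eqn{t}, with \eqn{W(0^+) = 0}.  Exposed because the
#' survival, hazard and log-likelihood all factor through it.
#'
#' @inheritParams hypertab-dist
#' @return numeric vector, \eqn{W(t) \le 0}.
#' @export
hypertab_w <- function(t, alpha, beta) {
  check_shape(alpha, beta)
  if (any(t < 0, na.rm = TRUE)) stop("'t' must be non-negative", call. = FALSE)
  alpha * one_minus_xcoth(t^beta) / beta
}

## log S0 = -log cosh(W).  For moderate W use cosh(W) - 1 = 2 sinh^2(W/2)
## (accurate down to W ~ 0); for large |W| use the asymptotic log-sech form.
log_sech <- function(w) {
  aw <- abs(w)
  out <- numeric(length(w))
  big <- aw > 300
  if (any(big)) out[big] <- log(2) - aw[big] - log1p(exp(-2 * aw[big]))
  if (any(!big)) out[!big] <- -log1p(2 * sinh(aw[!big] / 2)^2)
  out
}

## F = 1 - sech(W) = coshm1 / cosh, accurate near both tails
cdf_from_w <- function(w) {
  aw <- abs(w)
  out <- numeric(length(w))
  big <- aw > 300
  if (any(big)) out[big] <- 1 - 2 * exp(-aw[big]) / (1 + exp(-2 * aw[big]))
  if (any(!big)) {
    cm1 <- 2 * sinh(aw[!big] / 2)^2
    out[!big] <- cm1 / (1 + cm1)
  }
  out
}

#' @rdname hypertab-dist
#' @export
phypertab <- function(q, alpha, beta, lower.tail = TRUE, log.p = FALSE) {
  check_shape(alpha, beta)
  w <- rep(0, length(q))               # W = 0 at t <= 0
  pos <- !is.na(q) & q > 0
  if (any(pos)) w[pos] <- hypertab_w(q[pos], alpha, beta)
  w[is.na(q)] <- NA_real_
  if (!lower.tail) {
    ls <- log_sech(w)
    if (log.p) ls else exp(ls)
  } else {
    pr <- cdf_from_w(w)
    if (log.p) log(pr) else pr
  }
}

#' @rdname hypertab-dist
#' @export
hhypertab <- function(t, alpha, beta) {
  check_shape(alpha, beta)
  if (any(!is.finite(t)) || any(t <= 0))
    stop("hazard is defined for t > 0 only", call. = FALSE)
  x <- t^beta
  br <- numeric(length(t))
  small <- x < 0.05
  if (any(small)) {
    ## t^(2b-1)*csch^2(x) and t^(b-1)*coth(x) share a 1/t singularity that
    ## cancels exactly; the difference has the series below in x = t^beta
    xs <- x[small]
    br[small] <- t[small]^(2 * beta - 1) *
      (-2 / 3 + 4 * xs^2 / 45 - 4 * xs^4 / 315 + 8 * xs^6 / 4725)
  }
  if (any(!small)) {
    xb <- x[!small]
    e2 <- exp(-2 * pmin(xb, 2 * .X_LARGE))
    cothx <- (1 + e2) / (1 - e2)
    br[!small] <- t[!small]^(2 * beta - 1) * csch_sq(xb) -
      t[!small]^(beta - 1) * cothx
  }
  w <- alpha * one_minus_xcoth(x) / beta
  alpha * br * tanh(w)
}

#' @rdname hypertab-dist
#' @export
Hhypertab <- function(t, alpha, beta) {
  -phypertab(t, alpha, beta, lower.tail = FALSE, log.p = TRUE)
}

#' @rdname hypertab-dist
#' @export
dhypertab <- function(x, alpha, beta, log = FALSE) {
  check_shape(alpha, beta)
  out <- rep(-Inf, length(x))
  pos <- !is.na(x) & x > 0 & is.finite(x)
  if (any(pos)) {
    tp <- x[pos]
    out[pos] <- log(hhypertab(tp, alpha, beta)) +
      phypertab(tp, alpha, beta, lower.tail = FALSE, log.p = TRUE)
  }
  out[is.na(x)] <- NA_real_
  if (log) out else exp(out)
}

#' @rdname hypertab-dist
#' @export
qhypertab <- function(p, alpha, beta, lower.tail = TRUE, log.p = FALSE) {
  check_shape(alpha, beta)
  ## work with the log-survival target: solve log S0(t) = ls
  if (log.p) {
    ls <- if (lower.tail) log(-expm1(p)) else p
  } else {
    if (any(p < 0 | p > 1, na.rm = TRUE))
      stop("probabilities must lie in [0, 1]", call. = FALSE)
    ls <- if (lower.tail) log1p(-p) else log(p)
  }
  vapply(ls, function(target) {
    if (is.na(target)) return(NA_real_)
    if (target == 0) return(0)
    if (!is.finite(target)) return(Inf)
    f <- function(t) log_sech(hypertab_w(t, alpha, beta)) - target
    lo <- 1; hi <- 1
    while (f(lo) < 0 && lo > 1e-300) lo <- lo / 8
    while (f(hi) > 0 && hi < 1e12) hi <- hi * 8
    if (f(lo) < 0 || f(hi) > 0)
      stop("quantile bracketing failed", call. = FALSE)
    stats::uniroot(f, lower = lo, upper = hi, tol = 1e-14)$root
  }, numeric(1))
}

#' @rdname hypertab-dist
#' @export
rhypertab <- function(n, alpha, beta) {
  if (length(n) != 1 || !is.finite(n) || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  qhypertab(stats::runif(n), alpha, beta)
}
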