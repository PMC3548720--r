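#' Velocities of the survival and hazard curves
#'
#' \code{survival_velocity} is the time-derivative of the survival curve,
#' computed from the closed form \eqn{dS/dt = -h(t \mid x) S(t \mid x)}
#' (always \eqn{\le 0}).  \code{hazard_velocity} is
#' \eqn{dh/dt = g(x \mid \theta)\, h_0'(t)} with \eqn{h_0'} obtained by a
#' high-accuracy central finite difference of the baseline hazard (step
#' \eqn{10^{-5}\max(1, t)}): the baseline hazard's closed-form derivative is
#' long and error-prone, and the finite-difference error is bounded by the
#' accompanying tests.
#'
#' @inheritParams ph_survival
#' @return numeric vector along \code{t} (years\eqn{^{-1}} and
#'   years\eqn{^{-2}} respectively).
#' @export
survival_velocity <- function(object, t, profile = NULL) {
  spec <- as_ph_spec(object)
  if (any(t <= 0)) stop("velocities require t > 0", call. = FALSE)
  -ph_hazard(spec, t, profile) * ph_survival(spec, t, profile)
}

#' @rdname survival_velocity
#' @export
hazard_velocity <- function(object, t, profile = NULL) {
  spec <- as_ph_spec(object)
  if (any(t <= 0)) stop("velocities require t > 0", call. = FALSE)
  g <- spec_g(spec, profile)
  h <- 1e-5 * pmax(1, t)
  h <- pmin(h, t / 2)                    # keep the stencil inside t > 0
  d <- (spec$.fam$h0(t + h, spec$baseline) -
          spec$.fam$h0(t - h, spec$baseline)) / (2 * h)
  g * d
}

## dense log-spaced scan + golden-section refinement of a smooth objective;
## the scan guards against multimodality rather than assuming unimodality
refine_extremum <- function(f, lo, hi, maximize = FALSE, n_grid = 2048) {
  grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  vals <- f(grid)
  i <- if (maximize) which.max(vals) else which.min(vals)
  at_upper <- i == n_grid
  at_lower <- i == 1
  bl <- grid[max(i - 1, 1)]
  bu <- grid[min(i + 1, n_grid)]
  opt <- stats::optimize(f, lower = bl, upper = bu, maximum = maximize,
                         tol = 1e-8 * max(1, grid[i]))
  loc <- if (maximize) opt$maximum else opt$minimum
  val <- opt$objective
  ## never report worse than the best grid point
  if ((maximize && vals[i] > val) || (!maximize && vals[i] < val)) {
    loc <- grid[i]; val <- vals[i]
  }
  ## parabolic-vertex (Newton) polish at a step wide enough to sit above the
  ## objective's evaluation-noise floor; invariant to rescaling f, so it
  ## localises the stationary point far below the golden-section tolerance
  if (!at_upper && !at_lower) {
    for (iter in 1:2) {
      delta <- 1e-3 * max(1, abs(loc))
      fp <- f(loc + delta); fm <- f(loc - delta); f0 <- f(loc)
      curv <- fp - 2 * f0 + fm
      if (!is.finite(curv) || curv == 0) break
      cand <- loc - 0.5 * delta * (fp - fm) / curv
      if (!(cand > bl && cand < bu && abs(cand - loc) < 2 * delta)) break
      fc <- f(cand)
      slack <- 1e-6 * abs(val) + 1e-300
      if ((maximize && fc < val - slack) || (!maximize && fc > val + slack))
        break
      loc <- cand
      val <- if (maximize) max(val, fc) else min(val, fc)
    }
  }
  list(location = loc, value = val,
       boundary = if (at_upper) "upper" else if (at_lower) "lower" else "none")
}

#' Peak decline of survival / peak rise of hazard
#'
#' \code{peak_survival_decline} locates the time of the maximum rate of
#' decrease of the survival curve (the minimiser of
#' \code{\link{survival_velocity}} over \eqn{(0, t_{max}]}) and the velocity
#' attained there.  \code{peak_hazard_rise} locates the time of the maximum
#' rate of increase of the hazard.  Under proportional hazards
#' \eqn{dh/dt = g\, h_0'(t)}, so the peak hazard-rise \emph{time} is the
#' same for every covariate profile — only its magnitude scales with
#' \eqn{g}.  The search is a dense log-spaced scan over
#' \eqn{(10^{-3}, t_{max}]} followed by golden-section refinement.
#'
#' @inheritParams ph_survival
#' @param t_max right end of the search window in years (default 40, beyond
#'   a 20-year study horizon).
#' @return list with \code{location} (years), \code{velocity} (the signed
#'   rate at the extremum) and \code{boundary} (\code{"none"}, or
#'   \code{"upper"}/\code{"lower"} when the extremum sits on the search
#'   boundary).
#' @export
peak_survival_decline <- function(object, profile = NULL, t_max = 40) {
  spec <- as_ph_spec(object)
  stopifnot(t_max > 0)
  r <- refine_extremum(function(t) survival_velocity(spec, t, profile),
                       1e-3, t_max, maximize = FALSE)
  list(location = r$location, velocity = r$value, boundary = r$boundary)
}

#' @rdname peak_survival_decline
#' @export
peak_hazard_rise <- function(object, profile = NULL, t_max = 40) {
  spec <- as_ph_spec(object)
  stopifnot(t_max > 0)
  r <- refine_extremum(function(t) hazard_velocity(spec, t, profile),
                       1e-3, t_max, maximize = TRUE)
  list(location = r$location, velocity = r$value, boundary = r$boundary)
}

#' Survival at a fixed time as a function of one covariate
#'
#' Sweeps covariate \code{k} over \code{grid} (all other covariates held at
#' \code{profile}) and returns the survival probability at \code{t0}
#' together with its analytic derivative in the covariate level,
#' \eqn{dS/dx_k = S \log S_0(t_0)\, g\, \theta_k} (non-positive whenever
#' \eqn{\theta_k > 0}).
#'
#' @inheritParams ph_survival
#' @param t0 evaluation time (years), \code{t0 > 0}.
#' @param k covariate name to sweep.
#' @param grid numeric vector of levels for covariate \code{k}.
#' @return data frame with columns \code{level}, \code{survival},
#'   \code{dsurvival}.
#' @export
survival_vs_covariate <- function(object, t0, k, grid, profile = NULL) {
  spec <- as_ph_spec(object)
  stopifnot(length(t0) == 1, t0 > 0)
  if (!k %in% names(spec$coef))
    stop("unknown covariate: ", k, call. = FALSE)
  ls0 <- spec$.fam$logS0(t0, spec$baseline)
  out <- vapply(grid, function(v) {
    pr <- profile
    pr[[k]] <- v
    g <- spec_g(spec, pr)
    s <- exp(g * ls0)
    c(s, s * ls0 * g * spec$coef[[k]])
  }, numeric(2))
  data.frame(level = grid, survival = out[1, ], dsurvival = out[2, ])
}

#' Covariate level of maximal survival impact
#'
#' At a fixed time \code{t0}, finds the level of covariate \code{k} within
#' \code{range} at which the survival probability decreases fastest per
#' unit of covariate (the minimiser of \eqn{dS/dx_k}).  For a positive
#' coefficient the interior minimiser satisfies \eqn{g = 1/|\log S_0(t_0)|},
#' so it moves to lower covariate levels as \code{t0} grows; when the
#' stationary level lies outside \code{range} the minimiser is reported on
#' the boundary with \code{boundary} flagged.
#'
#' @inheritParams survival_vs_covariate
#' @param range length-2 numeric, the covariate interval to search.
#' @return list with \code{location} (covariate level), \code{velocity}
#'   (\eqn{dS/dx_k} attained) and \code{boundary}.
#' @export
peak_covariate_effect <- function(object, t0, k, range, profile = NULL) {
  spec <- as_ph_spec(object)
  stopifnot(length(range) == 2)
  if (range[1] >= range[2]) stop("'range' must satisfy lo < hi", call. = FALSE)
  f <- function(v) survival_vs_covariate(spec, t0, k, v, profile)$dsurvival
  grid <- seq(range[1], range[2], length.out = 2048)
  vals <- f(grid)
  i <- which.min(vals)
  opt <- stats::optimize(f, lower = grid[max(i - 1, 1)],
                         upper = grid[min(i + 1, length(grid))],
                         tol = 1e-9 * max(1, diff(range)))
  loc <- opt$minimum; val <- opt$objective
  if (vals[i] < val) { loc <- grid[i]; val <- vals[i] }
  boundary <- if (i == length(grid)) "upper" else if (i == 1) "lower"
              else "none"
  list(location = loc, velocity = val, boundary = boundary)
}

#' Conditional survival probability
#'
#' \eqn{P(T > t_2 \mid T > t_1, x) = S(t_2 \mid x)/S(t_1 \mid x)}, evaluated
#' in log space for stability.
#'
#' @inheritParams ph_survival
#' @param t1,t2 times in years with \eqn{0 < t_1 \le t_2}.
#' @return probability in \eqn{(0, 1]}.
#' @examples
#' spec <- ph_spec("hypertabastic", c(0.7247, 0.6205))
#' conditional_survival(spec, 10, 20)
#' @export
conditional_survival <- function(object, t1, t2, profile = NULL) {
  spec <- as_ph_spec(object)
  if (any(t1 <= 0) || any(t2 < t1))
    stop("need 0 < t1 <= t2", call. = FALSE)
  exp(ph_survival(spec, t2, profile, log.p = TRUE) -
        ph_survival(spec, t1, profile, log.p = TRUE))
}

#' Survival over a covariate (and optionally time) grid
#'
#' Dense evaluation of the survival function over one or two covariate axes
#' and, optionally, a time axis, for surface plots and tabulations.  Slices
#' at a fixed value of one axis agree exactly with
#' \code{\link{survival_vs_covariate}}.
#'
#' @inheritParams ph_survival
#' @param axes named list of one or two numeric grids, names being
#'   covariates of the model.
#' @param times numeric vector of evaluation times (years); scalar allowed.
#' @return long-format data frame: one column per axis, \code{time},
#'   \code{survival}.
#' @export
survival_surface <- function(object, axes, times, profile = NULL) {
  spec <- as_ph_spec(object)
  if (!length(axes) || length(axes) > 2)
    stop("'axes' must name one or two covariates", call. = FALSE)
  bad <- setdiff(names(axes), names(spec$coef))
  if (length(bad))
    stop("unknown covariate(s): ", paste(bad, collapse = ", "), call. = FALSE)
  grid <- do.call(expand.grid, c(axes, list(time = times)))
  grid$survival <- vapply(seq_len(nrow(grid)), function(i) {
    pr <- profile
    for (a in names(axes)) pr[[a]] <- grid[[a]][i]
    ph_survival(spec, grid$time[i], pr)
  }, numeric(1))
  grid
}
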