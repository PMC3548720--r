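# Maximum-likelihood fitting, inference and model comparison.

test_that("fit recovers generating parameters on a lightly censored cohort", {
  cfg <- cohort_config(n = 1500, admin_horizon = 1e4, censor_rate = 0,
                       seed = 101)
  d <- simulate_cohort(cfg)
  fit <- hypertab_ph(surv_formula, d)
  expect_true(fit$converged)
  expect_true(fit$se_defined)
  truth <- c(0.7247, 0.6205, table2_coef)
  z <- abs(fit$estimate - truth) / fit$se
  expect_true(all(z < 3))
  # CSR carries the largest positive coefficient, as in the generating model
  expect_equal(names(which.max(fit$estimate[names(table2_coef)])), "CSR")
})

test_that("degenerate designs are rejected", {
  d <- small_cohort(n = 200)
  d$CSR2 <- d$CSR
  expect_error(
    hypertab_ph(survival::Surv(time, event) ~ CSR + CSR2, d),
    "collinear")
  d$const <- 1.7
  expect_error(hypertab_ph(survival::Surv(time, event) ~ const, d),
               "constant")
  expect_error(hypertab_ph(surv_formula, d[1:5, ]), "at least 10")
  d2 <- d
  d2$time[1] <- -1
  expect_error(hypertab_ph(surv_formula, d2), "positive")
})

test_that("rescaling a covariate rescales its coefficient, not the fit", {
  d <- small_cohort(n = 300, seed = 17)
  f1 <- hypertab_ph(survival::Surv(time, event) ~ G70 + CSR, d)
  d$CSR <- d$CSR * 10
  f2 <- hypertab_ph(survival::Surv(time, event) ~ G70 + CSR, d)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(unname(f2$estimate["CSR"]) * 10,
               unname(f1$estimate["CSR"]), tolerance = 1e-3)
})

test_that("adding a covariate never decreases the maximised likelihood", {
  d <- small_cohort(n = 300, seed = 23)
  for (fam in c("hypertabastic", "weibull", "loglogistic")) {
    f0 <- hypertab_ph(survival::Surv(time, event) ~ 1, d, family = fam)
    f1 <- hypertab_ph(survival::Surv(time, event) ~ G70, d, family = fam)
    f2 <- hypertab_ph(survival::Surv(time, event) ~ G70 + CSR, d,
                      family = fam)
    expect_gte(f1$loglik, f0$loglik - 1e-6)
    expect_gte(f2$loglik, f1$loglik - 1e-6)
  }
})

test_that("fit results are internally consistent and well-formed", {
  d <- small_cohort(n = 300, seed = 31)
  fit <- hypertab_ph(surv_formula, d)
  expect_equal(fit$aic, fit$minus_two_loglik + 2 * fit$n_params)
  expect_equal(fit$wald, (fit$estimate / fit$se)^2)
  expect_equal(fit$hazard_ratio,
               exp(fit$estimate[names(table2_coef)]))
  expect_equal(fit$p_value, wald_p(fit$wald))
  vc <- vcov(fit)
  expect_equal(vc, t(vc), tolerance = 1e-10)
  expect_true(all(diag(vc) >= 0))
  # the reported optimum dominates the likelihood at perturbed parameters
  ll_hat <- ph_loglik(fit$spec, d$time, d$event,
                      as.matrix(d[names(table2_coef)]))
  expect_equal(ll_hat, fit$loglik, tolerance = 1e-8)
  for (k in seq_along(fit$estimate)) {
    pert <- fit$estimate
    pert[k] <- pert[k] * 1.05 + 0.01
    sp <- ph_spec(fit$family, pert[1:2], pert[-(1:2)])
    expect_lt(ph_loglik(sp, d$time, d$event,
                        as.matrix(d[names(table2_coef)])), ll_hat)
  }
  # stats generics
  expect_equal(AIC(fit), fit$aic)
  expect_equal(unname(nobs(fit)), nrow(d))
  out <- capture.output(print(fit))
  expect_true(any(grepl("hypertabastic", out)))
  expect_true(any(grepl("CSR", out)))
})

test_that("covariance inverts a known quadratic Hessian exactly", {
  # on a quadratic log-likelihood the observed information is the exact
  # curvature matrix; pracma's FD Hessian must recover its inverse
  A <- matrix(c(2, 0.5, 0.5, 1.5), 2)
  f <- function(p) drop(0.5 * t(p) %*% A %*% p)
  H <- pracma::hessian(f, c(0.3, -0.2))
  expect_equal(solve(H), solve(A), tolerance = 1e-6)
})

test_that("estimated SEs are calibrated against the empirical spread", {
  rec <- recovery_experiment(config = cohort_config(),
                             n_values = 500, replicates = 40, seed = 77)
  s <- rec$summary
  expect_true(all(s$n_fits >= 35))
  expect_true(all(abs(s$mean_se / s$sd - 1) < 0.25))
})

test_that("Weibull PH at k = 1 matches the closed-form exponential MLE", {
  set.seed(4)
  te <- stats::rexp(500, 0.3)
  ce <- stats::runif(500, 0, 8)
  time <- pmin(te, ce)
  event <- as.integer(te <= ce)
  lam_cf <- sum(event) / sum(time)
  opt <- stats::optimize(function(l)
    -ph_loglik(ph_spec("weibull", c(l, 1)), time, event),
    c(1e-4, 5), tol = 1e-10)
  expect_equal(opt$minimum, lam_cf, tolerance = 1e-4)
  # the free-k fit cannot do worse, and finds k near 1
  d <- data.frame(time = time, event = event)
  fit <- hypertab_ph(survival::Surv(time, event) ~ 1, d, family = "weibull")
  expect_gte(fit$loglik, -opt$objective - 1e-6)
  expect_equal(unname(fit$estimate["k"]), 1, tolerance = 0.15)
})

test_that("Weibull PH fit agrees with an independent AFT implementation", {
  # flexsurv fits the Weibull in AFT form; shape a and scale mu map to the
  # PH parameterisation as lambda = mu^-a, theta = -a * beta_AFT
  set.seed(2)
  n <- 600
  x <- stats::rnorm(n)
  tt <- stats::rweibull(n, shape = 1.4,
                        scale = (1 / 0.2)^(1 / 1.4) * exp(-(0.7 * x) / 1.4))
  cens <- stats::runif(n, 0, 15)
  d <- data.frame(time = pmin(tt, cens), event = as.integer(tt <= cens),
                  x = x)
  fit <- hypertab_ph(survival::Surv(time, event) ~ x, d, family = "weibull")
  fs <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ x, data = d,
                              dist = "weibull")
  a <- fs$res["shape", "est"]
  mu <- fs$res["scale", "est"]
  expect_equal(fit$loglik, fs$loglik, tolerance = 1e-6)
  expect_equal(unname(fit$estimate["lambda"]), mu^(-a), tolerance = 1e-3)
  expect_equal(unname(fit$estimate["k"]), a, tolerance = 1e-3)
  expect_equal(unname(fit$estimate["x"]), -a * fs$res["x", "est"],
               tolerance = 1e-3)
})

test_that("model comparison tabulates all families ranked by AIC", {
  d <- small_cohort(n = 300, seed = 41)
  cmp <- compare_models(surv_formula, d)
  expect_equal(nrow(cmp), 3)
  expect_true(!is.unsorted(cmp$aic))
  expect_true(all(cmp$converged))
  expect_true(all(cmp$n_params == 6))
  # null-model -2logL is never below the full model's (nesting)
  expect_true(all(cmp$minus_two_loglik_null >= cmp$minus_two_loglik))
  one <- compare_models(surv_formula, d, families = "weibull")
  expect_equal(nrow(one), 1)
})

test_that("forward selection screens correlated candidates and finds signal", {
  set.seed(55)
  n <- 400
  X <- data.frame(A = stats::rnorm(n), N1 = stats::rnorm(n),
                  N2 = stats::rnorm(n))
  truth <- ph_spec("hypertabastic", c(0.7247, 0.6205), coef = c(A = 1.2))
  tt <- simulate_event_times(X, truth)
  d <- cbind(apply_censoring(tt, cohort_config(n = n)), X)
  d$Adup <- d$A                       # |r| = 1 with A: must be screened
  sel <- forward_select(d, c("A", "Adup", "N1", "N2"))
  expect_true("A" %in% sel$included)
  expect_false("Adup" %in% sel$included)
  expect_true(any(sel$trace$action == "screened" &
                    sel$trace$candidate == "Adup"))
  # cap above 1 disables the screen: the duplicate now fails on collinearity
  # only when it would actually enter, so selection still excludes it or errs
  sel2 <- forward_select(d, c("A", "N1"), correlation_cap = 1.01)
  expect_true(all(sel2$trace$action != "screened"))
  # pure-noise candidates rarely enter across replicates
  hits <- 0; noise <- 0
  for (r in 1:6) {
    set.seed(600 + r)
    X <- data.frame(A = stats::rnorm(n), N1 = stats::rnorm(n),
                    N2 = stats::rnorm(n), N3 = stats::rnorm(n))
    tt <- simulate_event_times(X, truth)
    d <- cbind(apply_censoring(tt, cohort_config(n = n)), X)
    s <- forward_select(d, c("A", "N1", "N2", "N3"))
    hits <- hits + ("A" %in% s$included)
    noise <- noise + length(setdiff(s$included, "A"))
  }
  expect_equal(hits, 6)
  expect_lte(noise, 6)
})

test_that("an empty selection returns the baseline-only model", {
  set.seed(66)
  n <- 300
  X <- data.frame(N1 = stats::rnorm(n), N2 = stats::rnorm(n))
  tt <- simulate_event_times(X, ph_spec("hypertabastic", c(0.7, 0.6),
                                        coef = c(N1 = 0, N2 = 0)))
  d <- cbind(apply_censoring(tt, cohort_config(n = n)), X)
  sel <- forward_select(d, c("N1", "N2"), p_enter = 1e-6)
  expect_length(sel$included, 0)
  expect_equal(sel$fit$n_params, 2)
})

test_that("Wald helpers reproduce their closed forms", {
  expect_equal(wald_statistic(0.6205, 0.1244), (0.6205 / 0.1244)^2)
  expect_equal(wald_statistic(0, 2), 0)
  expect_equal(wald_p(0), 1)
  expect_true(is.nan(wald_statistic(1, 0)))
  # chi-square(1) arithmetic at a frozen point
  expect_equal(wald_p(6.298), 0.01208, tolerance = 1e-3)
  expect_equal(hazard_ratio(0), 1)
  expect_equal(aic(-193.8775, 6), 399.755)
  expect_equal(aic(0, 1), 2)
})
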