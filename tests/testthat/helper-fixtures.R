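# Shared fixtures: all synthetic, built in code.

table2_coef <- c(AGE = -0.0735, G70 = 1.199, CSR = 2.661, CERBB = 1.561)
table2_spec <- function() default_truth()

good_profile <- c(AGE = 45, G70 = 0, CSR = 0, CERBB = 0)
poor_profile <- c(AGE = 45, G70 = 1, CSR = 0, CERBB = 0)

surv_formula <- survival::Surv(time, event) ~ AGE + G70 + CSR + CERBB

small_cohort <- function(n = 400, seed = 42, ...) {
  simulate_cohort(cohort_config(n = n, seed = seed, ...))
}

# naive, independent evaluation of the closed forms (plain transcription,
# no stability tricks) -- valid for moderate t where doubles suffice
naive_S0 <- function(t, a, b) {
  x <- t^b
  1 / cosh(a * (1 - x / tanh(x)) / b)
}
naive_h0 <- function(t, a, b) {
  x <- t^b
  W <- a * (1 - x / tanh(x)) / b
  a * (t^(2 * b - 1) / sinh(x)^2 - t^(b - 1) / tanh(x)) * tanh(W)
}

# arbitrary-precision oracle via mpmath (ships with the Python stack);
# returns data.frame(S0, h0, f0) evaluated at 30 significant digits
mpmath_oracle <- function(t, alpha, beta) {
  stopifnot(length(t) == length(alpha), length(t) == length(beta))
  inp <- paste(t, alpha, beta, collapse = "\n")
  code <- paste(
    "import sys",
    "from mpmath import mp, mpf, coth, sech, csch, tanh",
    "mp.dps = 30",
    "for line in sys.stdin.read().strip().splitlines():",
    "    t, a, b = [mpf(v) for v in line.split()]",
    "    x = t**b",
    "    W = a*(1 - x*coth(x))/b",
    "    S0 = sech(W)",
    "    h0 = a*(t**(2*b-1)*csch(x)**2 - t**(b-1)*coth(x))*tanh(W)",
    "    print(mp.nstr(S0, 17), mp.nstr(h0, 17), mp.nstr(h0*S0, 17))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(code)), input = inp,
                 stdout = TRUE)
  vals <- do.call(rbind, lapply(strsplit(out, " +"), as.numeric))
  data.frame(S0 = vals[, 1], h0 = vals[, 2], f0 = vals[, 3])
}

rel_err <- function(x, y) abs(x - y) / pmax(abs(y), .Machine$double.xmin)
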