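# Internal numerical helpers. All log-domain work funnels through these so
# posterior normalisation is stable for z-scores in the hundreds.

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference underflows
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  ifelse(x > 35, x, log1p(exp(x)))
}

# two-sided normal p-value from a z-score
z_to_p <- function(z) 2 * pnorm(-abs(z))

first_or_na <- function(x) if (length(x)) x[[1]] else NA

`%||%` <- rlang::`%||%`

assert_cols <- function(x, cols, what = deparse(substitute(x))) {
  miss <- setdiff(cols, names(x))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# Exact Poisson-binomial distribution of a sum of independent Bernoulli(p_i),
# by dynamic programming over the success-count polynomial.
poisson_binomial_pmf <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  f <- 1
  for (pi in p) {
    f <- c(f * (1 - pi), 0) + c(0, f * pi)
  }
  f
}

# Upper tail P(X >= k) of the Poisson-binomial with success probs p
poisson_binomial_tail <- function(k, p) {
  f <- poisson_binomial_pmf(p)
  n <- length(p)
  if (k <= 0) return(1)
  if (k > n) return(0)
  sum(f[(k + 1):(n + 1)])
}

# Upper-tail probability P(sum_i lambda_i * chisq_1 > q) by Imhof's
# characteristic-function inversion. Adequate for the instrument counts
# (m <= ~20) used by the HEIDI heterogeneity test.
imhof_tail <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-12]
  if (!length(lambda)) return(1)
  if (length(lambda) == 1) {
    return(pchisq(q / lambda, df = 1, lower.tail = FALSE))
  }
  if (q <= 0) return(1)
  integrand <- function(u) {
    th <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    out <- sin(th) / (u * rho)
    # u -> 0 limit of the integrand is (sum(lambda) - q) / 2
    out[u < 1e-12] <- (sum(lambda) - q) / 2
    out
  }
  val <- tryCatch(
    integrate(integrand, lower = 0, upper = Inf, subdivisions = 2000L,
              rel.tol = 1e-9, abs.tol = 1e-12)$value,
    error = function(e) {
      integrate(integrand, lower = 0, upper = 1e4, subdivisions = 2000L,
                rel.tol = 1e-7)$value
    })
  p <- 0.5 + val / pi
  min(max(p, 1e-15), 1)
}

# Rank-based inverse-normal transform with the Blom offset; ties share the
# average rank.
inverse_normal <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  if (n == 0) return(out)
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}
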