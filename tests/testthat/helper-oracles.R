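# Independent brute-force oracles, written before the implementations they
# check and kept deliberately naive.

# population SD, matching the tolerance anchor convention
oracle_sd <- function(x) sqrt(mean((x - mean(x))^2))

# sample entropy by exhaustive template-pair enumeration (ordered pairs,
# i != j, self-matches excluded, Chebyshev distance)
oracle_sampen <- function(x, m, r, sd_ref = NULL) {
  n <- length(x)
  tol <- r * (if (is.null(sd_ref)) oracle_sd(x) else sd_ref)
  nt <- n - m # templates long enough for the m+1 comparison
  A <- 0; B <- 0
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i == j) next
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= tol) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= tol) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# approximate entropy by exhaustive enumeration, self-matches included
oracle_apen <- function(x, m, r) {
  n <- length(x)
  tol <- r * oracle_sd(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    lc <- vapply(seq_len(nt), function(i) {
      cnt <- sum(vapply(seq_len(nt), function(j)
        max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= tol, logical(1)))
      log(cnt / nt)
    }, numeric(1))
    mean(lc)
  }
  phi(m) - phi(m + 1)
}

# coarse-graining by explicit block loop
oracle_coarse <- function(x, s) {
  nb <- length(x) %/% s
  vapply(seq_len(nb), function(j) mean(x[((j - 1) * s + 1):(j * s)]),
         numeric(1))
}

# Pearson r from the definitional sum formula
oracle_pearson_r <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# two-sided p-value by numerical integration of the t density
oracle_pearson_p <- function(r, n) {
  df <- n - 2
  tstat <- abs(r) * sqrt(df / (1 - r^2))
  dens <- function(t) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + t^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, tstat, Inf, rel.tol = 1e-12)$value
}

# partial correlation by explicit residualize-then-correlate
oracle_partial <- function(x, y, g) {
  g <- factor(g)
  rx <- unlist(lapply(levels(g), function(l) x[g == l] - mean(x[g == l])))
  ry <- unlist(lapply(levels(g), function(l) y[g == l] - mean(y[g == l])))
  oracle_pearson_r(rx, ry)
}

# least-squares residuals through the normal equations
oracle_residuals <- function(X, design) {
  beta <- solve(t(design) %*% design, t(design) %*% X)
  X - design %*% beta
}

expect_scalar_equal <- function(object, expected, tol) {
  expect_true(is.finite(object) == is.finite(expected))
  if (is.finite(expected)) expect_lt(abs(object - expected), tol)
}
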