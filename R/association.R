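#' Pearson correlation with a two-sided p-value
#'
#' The p-value uses the usual t-transform with `length(x) - 2` degrees of
#' freedom. Pairs with missing values are dropped. Zero variance in either
#' variable gives the undefined sentinel (`NA` for both `r` and `p`).
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return A list with elements `r`, `p`, `n`, `df`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3)
    stop("need at least 3 complete pairs", call. = FALSE)
  if (pop_sd(x) == 0 || pop_sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, df = n - 2L))
  r <- stats::cor(x, y)
  r <- max(-1, min(1, r))
  df <- n - 2L
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(t), df)
  }
  list(r = r, p = p, n = n, df = df)
}

#' Partial correlation controlling for a grouping factor
#'
#' Pearson correlation of the residuals of `x` and `y` after removing group
#' means (equivalent to least squares on dummy-coded group indicators), the
#' standard way of controlling for a subject/animal effect in repeated
#' measurements. The p-value uses `N - #groups - 1` degrees of freedom.
#' Groups with a single observation carry no within-group information and
#' are dropped with a warning.
#'
#' @param x,y Numeric vectors of equal length.
#' @param group Group label per observation (factor or vector).
#' @return A list with elements `r`, `p`, `n`, `df`, `n_groups`.
#' @export
partial_correlation <- function(x, y, group) {
  if (length(x) != length(y) || length(x) != length(group))
    stop("`x`, `y` and `group` must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y) & !is.na(group)
  x <- x[ok]; y <- y[ok]; group <- factor(group[ok])
  sizes <- table(group)
  if (any(sizes < 2)) {
    warning("dropping group(s) with a single observation: ",
            paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
    keep <- group %in% names(sizes)[sizes >= 2]
    x <- x[keep]; y <- y[keep]; group <- droplevels(group[keep])
  }
  n <- length(x)
  k <- nlevels(group)
  df <- n - k - 1L
  if (n == 0 || df < 1)
    stop("not enough residual degrees of freedom (n = ", n,
         ", groups = ", k, ")", call. = FALSE)
  rx <- x - ave(x, group)
  ry <- y - ave(y, group)
  if (pop_sd(rx) == 0 || pop_sd(ry) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, df = df, n_groups = k))
  r <- stats::cor(rx, ry)
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(t), df)
  }
  list(r = r, p = p, n = n, df = df, n_groups = k)
}

#' Linear and quadratic fits with nested-model comparison
#'
#' Least-squares linear and quadratic fits of `y` on `x`, together with the
#' Pearson correlation. `quad_better` is `TRUE` when the quadratic term is
#' significant by the nested-model F-test at `alpha` (default 0.05), the
#' criterion used to call an association "best fit by a quadratic
#' function" (e.g. an inverted-U relationship).
#'
#' @param x,y Numeric vectors (>= 4 complete pairs).
#' @param alpha Significance level of the nested F-test.
#' @return An object of class `"association"`: list with `r`, `p`,
#'   `linear_fit` (intercept, slope), `quad_fit` (intercept, slope,
#'   curvature), `quad_better`, `F_quad`, `p_quad`, `n`.
#' @export
fit_linear_quadratic <- function(x, y, alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4)
    stop("need at least 4 complete pairs for the quadratic fit", call. = FALSE)
  if (pop_sd(x) == 0)
    stop("`x` has zero variance; fit is rank deficient", call. = FALSE)
  pear <- pearson_with_p(x, y)
  f_lin <- stats::lm(y ~ x)
  f_quad <- stats::lm(y ~ x + I(x^2))
  if (f_quad$rank < 3)
    stop("quadratic design is rank deficient", call. = FALSE)
  cmp <- stats::anova(f_lin, f_quad)
  F_quad <- cmp$F[2]
  p_quad <- cmp$`Pr(>F)`[2]
  rss_quad <- sum(resid(f_quad)^2)
  if (!is.finite(F_quad) && rss_quad < .Machine$double.eps * sum(y^2)) {
    # exact quadratic interpolation: zero residual, F degenerate
    F_quad <- Inf
    p_quad <- 0
  }
  structure(
    list(r = pear$r, p = pear$p,
         linear_fit = stats::coef(f_lin),
         quad_fit = stats::coef(f_quad),
         quad_better = is.finite(p_quad) && p_quad < alpha || identical(p_quad, 0),
         F_quad = F_quad, p_quad = p_quad, n = n),
    class = "association"
  )
}

#' @export
print.association <- function(x, ...) {
  cat(sprintf("Association (n = %d): r = %.3f, p = %.3g\n", x$n, x$r, x$p))
  cat(sprintf("  linear: y = %.3g + %.3g x\n",
              x$linear_fit[1], x$linear_fit[2]))
  cat(sprintf("  quadratic: y = %.3g + %.3g x + %.3g x^2 (%s, p_F = %.3g)\n",
              x$quad_fit[1], x$quad_fit[2], x$quad_fit[3],
              if (isTRUE(x$quad_better)) "preferred" else "not preferred",
              x$p_quad))
  invisible(x)
}
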