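#' Coarse-grain a time series
#'
#' Non-overlapping block averaging at an integer scale factor, the
#' coarse-graining step of multi-scale entropy: element \eqn{j} of the output
#' is the mean of the \eqn{j}-th block of `scale` consecutive samples. A
#' trailing partial block is dropped. The effective sampling rate of the
#' output is `fs / scale`.
#'
#' @param x Numeric vector of samples.
#' @param scale Positive integer scale factor, at most `length(x)`.
#' @return Numeric vector of length `floor(length(x) / scale)`.
#' @examples
#' coarse_grain(1:6, 2) # 1.5 3.5 5.5
#' @export
coarse_grain <- function(x, scale) {
  x <- as.numeric(x)
  if (length(scale) != 1L || !is.finite(scale) || scale < 1 ||
      scale != round(scale))
    stop("`scale` must be a single positive integer", call. = FALSE)
  scale <- as.integer(scale)
  if (scale > length(x))
    stop("`scale` exceeds the series length", call. = FALSE)
  if (scale == 1L) return(x)
  nb <- length(x) %/% scale
  colMeans(matrix(x[seq_len(nb * scale)], nrow = scale))
}

#' Sample entropy (SampEn)
#'
#' The negative log conditional probability that two subsequences matching
#' for `m` points (within a Chebyshev tolerance) remain matching for `m + 1`
#' points, excluding self-matches. The tolerance is `r` times the population
#' standard deviation of the series (or of a reference series via `sd_ref`,
#' the convention used by coarse-grained multi-scale entropy, where the
#' anchor stays the scale-1 series).
#'
#' Returns 0 for a constant series (perfect regularity) and `NA` when no
#' template pairs match at length `m` or `m + 1`, in which case the estimate
#' is undefined rather than infinite.
#'
#' @param x Numeric vector, length at least `m + 2`.
#' @param m Pattern length (positive integer).
#' @param r Matching tolerance as a fraction of the standard deviation.
#' @param sd_ref Optional standard deviation used to form the tolerance in
#'   place of `sd(x)`.
#' @return A single number, or `NA` if undefined.
#' @seealso [approximate_entropy()], [mse_curve()]
#' @export
sample_entropy <- function(x, m = 2, r = 0.5, sd_ref = NULL) {
  x <- as.numeric(x)
  check_entropy_params(m, r)
  if (length(x) <= m + 1)
    stop("series too short for pattern length m = ", m, call. = FALSE)
  s <- if (is.null(sd_ref)) pop_sd(x) else stopifnot_scalar_number(sd_ref, "sd_ref")
  if (is.null(sd_ref) && s == 0) return(0)   # constant-series convention
  cpp_sampen(x, as.integer(m), r * s)
}

#' Approximate entropy (ApEn)
#'
#' Pincus' regularity statistic \eqn{\Phi^m - \Phi^{m+1}}, where
#' \eqn{\Phi^m} is the mean log frequency of template matches of length `m`
#' under the Chebyshev metric, self-matches included. Unlike sample entropy
#' it is always finite, at the price of a bias toward regularity.
#'
#' @inheritParams sample_entropy
#' @return A single non-negative number (0 for a constant series).
#' @export
approximate_entropy <- function(x, m = 2, r = 0.5, sd_ref = NULL) {
  x <- as.numeric(x)
  check_entropy_params(m, r)
  if (length(x) <= m + 1)
    stop("series too short for pattern length m = ", m, call. = FALSE)
  s <- if (is.null(sd_ref)) pop_sd(x) else stopifnot_scalar_number(sd_ref, "sd_ref")
  cpp_apen(x, as.integer(m), r * s)
}

check_entropy_params <- function(m, r) {
  if (length(m) != 1L || !is.finite(m) || m < 1 || m != round(m))
    stop("`m` must be a positive integer", call. = FALSE)
  if (length(r) != 1L || !is.finite(r) || r <= 0)
    stop("`r` must be a positive number", call. = FALSE)
  invisible(TRUE)
}

#' Multi-scale entropy (MSE) curve
#'
#' Sample entropy of successively coarse-grained versions of a signal. The
#' matching tolerance is anchored to the population SD of the *original*
#' (scale-1) series at every scale, so entropy values are comparable across
#' scales: white noise then shows the characteristic decrease toward coarse
#' scales while 1/f-like signals stay comparatively flat.
#'
#' Scales that leave fewer than `m + 2` coarse-grained points, or at which no
#' template pair matches, are returned as `NA` with a warning.
#'
#' @inheritParams sample_entropy
#' @param scales Vector of positive integer scale factors.
#' @param fs Sampling rate of `x` in Hz (used by frequency-band summaries).
#' @return An object of class `"mse_curve"`: a list with elements `scales`,
#'   `entropy`, `m`, `r`, `fs` and `sd_ref`.
#' @examples
#' x <- rnorm(2000)
#' mse_curve(x, scales = 1:10, m = 2, r = 0.2, fs = 100)
#' @export
mse_curve <- function(x, scales = 1:20, m = 2, r = 0.5, fs = 1, sd_ref = NULL) {
  x <- as.numeric(x)
  check_entropy_params(m, r)
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  scales <- as.integer(scales)
  if (any(!is.finite(scales)) || any(scales < 1))
    stop("`scales` must be positive integers", call. = FALSE)
  if (is.unsorted(scales, strictly = TRUE))
    stop("`scales` must be strictly increasing", call. = FALSE)
  s <- sd_ref %||% pop_sd(x)
  if (s == 0) {
    ent <- ifelse(length(x) %/% scales >= m + 2, 0, NA_real_)
  } else {
    ent <- cpp_mse(x, scales, as.integer(m), r * s)
  }
  if (anyNA(ent))
    warning(sum(is.na(ent)), " scale(s) undefined (too few points or no matches)",
            call. = FALSE)
  structure(
    list(scales = scales, entropy = as.numeric(ent),
         m = as.integer(m), r = r, fs = fs, sd_ref = s),
    class = "mse_curve"
  )
}

#' @export
print.mse_curve <- function(x, ...) {
  cat("Multi-scale entropy curve (m =", x$m, ", r =", x$r,
      ", fs =", x$fs, "Hz)\n")
  cat("  scales:", length(x$scales), "in [", min(x$scales), ",",
      max(x$scales), "]\n")
  ok <- is.finite(x$entropy)
  cat("  entropy:", sum(ok), "defined, range",
      if (any(ok)) paste(round(range(x$entropy[ok]), 3), collapse = " .. ")
      else "-", "\n")
  invisible(x)
}

#' @export
as.data.frame.mse_curve <- function(x, ...) {
  data.frame(scale = x$scales,
             frequency = x$fs / x$scales,
             entropy = x$entropy)
}
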