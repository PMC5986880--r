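#' Map a coarse-graining scale to a representative temporal frequency
#'
#' Two conventions are in common use. The `"direct"` convention takes the
#' sampling rate of the coarse-grained series, \eqn{f = fs / s}; under it a
#' 200 Hz signal at scales 1–400 spans 200–0.5 Hz. The `"nyquist"`
#' convention takes the Nyquist frequency of the coarse-grained series,
#' \eqn{f = fs / (2 s)}, the natural reading for slow fMRI series: at
#' TR = 0.72 s (fs = 1.389 Hz) scales 1–2 map to 0.694–0.347 Hz.
#'
#' @param s Integer scale factor(s), at least 1.
#' @param fs Sampling rate of the original series in Hz.
#' @param convention `"direct"` (`fs / s`) or `"nyquist"` (`fs / (2 s)`).
#' @return Frequency in Hz, same length as `s`.
#' @export
scale_to_frequency <- function(s, fs, convention = c("direct", "nyquist")) {
  convention <- match.arg(convention)
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  if (any(!is.finite(s)) || any(s < 1))
    stop("scales must be >= 1", call. = FALSE)
  if (convention == "direct") fs / s else fs / (2 * s)
}

#' Canonical electrophysiological frequency bands
#'
#' The band set used by the coupling sweep: broad and narrow delta, theta,
#' alpha, beta and gamma. The narrow delta band (2.7–4 Hz) spans roughly as
#' many integer scales at 200 Hz as the other bands, which makes its
#' band-averaged MSE comparable to theirs.
#'
#' @return A data frame with columns `name`, `f_lo`, `f_hi` (Hz).
#' @export
default_bands <- function() {
  data.frame(
    name = c("delta_broad", "delta_narrow", "theta", "alpha", "beta", "gamma"),
    f_lo = c(0.5, 2.7, 4, 8, 16, 32),
    f_hi = c(4, 4, 7, 15, 31, 200),
    stringsAsFactors = FALSE
  )
}

#' Integer scales whose mapped frequency falls inside a band
#'
#' @param scales Integer scales available.
#' @inheritParams scale_to_frequency
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi`.
#' @param lower_edge `"include"` keeps a scale whose mapped frequency equals
#'   `f_lo` exactly; `"exclude"` assigns such boundary scales to the
#'   adjacent lower-frequency band instead (the deterministic tie-break used
#'   when a set of contiguous bands shares an edge).
#' @return The subset of `scales` inside the band.
#' @export
band_scales <- function(scales, fs, f_lo, f_hi,
                        convention = c("direct", "nyquist"),
                        lower_edge = c("include", "exclude")) {
  convention <- match.arg(convention)
  lower_edge <- match.arg(lower_edge)
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo <= 0 || f_hi <= f_lo)
    stop("band edges must satisfy 0 < f_lo < f_hi", call. = FALSE)
  f <- scale_to_frequency(scales, fs, convention)
  keep <- if (lower_edge == "include") f >= f_lo & f <= f_hi
          else f > f_lo & f <= f_hi
  scales[keep]
}

#' Average an MSE curve over a frequency band
#'
#' Unweighted mean of the defined entropy values over the integer scales
#' whose mapped frequency lies within `[f_lo, f_hi]`.
#'
#' @param curve An [mse_curve()] object.
#' @inheritParams band_scales
#' @return A single number, or `NA` if every entropy value in the band is
#'   undefined.
#' @export
band_average_mse <- function(curve, f_lo, f_hi,
                             convention = c("direct", "nyquist"),
                             lower_edge = c("include", "exclude")) {
  if (!inherits(curve, "mse_curve"))
    stop("`curve` must be an mse_curve object", call. = FALSE)
  keep <- curve$scales %in%
    band_scales(curve$scales, curve$fs, f_lo, f_hi,
                convention = convention, lower_edge = lower_edge)
  if (!any(keep))
    stop(sprintf("no scale maps into the band [%g, %g] Hz", f_lo, f_hi),
         call. = FALSE)
  vals <- curve$entropy[keep]
  if (all(is.na(vals))) {
    warning("all entropy values in the band are undefined", call. = FALSE)
    return(NA_real_)
  }
  mean(vals, na.rm = TRUE)
}
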