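#' Bundle one subject's node time series
#'
#' Container for the across-subject analyses: one or more recording
#' sessions of the same node set (e.g. two phase-encoding runs), stored as
#' time-by-node matrices, plus the repetition time or sampling rate.
#'
#' @param id Subject identifier.
#' @param sessions A time-by-node matrix or list of such matrices with
#'   identical column sets.
#' @param TR Repetition time in seconds (alternative to `fs`).
#' @param fs Sampling rate in Hz (alternative to `TR`).
#' @return An object of class `"subject_node_data"`.
#' @export
subject_node_data <- function(id, sessions, TR = NULL, fs = NULL) {
  if (is.matrix(sessions) || is.data.frame(sessions))
    sessions <- list(sessions)
  sessions <- lapply(sessions, as_node_matrix)
  nc <- vapply(sessions, ncol, integer(1))
  if (length(unique(nc)) != 1)
    stop("all sessions must share the same node set", call. = FALSE)
  if (is.null(fs)) {
    if (is.null(TR)) stop("supply `TR` or `fs`", call. = FALSE)
    fs <- 1 / TR
  }
  structure(list(id = id, sessions = sessions, fs = fs),
            class = "subject_node_data")
}

#' Scrub trigger-locked artifacts from an LFP trace
#'
#' Gradient-switching artifacts recorded during concurrent MR acquisition
#' are removed in the order: (1) each `artifact_ms` segment immediately
#' following a trigger is replaced by linear interpolation between the
#' samples flanking it; (2) the linear segment is then replaced by a cubic
#' smoothing spline fitted on the `context_ms` of data before and after
#' the segment (penalized rather than interpolating through every flank
#' sample, so wide-band noise on the flanks cannot destabilize the
#' reconstruction across the gap);
#' (3) the trace is zero-phase low-pass filtered at `lowpass_hz`; (4) an
#' additional anti-alias low-pass at `0.4 * fs_out` is applied before
#' decimating to `fs_out` (the nominal low-pass alone would not prevent
#' aliasing when it exceeds the output Nyquist frequency).
#'
#' Triggers whose artifact or context window extends beyond the series are
#' skipped with a warning.
#'
#' @param x Numeric LFP trace.
#' @param fs Sampling rate of `x` in Hz.
#' @param triggers Trigger onset times in seconds.
#' @param artifact_ms Artifact duration after each trigger (ms).
#' @param context_ms Flank length used for the spline fit (ms).
#' @param lowpass_hz Low-pass corner frequency (Hz).
#' @param fs_out Output sampling rate (Hz); `fs / fs_out` must be an
#'   integer.
#' @return Numeric vector sampled at `fs_out`.
#' @export
clean_lfp <- function(x, fs, triggers = numeric(0), artifact_ms = 60,
                      context_ms = 35, lowpass_hz = 100, fs_out = 50) {
  x <- as.numeric(x)
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  n <- length(x)
  alen <- max(1L, round(artifact_ms / 1000 * fs))
  clen <- max(2L, round(context_ms / 1000 * fs))
  for (tt in sort(triggers)) {
    a0 <- floor(tt * fs) + 1L
    a1 <- a0 + alen - 1L
    if (a0 < 1L + clen || a1 > n - clen) {
      warning(sprintf("trigger at %.4f s skipped: window outside the series", tt),
              call. = FALSE)
      next
    }
    # step 1: endpoint-to-endpoint linear interpolation
    x[a0:a1] <- x[a0 - 1L] +
      (x[a1 + 1L] - x[a0 - 1L]) * seq_len(alen) / (alen + 1)
    # step 2: cubic smoothing spline fitted to the flanking context; an
    # exact interpolant through every (noisy) flank sample has noise-driven
    # edge derivatives and swings wildly across the gap, so the spline is
    # penalized (fixed equivalent df), not interpolating
    flank <- c((a0 - clen):(a0 - 1L), (a1 + 1L):(a1 + clen))
    sm <- stats::smooth.spline(flank, x[flank],
                               df = min(10, length(flank) - 4))
    x[a0:a1] <- stats::predict(sm, a0:a1)$y
  }
  if (lowpass_hz < fs / 2)
    x <- zero_phase_lowpass(x, fs, lowpass_hz)
  dec <- fs / fs_out
  if (abs(dec - round(dec)) > 1e-8)
    stop("`fs / fs_out` must be an integer decimation factor", call. = FALSE)
  dec <- as.integer(round(dec))
  if (dec > 1L) {
    aa <- 0.4 * fs_out
    if (aa < min(lowpass_hz, fs / 2))
      x <- zero_phase_lowpass(x, fs, aa)
    x <- x[seq(1L, length(x), by = dec)]
  }
  x
}

zero_phase_lowpass <- function(x, fs, corner) {
  bf <- signal::butter(4, corner / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Zero-phase band-pass filter
#'
#' Order-4 Butterworth filter applied forward and backward
#' (`signal::filtfilt`), so the pass band is phase-neutral. `f_lo = 0`
#' gives a pure low-pass.
#'
#' @param x Numeric vector, or a time-by-node matrix (filtered per column).
#' @param fs Sampling rate in Hz.
#' @param f_lo,f_hi Band edges in Hz, `0 <= f_lo < f_hi < fs / 2`.
#' @return Filtered data with the shape of `x`.
#' @export
bandpass <- function(x, fs, f_lo, f_hi) {
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  if (f_lo < 0 || f_hi <= f_lo || f_hi >= fs / 2)
    stop("band edges must satisfy 0 <= f_lo < f_hi < fs/2", call. = FALSE)
  bf <- if (f_lo == 0) signal::butter(4, f_hi / (fs / 2), type = "low")
        else signal::butter(4, c(f_lo, f_hi) / (fs / 2), type = "pass")
  if (is.matrix(x)) apply(x, 2, function(col)
    as.numeric(signal::filtfilt(bf, col)))
  else as.numeric(signal::filtfilt(bf, as.numeric(x)))
}

#' Regress confound time courses out of node series
#'
#' Ordinary least squares residualization of every node on the confound
#' matrix (an intercept is always included), the standard nuisance step for
#' physiological noise and motion parameters.
#'
#' @param ts Time-by-node matrix.
#' @param confounds Time-by-regressor matrix (same number of rows).
#' @return Residual matrix with the shape of `ts`.
#' @export
regress_confounds <- function(ts, confounds) {
  ts <- as_node_matrix(ts)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(ts))
    stop("confound rows must match the number of time points", call. = FALSE)
  design <- cbind(`(intercept)` = 1, confounds)
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    dropped <- colnames(design)[qd$pivot[-seq_len(qd$rank)]]
    stop("confound design is rank deficient; collinear column(s): ",
         paste(dropped %||% "(unnamed)", collapse = ", "), call. = FALSE)
  }
  res <- stats::lm.fit(design, ts)$residuals
  dimnames(res) <- dimnames(ts)
  res
}

# per-subject session-averaged summaries shared by the cohort analyses
cohort_summaries <- function(cohort, scales, m, r) {
  if (length(cohort) < 4)
    stop("need at least 4 subjects", call. = FALSE)
  stopifnot(all(vapply(cohort, inherits, logical(1), "subject_node_data")))
  n_nodes <- ncol(cohort[[1]]$sessions[[1]])
  if (n_nodes < 2)
    stop("single-node networks have no connections", call. = FALSE)
  lapply(cohort, function(subj) {
    per_sess <- lapply(subj$sessions, function(ses) {
      ent <- suppressWarnings(vapply(seq_len(ncol(ses)), function(j)
        mse_curve(ses[, j], scales = scales, m = m, r = r,
                  fs = subj$fs)$entropy, numeric(length(scales))))
      fc <- suppressWarnings(stats::cor(ses))
      diag(fc) <- NA
      list(mse = t(ent),                       # nodes x scales
           nodal_fc = rowMeans(fc, na.rm = TRUE),
           net_fc = mean(fc[upper.tri(fc)], na.rm = TRUE))
    })
    list(
      mse = Reduce(`+`, lapply(per_sess, `[[`, "mse")) / length(per_sess),
      nodal_fc = Reduce(`+`, lapply(per_sess, `[[`, "nodal_fc")) /
        length(per_sess),
      net_fc = mean(vapply(per_sess, `[[`, numeric(1), "net_fc")),
      fs = subj$fs
    )
  })
}

#' Across-subject correlation of network MSE with network FC
#'
#' Per subject, the network summaries are the session-averaged mean MSE
#' over all nodes (per scale) and the mean of all node-to-node
#' correlations. Across subjects, each scale's network MSE is then
#' correlated with network FC, giving the global
#' complexity-vs-connectivity profile over temporal frequencies.
#'
#' @param cohort List of [subject_node_data()] objects (>= 4) over a
#'   common node set.
#' @param scales Integer MSE scale grid.
#' @param m,r Sample-entropy parameters.
#' @param convention Scale-to-frequency convention for the reported
#'   frequency axis (fMRI cohorts default to `"nyquist"`).
#' @return Data frame with one row per scale: `scale`, `frequency`, `r`,
#'   `p`, `n`. Zero across-subject variance yields `NA` sentinels.
#' @export
network_mse_fc_correlation <- function(cohort, scales = 1:40, m = 2, r = 0.5,
                                       convention = c("nyquist", "direct")) {
  convention <- match.arg(convention)
  summ <- cohort_summaries(cohort, scales, m, r)
  net_mse <- t(vapply(summ, function(s) colMeans(s$mse, na.rm = TRUE),
                      numeric(length(scales))))  # subjects x scales
  net_fc <- vapply(summ, `[[`, numeric(1), "net_fc")
  out <- lapply(seq_along(scales), function(si) {
    pr <- pearson_with_p(net_mse[, si], net_fc)
    data.frame(scale = scales[si],
               frequency = scale_to_frequency(scales[si], summ[[1]]$fs,
                                              convention),
               r = pr$r, p = pr$p, n = pr$n)
  })
  do.call(rbind, out)
}

#' Across-subject correlation of nodal MSE with nodal FC
#'
#' Per subject and node, the session-averaged MSE curve and the node's mean
#' correlation to all other nodes; across subjects, Pearson r and p per
#' node and scale, with a significance mask at `p < alpha`.
#'
#' @inheritParams network_mse_fc_correlation
#' @param alpha Significance level of the mask.
#' @return Long data frame: `node`, `scale`, `frequency`, `r`, `p`,
#'   `significant`.
#' @export
nodal_mse_fc_correlation <- function(cohort, scales = 1:40, m = 2, r = 0.5,
                                     convention = c("nyquist", "direct"),
                                     alpha = 0.05) {
  convention <- match.arg(convention)
  summ <- cohort_summaries(cohort, scales, m, r)
  n_nodes <- nrow(summ[[1]]$mse)
  nodes <- rownames(summ[[1]]$mse) %||% paste0("n", seq_len(n_nodes))
  freq <- scale_to_frequency(scales, summ[[1]]$fs, convention)
  out <- vector("list", n_nodes * length(scales))
  k <- 0
  for (nd in seq_len(n_nodes)) {
    mse_nd <- t(vapply(summ, function(s) s$mse[nd, ],
                       numeric(length(scales))))
    fc_nd <- vapply(summ, function(s) s$nodal_fc[nd], numeric(1))
    for (si in seq_along(scales)) {
      pr <- pearson_with_p(mse_nd[, si], fc_nd)
      k <- k + 1
      out[[k]] <- data.frame(node = nodes[nd], scale = scales[si],
                             frequency = freq[si], r = pr$r, p = pr$p)
    }
  }
  res <- do.call(rbind, out)
  res$significant <- !is.na(res$p) & res$p < alpha
  res
}

#' Extract voxel time series from a 4-D image
#'
#' Treats every in-mask voxel as a node series, so the entropy and
#' connectivity functions apply to volumetric fMRI directly.
#'
#' @param image A 4-D numeric array, or a path to a 4-D NIfTI volume
#'   (requires the RNifti package).
#' @param mask A 3-D logical/numeric array (non-zero = in mask), or a path
#'   to a 3-D NIfTI volume.
#' @return A time-by-voxel matrix; attribute `mask_index` holds the voxel
#'   indices for writing maps back.
#' @export
nifti_node_series <- function(image, mask) {
  image <- read_volume(image, 4)
  mask <- read_volume(mask, 3)
  if (!all(dim(image)[1:3] == dim(mask)))
    stop("mask and image grids differ", call. = FALSE)
  idx <- which(mask != 0)
  nvox <- prod(dim(image)[1:3])
  flat <- matrix(image, nrow = nvox)
  out <- t(flat[idx, , drop = FALSE])
  attr(out, "mask_index") <- idx
  attr(out, "dim3") <- dim(mask)
  out
}

read_volume <- function(x, ndim) {
  if (is.character(x)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI files requires the RNifti package", call. = FALSE)
    x <- as.array(RNifti::readNifti(x))
  }
  if (length(dim(x)) != ndim)
    stop(sprintf("expected a %d-D array", ndim), call. = FALSE)
  x
}

#' Voxelwise MSE maps
#'
#' MSE curve per in-mask voxel, returned as a 4-D array with one volume per
#' scale (out-of-mask voxels are `NA`).
#'
#' @inheritParams nifti_node_series
#' @param scales Integer MSE scale grid.
#' @param m,r Sample-entropy parameters.
#' @return 4-D array `x * y * z * length(scales)`.
#' @export
mse_voxel_map <- function(image, mask, scales = 1:10, m = 2, r = 0.5) {
  ts <- nifti_node_series(image, mask)
  ent <- suppressWarnings(vapply(seq_len(ncol(ts)), function(j)
    mse_curve(ts[, j], scales = scales, m = m, r = r)$entropy,
    numeric(length(scales))))
  d3 <- attr(ts, "dim3")
  out <- array(NA_real_, c(d3, length(scales)))
  nvox <- prod(d3)
  for (si in seq_along(scales)) {
    vol <- rep(NA_real_, nvox)
    vol[attr(ts, "mask_index")] <- ent[si, ]
    out[, , , si] <- vol
  }
  out
}
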