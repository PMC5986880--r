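#' Generate a modular surrogate connectome
#'
#' Seeded random structural connectivity with a block-modular architecture:
#' node pairs within a module connect with probability `p_within`, pairs in
#' different modules with `p_between`, and realized edges get uniform
#' weights in `(0.5, 1] * weight_scale`. The matrix is symmetric with a
#' zero diagonal. The default preset (47 nodes, 5 modules) is the bundled
#' surrogate for a macaque-scale 5-module anatomical matrix, which is not
#' redistributed here.
#'
#' @param n_nodes,n_modules Network size and number of modules (modules are
#'   contiguous, near-equal blocks).
#' @param p_within,p_between Connection probabilities,
#'   `0 <= p_between < p_within <= 1`.
#' @param weight_scale Multiplier on the edge weights.
#' @param seed Optional integer seed.
#' @return A [connectome()] object.
#' @export
gen_modular_connectome <- function(n_nodes = 47, n_modules = 5,
                                   p_within = 0.8, p_between = 0.1,
                                   weight_scale = 1, seed = NULL) {
  if (p_between < 0 || p_within > 1 || p_between >= p_within)
    stop("need 0 <= p_between < p_within <= 1", call. = FALSE)
  if (n_modules > n_nodes)
    stop("more modules than nodes", call. = FALSE)
  modules <- sort(rep_len(seq_len(n_modules), n_nodes))
  with_seed(seed, {
    w <- matrix(0, n_nodes, n_nodes)
    for (i in seq_len(n_nodes - 1)) {
      for (j in (i + 1):n_nodes) {
        p <- if (modules[i] == modules[j]) p_within else p_between
        if (runif(1) < p) {
          w[i, j] <- runif(1, 0.5, 1) * weight_scale
          w[j, i] <- w[i, j]
        }
      }
    }
    connectome(w, modules = paste0("M", modules))
  })
}

#' The bundled default surrogate connectome
#'
#' The package's canonical 47-node, 5-module surrogate structural matrix:
#' a fixed draw of [gen_modular_connectome()] standing in for a
#' macaque-scale anatomical connectome with five structural modules. All
#' bundled experiments (tests, the acceptance analysis, the vignette) use
#' this one matrix, mirroring how a single fixed anatomical matrix anchors
#' the original analyses; it is synthetic, not a redistribution of any
#' anatomical dataset.
#'
#' @return A [connectome()] object.
#' @export
default_connectome <- function() {
  gen_modular_connectome(n_nodes = 47, n_modules = 5, seed = 3)
}

#' Generate colored (1/f^n) Gaussian noise
#'
#' Seeded Gaussian noise whose power spectrum falls as `1/f^exponent`,
#' produced by frequency-domain amplitude shaping of white noise (exact and
#' deterministic). The output is standardized to zero mean and unit
#' variance. `exponent = 0` gives white noise, `exponent = 1` pink noise.
#'
#' @param exponent Spectral slope `n >= 0` of `1/f^n`.
#' @param n Number of samples (>= 16).
#' @param fs Sampling rate in Hz (metadata only).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
gen_colored_noise <- function(exponent, n, fs = 1, seed = NULL) {
  if (exponent < 0) stop("`exponent` must be >= 0", call. = FALSE)
  if (n < 16) stop("`n` must be >= 16", call. = FALSE)
  with_seed(seed, {
    w <- rnorm(n)
    if (exponent == 0) return(as.numeric(scale(w)) * sqrt(n / (n - 1)))
    spec <- stats::fft(w)
    f <- c(1e-12, seq_len(n - 1)) # bin frequencies up to a constant factor
    f <- pmin(f, n - f)           # fold to the Nyquist mirror
    amp <- f^(-exponent / 2)
    amp[1] <- 0                   # remove DC
    x <- Re(stats::fft(spec * amp, inverse = TRUE)) / n
    (x - mean(x)) / pop_sd(x)
  })
}

#' Inject MR-trigger artifacts into an LFP-like trace
#'
#' Adds high-amplitude, fast-alternating segments after periodic slice
#' triggers, emulating gradient-switching artifacts in concurrent LFP/MRI
#' recordings, and returns the clean ground truth alongside so the
#' scrubbing pipeline can be validated against it.
#'
#' @param base Numeric baseline trace (the ground truth).
#' @param fs Sampling rate in Hz.
#' @param trigger_period_s Trigger spacing in seconds (must exceed the
#'   artifact duration).
#' @param artifact_ms Artifact duration per trigger (ms).
#' @param amplitude Peak artifact amplitude (> 0), e.g. volts.
#' @param seed Optional integer seed for the artifact waveform.
#' @return List with `signal` (contaminated trace), `triggers` (onset
#'   times, seconds), and `clean` (the untouched baseline).
#' @export
gen_lfp_with_artifacts <- function(base, fs, trigger_period_s,
                                   artifact_ms = 60, amplitude = 5,
                                   seed = NULL) {
  if (amplitude <= 0) stop("`amplitude` must be positive", call. = FALSE)
  if (trigger_period_s <= artifact_ms / 1000)
    stop("trigger period must exceed the artifact duration", call. = FALSE)
  base <- as.numeric(base)
  n <- length(base)
  alen <- max(1L, round(artifact_ms / 1000 * fs))
  triggers <- seq(trigger_period_s, n / fs - trigger_period_s / 2,
                  by = trigger_period_s)
  x <- base
  with_seed(seed, {
    for (tt in triggers) {
      a0 <- floor(tt * fs) + 1L
      a1 <- min(a0 + alen - 1L, n)
      len <- a1 - a0 + 1L
      # fast-alternating high-amplitude burst
      burst <- amplitude * sign(rnorm(len)) * runif(len, 0.5, 1)
      x[a0:a1] <- x[a0:a1] + burst
    }
    list(signal = x, triggers = triggers, clean = base)
  })
}

#' Canonical double-gamma hemodynamic response kernel
#'
#' @param fs Sampling rate of the kernel in Hz.
#' @param duration_s Kernel length in seconds.
#' @param peak,undershoot Shape parameters (seconds to peak/undershoot).
#' @param ratio Undershoot amplitude relative to the peak.
#' @return Numeric kernel sampled at `fs`, unit peak.
#' @export
hrf_kernel <- function(fs, duration_s = 32, peak = 6, undershoot = 16,
                       ratio = 1 / 6) {
  t <- seq(0, duration_s, by = 1 / fs)
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot, rate = 1)
  h / max(h)
}

#' Convolve neural series with a hemodynamic kernel and resample to TR
#'
#' Bridges fast simulated activity to BOLD-like series: each node is
#' convolved with the kernel (causal convolution, output aligned to the
#' input onset) and then decimated to one sample per `TR`.
#'
#' @param ts Time-by-node matrix of neural activity.
#' @param fs Sampling rate of `ts` in Hz.
#' @param TR Output repetition time in seconds (>= `1 / fs`).
#' @param kernel Hemodynamic kernel sampled at `fs`; defaults to
#'   [hrf_kernel()].
#' @return Time-by-node matrix with `floor(nrow(ts) / (TR * fs))` rows.
#' @export
gen_bold_like <- function(ts, fs, TR, kernel = NULL) {
  ts <- as_node_matrix(ts)
  if (TR < 1 / fs) stop("`TR` must be >= 1/fs", call. = FALSE)
  kernel <- kernel %||% hrf_kernel(fs)
  if (length(kernel) > nrow(ts))
    stop("kernel longer than the series", call. = FALSE)
  dec <- TR * fs
  if (abs(dec - round(dec)) > 1e-8)
    stop("`TR * fs` must be an integer decimation factor", call. = FALSE)
  dec <- as.integer(round(dec))
  conv <- apply(ts, 2, function(col)
    stats::convolve(col, rev(kernel), type = "open")[seq_along(col)])
  conv[seq(1L, nrow(ts), by = dec), , drop = FALSE]
}

#' Generate a multi-subject cohort with coupled complexity and connectivity
#'
#' Emulates the statistical structure assumed by the across-subject
#' analyses: every node's series is a subject-shared low-frequency
#' component plus a node-local high-frequency component plus white noise.
#' A per-subject factor `g` scales the shared slow component up and the
#' local fast component down (strength set by `coupling`), so subjects
#' with larger `g` have higher functional connectivity, higher
#' coarse-scale entropy, and lower fine-scale entropy — a positive
#' MSE-FC correlation at coarse scales turning negative at the finest
#' scales. With `coupling = 0` the amplitudes are constant across subjects
#' and no systematic association remains.
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param n_nodes Nodes per subject.
#' @param TR Repetition time in seconds.
#' @param n_timepoints Samples per session.
#' @param n_sessions Sessions per subject (each a fresh realization).
#' @param shared_band Low-frequency band (Hz) of the shared component.
#' @param local_band High-frequency band (Hz) of the node-local component.
#' @param coupling Coupling strength in `[0, 1]`.
#' @param noise_sd SD of the added white noise.
#' @param seed Optional integer seed.
#' @return List of [subject_node_data()] objects.
#' @export
gen_coupled_cohort <- function(n_subjects = 30, n_nodes = 20, TR = 0.72,
                               n_timepoints = 1200, n_sessions = 2,
                               shared_band = c(0.020, 0.087),
                               local_band = c(0.347, 0.694),
                               coupling = 1, noise_sd = 0.3, seed = NULL) {
  if (n_subjects < 4) stop("need at least 4 subjects", call. = FALSE)
  fs <- 1 / TR
  nyq <- fs / 2
  if (shared_band[2] > nyq || local_band[2] > nyq)
    stop("band edges must lie below the Nyquist frequency 1/(2 TR)",
         call. = FALSE)
  if (coupling < 0 || coupling > 1)
    stop("`coupling` must be in [0, 1]", call. = FALSE)
  with_seed(seed, {
    g <- runif(n_subjects, 0.5, 1.5)
    lapply(seq_len(n_subjects), function(si) {
      amp_shared <- 1 + coupling * (g[si] - 1)
      amp_local <- 1 - coupling * (g[si] - 1)
      sessions <- lapply(seq_len(n_sessions), function(ss) {
        shared <- band_noise(n_timepoints, fs, shared_band)
        sapply(seq_len(n_nodes), function(nd)
          amp_shared * shared +
            amp_local * band_noise(n_timepoints, fs, local_band) +
            noise_sd * rnorm(n_timepoints))
      })
      subject_node_data(id = sprintf("s%02d", si), sessions = sessions,
                        TR = TR)
    })
  })
}

# unit-variance Gaussian noise band-limited by spectral masking
band_noise <- function(n, fs, band) {
  w <- rnorm(n)
  spec <- stats::fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  keep <- f >= band[1] & f <= band[2]
  spec[!keep] <- 0
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- pop_sd(x)
  if (s == 0) stop("band too narrow for the series length", call. = FALSE)
  (x - mean(x)) / s
}
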