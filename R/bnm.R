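#' Parameters of the conductance-based neural-mass node
#'
#' Default constants of the mean-field model of a local population of
#' coupled excitatory and inhibitory neurons: sigmoidal voltage-dependent
#' calcium and sodium conductances, a potassium conductance that relaxes
#' exponentially toward its voltage-dependent equilibrium, passive leak,
#' local excitatory<->inhibitory coupling, an NMDA fraction of the
#' excitatory synaptic current, and a constant non-specific input. Values
#' follow the published chaotic mean-field parameter regime for this model
#' family; any constant can be overridden by name.
#'
#' The excitatory-to-excitatory gain `aee` is not a constant here: it is
#' the swept argument of [simulate_bnm()]. It multiplies the total
#' excitatory drive, of which a fixed fraction `gc` is the long-range
#' (connectome-weighted, row-normalized) input and `1 - gc` the node's own
#' recurrent firing, so raising `aee` both enriches the local dynamics
#' (through the regular-to-chaotic transition of the node) and strengthens
#' inter-node coupling without ever locking the network into full
#' synchrony.
#'
#' @param ... Named overrides of individual constants.
#' @return A named numeric vector of model constants.
#' @export
bnm_params <- function(...) {
  p <- c(
    gCa = 1,    VCa = 1,    TCa = -0.01, dCa = 0.15,
    gK  = 2,    VK  = -0.7, TK  = 0,     dK  = 0.3,
    gNa = 6.7,  VNa = 0.53, TNa = 0.3,   dNa = 0.15,
    gL  = 0.5,  VL  = -0.5,
    VT  = 0,    dV  = 0.65, ZT  = 0,     dZ  = 0.65,
    QVmax = 1,  QZmax = 1,
    aei = 2,    aie = 2,
    ane = 1,    ani = 0.4,  rNMDA = 0.25,
    b = 0.1,    phi = 0.7,  tau = 1,     I = 0.3,
    aee_l = 0.36, aee_s = 0, gc = 0.33
  )
  ov <- c(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown))
      stop("unknown model constant(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(ov)] <- ov
  }
  p
}

#' Time-derivatives of the neural-mass network state
#'
#' Right-hand side of the coupled node equations, mainly useful for
#' fixed-point and finite-difference checks. The coupling input to node
#' \eqn{i} is the row-normalized connectome-weighted mean firing rate of the
#' other nodes, scaled by `aee`.
#'
#' @param state Numeric `n x 3` matrix with columns `V` (excitatory
#'   potential), `Z` (inhibitory potential), `W` (open potassium-channel
#'   proportion).
#' @param conn A [connectome()] object (or `n x n` weight matrix).
#' @param aee Long-range excitatory-to-excitatory gain.
#' @param params Model constants from [bnm_params()].
#' @return `n x 3` matrix of derivatives (per model time unit).
#' @export
bnm_derivatives <- function(state, conn, aee, params = bnm_params()) {
  K <- normalize_rows(if (inherits(conn, "connectome")) conn$weights else conn)
  state <- as.matrix(state)
  if (ncol(state) != 3 || nrow(state) != nrow(K))
    stop("`state` must be an n x 3 matrix matching the connectome",
         call. = FALSE)
  if (any(!is.finite(state)))
    stop("non-finite state", call. = FALSE)
  d <- cpp_bnm_deriv(state, K, aee, params)
  dimnames(d) <- list(rownames(K), c("V", "Z", "W"))
  d
}

normalize_rows <- function(w) {
  rs <- rowSums(w)
  rs[rs == 0] <- 1
  w / rs
}

#' Simulate a neural-mass brain-network model
#'
#' Stochastic (Euler–Maruyama) integration of conductance-based neural-mass
#' nodes coupled through a structural connectome. The long-range excitatory
#' input to each node is the connectome-row-weighted mean firing rate of
#' the network (rows normalized to unit in-strength) scaled by `aee`, so
#' `aee` is comparable across connectomes of any size or density. Coupling
#' is instantaneous (no transmission delays). The recorded output is the
#' excitatory mean-field firing rate \eqn{Q_V} of each node.
#'
#' Integration runs at `substeps` Euler steps per output sample
#' (`dt = 1 / (substeps * fs)` seconds) and is decimated to `fs`; the first
#' `burn_in` seconds are discarded. Additive noise is a Wiener increment on
#' the excitatory potential with standard deviation `noise * sqrt(dt)` per
#' step; with `noise = 0` the integration never touches the random number
#' generator and is bit-reproducible regardless of `seed`.
#'
#' The model time unit is arbitrary; `time_scale` fixes how many model time
#' units elapse per second of output. The default (20) places the model's
#' spontaneous oscillation in the delta frequency range at the nominal
#' 200 Hz output rate, so that the 1–400 scale grid of the sweep experiment
#' brackets the dynamics.
#'
#' @param conn A [connectome()] object.
#' @param aee Long-range excitatory-to-excitatory gain (typically 0–0.55).
#' @param n_samples Number of output samples per node.
#' @param fs Output sampling rate in Hz.
#' @param noise Additive volatility of the excitatory equation (per
#'   square-root second); 0 disables noise.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @param burn_in Seconds of initial transient to discard.
#' @param substeps Euler steps per output sample.
#' @param time_scale Model time units per second of output.
#' @param params Node constants from [bnm_params()].
#' @param init Optional `n x 3` initial state; by default node states are
#'   drawn from a small seeded uniform perturbation around a common
#'   operating point so the nodes desynchronize naturally.
#' @return An object of class `"bnm_sim"`: list with `series` (matrix,
#'   `n_samples` rows x nodes columns, the firing-rate output), `fs`,
#'   `aee`, `noise`, `seed`, `modules` and `params`.
#' @export
simulate_bnm <- function(conn, aee, n_samples = 10000, fs = 200,
                         noise = 0.001, seed = NULL, burn_in = 2,
                         substeps = 10, time_scale = 20,
                         params = bnm_params(), init = NULL) {
  stopifnot(inherits(conn, "connectome"))
  stopifnot_scalar_number(aee, "aee")
  if (aee < 0) stop("`aee` must be non-negative", call. = FALSE)
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  stopifnot_scalar_number(noise, "noise")
  if (noise < 0) stop("`noise` must be non-negative", call. = FALSE)
  if (n_samples < 1) stop("`n_samples` must be >= 1", call. = FALSE)
  n <- length(conn$names)
  K <- normalize_rows(conn$weights)
  dt_s <- 1 / (substeps * fs)
  dt_model <- time_scale * dt_s
  burn_steps <- as.integer(round(burn_in * fs * substeps))
  # noise volatility is specified per sqrt(second)
  step_sd <- noise * sqrt(dt_s)

  series <- with_seed(seed, {
    st <- init %||% default_init(n)
    if (!is.matrix(st) || any(dim(st) != c(n, 3)))
      stop("`init` must be an n x 3 matrix", call. = FALSE)
    cpp_bnm_integrate(K, aee, st, as.integer(n_samples),
                      as.integer(substeps), dt_model, step_sd,
                      burn_steps, params)
  })
  colnames(series) <- conn$names
  structure(
    list(series = series, fs = fs, aee = aee, noise = noise, seed = seed,
         modules = conn$modules, params = params),
    class = "bnm_sim"
  )
}

# operating point of the uncoupled node (rest state of the noise-free
# equations at the default constants) plus a uniform perturbation
default_init <- function(n) {
  cbind(V = -0.2 + runif(n, -0.1, 0.1),
        Z = -0.1 + runif(n, -0.1, 0.1),
        W = 0.3 + runif(n, -0.05, 0.05))
}

#' @export
print.bnm_sim <- function(x, ...) {
  cat("Neural-mass network simulation:", ncol(x$series), "nodes x",
      nrow(x$series), "samples at", x$fs, "Hz\n")
  cat("  aee =", x$aee, ", noise =", x$noise, "\n")
  invisible(x)
}
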