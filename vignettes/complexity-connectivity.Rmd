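---
title: "Linking multi-scale entropy to functional connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking multi-scale entropy to functional connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`msefc` implements a computational chain that relates the *complexity* of a
regional neural signal — quantified by multi-scale entropy (MSE) — to the
*functional connectivity* (FC) of the network the region belongs to. The
chain has four stages: entropy estimation, network simulation, association
statistics, and the cohort-level analyses used for electrophysiology and
fMRI series. A seeded synthetic-data module generates every input the other
stages need, so the whole pipeline is testable without any external
recordings.

```{r setup}
library(msefc)
```

## Entropy estimators

Sample entropy (`sample_entropy`) is the negative log conditional
probability that two length-`m` subsequences that match within a Chebyshev
tolerance still match when extended to length `m + 1`. Self-matches are
excluded, both template sets run over the first `N - m` positions (the
standard bookkeeping that keeps the numerator and denominator comparable),
and the tolerance is `r` times the *population* standard deviation of the
series. Approximate entropy (`approximate_entropy`) is the
`Phi(m) - Phi(m + 1)` variant that includes self-matches; it is always
finite but biased toward regularity, and is provided mainly for
completeness and comparison.

Multi-scale entropy (`mse_curve`) evaluates sample entropy on
coarse-grained copies of the signal: scale `s` replaces the series by the
means of consecutive non-overlapping blocks of `s` samples (trailing
remainder dropped, no overlap, no interpolation). Two conventions matter
and are deliberate:

* **Tolerance anchor.** The matching tolerance is anchored to the SD of
  the *original* (scale-1) series at every scale. Coarse-graining shrinks
  the variance of uncorrelated noise, so re-estimating the SD per scale
  would hide exactly the effect MSE is meant to expose. With the fixed
  anchor, white noise shows the canonical entropy decrease toward coarse
  scales while 1/f-like signals stay comparatively flat — both properties
  are asserted in the test suite on 20,000-sample seeded signals.
* **Undefined values.** When no template pair matches (or a scale leaves
  fewer than `m + 2` points), the estimate is undefined. We return a typed
  `NA` sentinel — never infinity — and band averages skip undefined scales
  with a warning. A constant series is defined to have entropy 0
  (perfect regularity), bypassing the zero-tolerance division.

For a series of 10,000 low-noise samples, pattern length `m = 3` with
tolerance `r = 0.2` is appropriate; shorter and noisier experimental
series use `m = 2`, `r = 0.5`. These are the defaults used by the sweep
and the cohort analyses respectively.

### Scales and frequencies

A coarse-graining scale `s` at sampling rate `fs` is mapped to a
representative temporal frequency by one of two conventions
(`scale_to_frequency`): the **direct** convention `f = fs / s` (the
sampling rate of the coarse-grained series; used for the simulation stage,
where scales 1–400 at 200 Hz span 200–0.5 Hz) and the **nyquist**
convention `f = fs / (2 s)` (the highest frequency the coarse-grained
series can represent; the natural reading for slow fMRI series, where
scales 1–2 at TR = 0.72 s map to 0.694–0.347 Hz). Both conventions appear
in practice and the choice is an explicit argument throughout.

Band averages (`band_average_mse`) take the unweighted mean of the defined
entropy values over the integer scales mapping into a band. Where two
configured bands share an edge (delta ends at 4 Hz where theta begins) the
boundary scale is assigned to the lower-frequency band — a deterministic
tie-break implemented by excluding the lower edge of the higher band
(`band_edge_rule`). The narrow high-delta band (2.7–4 Hz) exists so that a
delta-range average uses roughly as many integer scales as the other
bands; both broad and narrow delta are always computed.

## The network simulator

`simulate_bnm` integrates a network of conductance-based neural-mass
nodes coupled through a structural connectome. Each node carries three
state variables: the mean excitatory membrane potential `V`, the mean
inhibitory potential `Z`, and the proportion `W` of open potassium
channels. Calcium and sodium conductances follow sigmoidal
voltage-dependent activation; the potassium conductance relaxes
exponentially toward its voltage-dependent equilibrium; mean firing rates
`Q_V`, `Q_Z` are sigmoids of the potentials. The recorded output is the
excitatory firing rate `Q_V`, which plays the role of a nodal "spike
train". Default constants are the published chaotic mean-field regime for
this model family and live in one place (`bnm_params`), so any re-tuning
is explicit and versioned.

### The swept coupling gain

The swept argument `aee` is the excitatory-to-excitatory gain. The total
excitatory drive to node `i` is

```
exc_i = (aee_l + aee_s * aee) * Q_V[i]  +  gc * aee * (K Q_V)[i]
```

with `K` the connectome row-normalized to unit in-strength (so `aee` is
comparable across connectomes of any size or density), `aee_l = 0.36` the
within-node recurrent gain, `aee_s = 0` by default, and `gc = 0.33` the
long-range attenuation. Raising `aee` therefore strengthens the
*between-node* excitatory current. Two failure modes bracketed the choice
of `gc`, measured during calibration on repeated sweeps at several master
seeds:

* with `gc` at 0.4 and above, a fraction of high-`aee` realizations falls
  into a strongly synchronized attractor (mean FC jumping above ~0.5 with
  mean MSE *dropping*, because the synchronized attractor is simpler than
  the desynchronized one); these runs anti-correlate complexity and
  connectivity and can erase the across-run association;
* with `gc` well below 0.3 the network barely couples and the FC gradient
  across the sweep range flattens toward zero.

`gc = 0.33` keeps every run below the synchronized attractor across
`aee` in [0, 0.55] (mean FC rising smoothly from ~0 to ~0.3–0.45) while
both mean MSE and mean FC increase with `aee` — the regime in which
regional complexity and network connectivity are two expressions of the
same coupling strength. Coupling is instantaneous: no transmission delays.

### Integration, noise and time units

Integration is Euler–Maruyama at `substeps = 10` steps per output sample
(`dt = 1 / (10 fs)` seconds), decimated to `fs`; the first `burn_in = 2`
seconds are discarded. Additive noise is a Wiener increment on the
excitatory equation with per-step SD `noise * sqrt(dt)` (volatility per
square-root second, default 0.001); with `noise = 0` the random number
generator is never touched, so noise-free runs are bit-reproducible and
seed-independent — a property the test suite asserts, along with
trajectory boundedness across the sweep range and an order-`h` agreement
between the integrator and the analytic right-hand side
(`bnm_derivatives`).

The model equations have an arbitrary time unit; `time_scale` fixes how
many model time units elapse per second of output. The intrinsic
oscillation of the uncoupled node sits at ~0.09–0.10 cycles per model
unit (measured on noise-free runs); the default `time_scale = 20` places
it at ~2 Hz, i.e. in the delta range of the nominal 200 Hz output — the
part of the spectrum where the band-resolved analyses of this pipeline
concentrate. The choice of output unit does not affect any dimensionless
result (correlations across runs); it determines which named frequency
band the dynamics fall into.

Initial conditions are drawn per node from a small seeded uniform
perturbation around the model's operating point, so identical nodes
desynchronize naturally. Divergent integrations raise an error naming the
step and `aee`; the sweep records such runs as failed and excludes them
rather than re-drawing, keeping the `aee` sampling unbiased.

## The coupling-strength sweep

`run_sweep` repeats the simulation `n_runs` times (default 50), drawing
`aee` uniformly from [0, 0.55] under a master seed; per-run seeds are
derived from the master seed so runs are independent and individually
reproducible. Per run it computes every node's MSE curve (tolerance
anchored to that node's scale-1 series), the full-scale mean over scales
1–400 and nodes, per-module means (nodes within the module only), band
averages under the direct mapping, and mean off-diagonal FC (whole network
and within modules). `associate_sweep` then fits every MSE-vs-FC pairing
with `pearson_with_p` and `fit_linear_quadratic`.

Two conventions resolve ambiguities that arise here:

* the full-scale average includes scale 1 (the raw series) even though
  coarse-graining proper starts at scale 2 — the curve is defined on
  1–400 and the scale-1 value is simply the sample entropy of the raw
  series;
* "best fit by a quadratic function" is adjudicated by the nested-model
  F-test at significance level 0.05, an exact and standard criterion for
  nested least-squares fits.

## Association statistics

`pearson_with_p` uses the t-transform with `n - 2` degrees of freedom.
`partial_correlation` controls a grouping factor (e.g. repeated
measurements within animals) by removing group means from both variables —
equivalent to dummy-coded least squares — and uses `n - k - 1` degrees of
freedom for `k` groups; groups with a single observation carry no
within-group information and are dropped with a warning. Zero-variance
inputs yield `NA` sentinels rather than errors wherever a degenerate value
can arise from data (rather than from a misuse of the API).

## Imaging-stage preprocessing

`clean_lfp` scrubs trigger-locked MR artifacts from electrophysiological
traces in the order: linear interpolation of each 60 ms post-trigger
segment, replacement by a cubic spline fitted on 35 ms flanks, zero-phase
low-pass at 100 Hz, decimation to 50 Hz. Two numerical caveats are handled
explicitly. First, the spline is a *smoothing* spline (penalized, fixed
equivalent degrees of freedom) rather than an exact interpolant: raw LFP
flanks carry wide-band noise, and an interpolant's edge derivatives are
noise-driven, which makes its reconstruction swing wildly across a 60 ms
gap. Second, a
100 Hz low-pass does not prevent aliasing when decimating to
50 Hz (output Nyquist 25 Hz), so an additional anti-alias low-pass at
`0.4 * fs_out` is applied before decimation. Filters are order-4
Butterworth run forward and backward (`signal::filtfilt`), hence
phase-neutral; `bandpass` exposes the same filter for band-limited
analyses. `regress_confounds` removes nuisance regressors (physiological
noise, motion and derivatives) by ordinary least squares with an intercept
always included; rank-deficient designs fail loudly, naming the collinear
columns.

The across-subject analyses (`network_mse_fc_correlation`,
`nodal_mse_fc_correlation`) compute per subject and session the nodal MSE
curves and FC summaries, average across sessions (computed per session
first, then averaged — not concatenated), and correlate MSE against FC
across subjects per scale (and per node for the nodal variant), with a
significance mask at p < 0.05. "Network FC" is the mean over *all*
node pairs; when several networks are combined into one node set, all
between-network pairs count as well. Volumetric input is supported by
treating every in-mask voxel as a node (`nifti_node_series`,
`mse_voxel_map`).

## Synthetic data

The generators are first-class, seeded, pure functions of their arguments:

* `gen_modular_connectome` — block-modular weighted graphs; the default
  47-node, 5-module preset is the bundled surrogate for a macaque-scale
  anatomical matrix with five structural modules (the original matrix is
  not redistributed with the package).
* `gen_colored_noise` — `1/f^n` Gaussian noise by frequency-domain
  amplitude shaping; exact, fast, and used for the white/pink reference
  signatures.
* `gen_lfp_with_artifacts` — injects high-amplitude fast-alternating
  bursts after periodic triggers and returns the clean ground truth, so
  `clean_lfp` can be validated against a known answer.
* `gen_bold_like` — convolution with a double-gamma hemodynamic kernel
  (`hrf_kernel`; any kernel may be supplied) and decimation to TR.
* `gen_coupled_cohort` — multi-subject node series in which a shared
  low-frequency component (0.020–0.087 Hz at TR = 0.72 s) scales *up*
  with a latent subject factor while node-local high-frequency components
  (0.347–0.694 Hz) scale *down*. By construction, subjects with a larger
  factor have higher FC, higher coarse-scale MSE and lower fine-scale
  MSE, which induces the coarse-positive / fine-negative sign pattern of
  the across-subject analyses. With `coupling = 0` the construction is
  exactly decoupled and significant correlations occur at the nominal
  rate.

One transitional detail is worth knowing: under the Nyquist mapping at
TR = 0.72 s the local high-frequency band spans scales 1–2, but two-point
coarse-graining strongly attenuates the upper half of that band, so the
negative across-subject correlation is strongest at scale 1 and crosses
zero near scale 2. Tests therefore assert the sign at the finest scale
and in the shared low-frequency range, not at the transitional scale.

What the generators do *not* emulate: realistic MR noise, biophysically
detailed hemodynamics (balloon-type models), head motion, or anatomical
variability across subjects. Passing tests on these fixtures demonstrates
that the estimators and analyses recover structure that is genuinely
present; it does not certify performance on real recordings with
artifacts outside this model class.

## Problem sizes and runtime choices

The package's own experiments run at what a single CPU core handles
comfortably: sweeps of 12–50 runs with 5,000 output samples per node on
the 47-node surrogate (the full-scale configuration of 50 runs of 10,000
samples behaves identically and simply takes proportionally longer),
MSE grids of 1–400 for the simulation stage and 1–40 for cohort series,
and cohorts of 20–30 subjects with 1,200 time points over 1–2 sessions.
Entropy template counting and the stochastic integrator are implemented
in C++ (via Rcpp); both are exact algorithms, not approximations — the
test suite pins them to brute-force R oracles to 1e-10.

## Known limitations

* The sweep's band-resolved correlations are stochastic functionals of a
  chaotic simulation: with 12-run sweeps their rank order fluctuates
  between seeds, and stable band rankings need run counts near the
  full-scale configuration.
* Sample entropy is undefined (NA) when no templates match; very short or
  very regular series at strict tolerances produce patchy MSE curves, and
  band averages then rest on few scales.
* `partial_correlation` models the group effect as a mean shift only; a
  group-specific slope would require an interaction model outside this
  package's scope.
* The simulator's constants are a single published operating regime;
  conclusions about other regimes (e.g. strong-delay loops, heterogeneous
  nodes) are out of scope, as are lagged cross-correlations, sliding-window
  FC and graph-theoretic summaries.
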