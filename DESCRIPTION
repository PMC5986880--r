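Package: msefc
Title: Multi-Scale Entropy and Functional Connectivity of Neural Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools linking the complexity of regional neural signals to
    network functional connectivity. Provides approximate entropy, sample
    entropy and coarse-grained multi-scale entropy (MSE) with
    frequency-band summaries; a stochastic conductance-based neural-mass
    network simulator coupled through a structural connectome; Pearson and
    partial correlation with linear/quadratic model comparison; a
    coupling-strength sweep experiment relating per-run mean MSE to mean
    functional connectivity; preprocessing for concurrent
    electrophysiology and fMRI series (trigger-artifact scrubbing,
    confound regression, zero-phase band-pass); and seeded generators for
    modular connectomes, colored noise, artifact-laden local field
    potential traces and multi-subject BOLD-like cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    RNifti,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
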