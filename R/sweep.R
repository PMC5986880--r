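#' Configuration of the coupling-strength sweep
#'
#' Settings for repeated network simulations with the long-range excitatory
#' gain drawn uniformly at random, the experiment linking per-run mean MSE
#' to mean functional connectivity. Defaults are the full-scale settings
#' (50 runs, 10,000 samples at 200 Hz, MSE with m = 3 and r = 0.2 over
#' scales 1–400, additive noise volatility 0.001, Aee in [0, 0.55]).
#'
#' @param n_runs Number of simulation runs (>= 2).
#' @param aee_range Lower and upper bound of the uniform Aee draw.
#' @param m,r Sample-entropy pattern length and tolerance fraction.
#' @param scales Integer scale grid of the MSE curve.
#' @param fs Output sampling rate in Hz.
#' @param n_samples Output samples per node and run.
#' @param noise Additive volatility of the simulator.
#' @param bands Frequency-band table (`name`, `f_lo`, `f_hi`), as from
#'   [default_bands()].
#' @param seed Master seed; per-run streams are derived from it by run
#'   index so runs are independent and individually reproducible.
#' @param burn_in,substeps,time_scale Passed to [simulate_bnm()].
#' @return A list of class `"sweep_config"`.
#' @export
sweep_config <- function(n_runs = 50, aee_range = c(0, 0.55),
                         m = 3, r = 0.2, scales = 1:400, fs = 200,
                         n_samples = 10000, noise = 0.001,
                         bands = default_bands(), seed = 1,
                         burn_in = 2, substeps = 10, time_scale = 20) {
  if (n_runs < 2) stop("`n_runs` must be >= 2", call. = FALSE)
  if (length(aee_range) != 2 || aee_range[1] < 0 ||
      aee_range[2] < aee_range[1])
    stop("`aee_range` must be 0 <= lo <= hi", call. = FALSE)
  check_entropy_params(m, r)
  if (!is.null(bands)) {
    stopifnot(is.data.frame(bands),
              all(c("name", "f_lo", "f_hi") %in% names(bands)))
    if (anyDuplicated(bands$name))
      stop("band names must be unique", call. = FALSE)
  }
  structure(
    list(n_runs = as.integer(n_runs), aee_range = aee_range, m = m, r = r,
         scales = as.integer(scales), fs = fs,
         n_samples = as.integer(n_samples), noise = noise, bands = bands,
         seed = seed, burn_in = burn_in, substeps = substeps,
         time_scale = time_scale),
    class = "sweep_config"
  )
}

# a band's lower edge is excluded when an adjacent band in the set ends
# exactly there, so boundary scales go to the lower-frequency band
band_edge_rule <- function(bands) {
  vapply(seq_len(nrow(bands)), function(i) {
    if (any(bands$f_hi[-i] == bands$f_lo[i])) "exclude" else "include"
  }, character(1))
}

#' Run the coupling-strength sweep
#'
#' For each run: draw Aee uniformly from `cfg$aee_range`, simulate the
#' network, compute every node's MSE curve (tolerance anchored to each
#' node's scale-1 series), and summarize: mean MSE over all nodes and
#' scales (`mse_full`), per structural module (nodes within the module
#' only), and per frequency band (scale-to-frequency mapping `f = fs / s`);
#' mean off-diagonal FC over the whole network (`fc_whole`) and within each
#' module. Runs whose integration diverges are excluded from the table with
#' a message rather than re-drawn, keeping the Aee sampling unbiased.
#'
#' @param conn A [connectome()] object.
#' @param cfg A [sweep_config()].
#' @return A data frame of class `"sweep_table"`, one row per completed
#'   run: `run`, `aee`, `mse_full`, `fc_whole`, `mse_mod_*`, `fc_mod_*`
#'   and `mse_band_*` columns. Attribute `failed` lists excluded runs.
#' @export
run_sweep <- function(conn, cfg = sweep_config()) {
  stopifnot(inherits(conn, "connectome"), inherits(cfg, "sweep_config"))
  mods <- levels(conn$modules)
  draws <- with_seed(cfg$seed, {
    list(aee = runif(cfg$n_runs, cfg$aee_range[1], cfg$aee_range[2]),
         run_seed = sample.int(.Machine$integer.max - 1L, cfg$n_runs))
  })
  edge <- if (!is.null(cfg$bands)) band_edge_rule(cfg$bands)
  rows <- vector("list", cfg$n_runs)
  failed <- integer(0)
  for (i in seq_len(cfg$n_runs)) {
    sim <- tryCatch(
      simulate_bnm(conn, aee = draws$aee[i], n_samples = cfg$n_samples,
                   fs = cfg$fs, noise = cfg$noise, seed = draws$run_seed[i],
                   burn_in = cfg$burn_in, substeps = cfg$substeps,
                   time_scale = cfg$time_scale),
      error = function(e) e
    )
    if (inherits(sim, "error")) {
      message(sprintf("run %d (aee = %.3f) excluded: %s",
                      i, draws$aee[i], conditionMessage(sim)))
      failed <- c(failed, i)
      next
    }
    ent <- suppressWarnings(
      vapply(seq_len(ncol(sim$series)), function(j)
        mse_curve(sim$series[, j], scales = cfg$scales, m = cfg$m,
                  r = cfg$r, fs = cfg$fs)$entropy,
        numeric(length(cfg$scales)))
    ) # scales x nodes
    node_full <- colMeans(ent, na.rm = TRUE)
    fc <- fc_matrix(sim)
    row <- data.frame(run = i, aee = draws$aee[i],
                      mse_full = mean(node_full),
                      fc_whole = mean_fc(fc))
    for (mdl in mods) {
      idx <- conn$modules == mdl
      row[[paste0("mse_mod_", mdl)]] <- mean(node_full[idx])
      row[[paste0("fc_mod_", mdl)]] <-
        if (sum(idx) >= 2) mean_fc(fc, idx) else NA_real_
    }
    if (!is.null(cfg$bands)) {
      for (bi in seq_len(nrow(cfg$bands))) {
        bs <- band_scales(cfg$scales, cfg$fs, cfg$bands$f_lo[bi],
                          cfg$bands$f_hi[bi], lower_edge = edge[bi])
        vals <- ent[cfg$scales %in% bs, , drop = FALSE]
        row[[paste0("mse_band_", cfg$bands$name[bi])]] <-
          if (length(bs)) mean(colMeans(vals, na.rm = TRUE)) else NA_real_
      }
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  structure(out, failed = failed, config = cfg,
            class = c("sweep_table", "data.frame"))
}

#' Association analysis of a sweep table
#'
#' Pearson correlation (with p-value) and linear/quadratic fits for every
#' MSE-vs-FC pairing of the sweep: whole-network mean MSE vs mean FC, each
#' module's MSE vs that module's FC, Aee vs each summary, and each
#' band-averaged MSE vs whole-network FC.
#'
#' @param table A [run_sweep()] result (>= 4 rows).
#' @return A data frame, one row per pairing, with columns `x`, `y`, `r`,
#'   `p`, `n`, linear and quadratic coefficients, `quad_better` and
#'   `p_quad`. Degenerate pairings (zero variance) come back as `NA`.
#' @export
associate_sweep <- function(table) {
  if (nrow(table) < 4)
    stop("need at least 4 sweep rows", call. = FALSE)
  cols <- names(table)
  mods <- sub("^mse_mod_", "", grep("^mse_mod_", cols, value = TRUE))
  bands <- sub("^mse_band_", "", grep("^mse_band_", cols, value = TRUE))
  pairs <- list(c("mse_full", "fc_whole"))
  for (mdl in mods)
    pairs <- c(pairs, list(c(paste0("mse_mod_", mdl), paste0("fc_mod_", mdl))))
  for (yv in c("mse_full", "fc_whole"))
    pairs <- c(pairs, list(c("aee", yv)))
  for (mdl in mods)
    pairs <- c(pairs, list(c("aee", paste0("mse_mod_", mdl)),
                           c("aee", paste0("fc_mod_", mdl))))
  for (bd in bands)
    pairs <- c(pairs, list(c(paste0("mse_band_", bd), "fc_whole")))
  res <- lapply(pairs, function(pr) {
    x <- table[[pr[1]]]; y <- table[[pr[2]]]
    fit <- tryCatch(fit_linear_quadratic(x, y), error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(x = pr[1], y = pr[2], r = NA_real_, p = NA_real_,
                        n = sum(is.finite(x) & is.finite(y)),
                        intercept = NA_real_, slope = NA_real_,
                        quad_a0 = NA_real_, quad_a1 = NA_real_,
                        quad_a2 = NA_real_, quad_better = NA,
                        p_quad = NA_real_))
    data.frame(x = pr[1], y = pr[2], r = fit$r, p = fit$p, n = fit$n,
               intercept = unname(fit$linear_fit[1]),
               slope = unname(fit$linear_fit[2]),
               quad_a0 = unname(fit$quad_fit[1]),
               quad_a1 = unname(fit$quad_fit[2]),
               quad_a2 = unname(fit$quad_fit[3]),
               quad_better = fit$quad_better, p_quad = fit$p_quad)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
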