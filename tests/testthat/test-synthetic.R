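test_that("modular connectomes realize the requested block architecture", {
  cn <- gen_modular_connectome(n_nodes = 30, n_modules = 3, p_within = 1,
                               p_between = 0, seed = 61)
  w <- cn$weights
  mods <- as.integer(cn$modules)
  same <- outer(mods, mods, `==`) & row(w) != col(w)
  expect_true(all(w[same] > 0))
  expect_true(all(w[!same & row(w) != col(w)] == 0))
  # determinism
  cn2 <- gen_modular_connectome(n_nodes = 30, n_modules = 3, p_within = 1,
                                p_between = 0, seed = 61)
  expect_identical(cn$weights, cn2$weights)
  expect_error(gen_modular_connectome(p_within = 0.2, p_between = 0.5),
               "p_between < p_within")
})

test_that("realized densities sit within 3 binomial SDs of the probabilities", {
  p_w <- 0.7; p_b <- 0.15
  cn <- gen_modular_connectome(n_nodes = 47, n_modules = 5, p_within = p_w,
                               p_between = p_b, seed = 62)
  w <- cn$weights
  mods <- as.integer(cn$modules)
  ut <- upper.tri(w)
  same <- outer(mods, mods, `==`)
  for (case in list(list(mask = same & ut, p = p_w),
                    list(mask = !same & ut, p = p_b))) {
    n <- sum(case$mask)
    obs <- sum(w[case$mask] > 0)
    expect_lt(abs(obs - n * case$p), 3 * sqrt(n * case$p * (1 - case$p)))
  }
})

test_that("colored noise hits the requested spectral slope", {
  # white: negligible lag-1 autocorrelation
  w <- gen_colored_noise(0, 4096, seed = 63)
  n <- length(w)
  expect_lt(abs(cor(w[-1], w[-n])), 3 / sqrt(n))
  # pink: log-log periodogram slope -1 +/- 0.1
  p <- gen_colored_noise(1, 2^16, seed = 64)
  sp <- stats::spec.pgram(stats::ts(p, frequency = 1), plot = FALSE,
                          taper = 0)
  keep <- sp$freq > 0.001 & sp$freq < 0.4
  slope <- coef(lm(log(sp$spec[keep]) ~ log(sp$freq[keep])))[2]
  expect_lt(abs(slope + 1), 0.1)
  # determinism and standardization
  expect_identical(gen_colored_noise(1, 1024, seed = 9),
                   gen_colored_noise(1, 1024, seed = 9))
  expect_equal(mean(p), 0, tolerance = 1e-12)
  expect_equal(oracle_sd(p), 1, tolerance = 1e-12)
})

test_that("artifact injection touches only the artifact windows", {
  base <- sin(2 * pi * 2 * seq(0, 5, by = 1e-3))[-1]
  lfp <- gen_lfp_with_artifacts(base, fs = 1000, trigger_period_s = 1,
                                amplitude = 5, seed = 65)
  expect_identical(lfp$clean, base)
  changed <- which(lfp$signal != base)
  amask <- integer(0)
  for (tt in lfp$triggers) {
    a0 <- floor(tt * 1000) + 1
    amask <- c(amask, a0:(a0 + 59))
  }
  expect_true(all(changed %in% amask))
  expect_gt(max(abs(lfp$signal - base)), 2) # high amplitude relative to base
  expect_error(gen_lfp_with_artifacts(base, 1000, 1, amplitude = 0),
               "positive")
})

test_that("the BOLD-like transform is a linear convolution sampled at TR", {
  fs <- 10
  n <- 400
  k <- hrf_kernel(fs, duration_s = 20)
  imp <- matrix(0, n, 1); imp[1, 1] <- 1
  out <- gen_bold_like(imp, fs, TR = 0.5, kernel = k)
  expect_equal(nrow(out), n / 5)
  # impulse response reproduces the sampled kernel
  expect_equal(out[1:30, 1], k[seq(1, length.out = 30, by = 5)],
               tolerance = 1e-8)
  # linearity
  set.seed(66)
  a <- matrix(rnorm(n), n, 1); b <- matrix(rnorm(n), n, 1)
  expect_equal(gen_bold_like(a + b, fs, 0.5, k),
               gen_bold_like(a, fs, 0.5, k) + gen_bold_like(b, fs, 0.5, k),
               tolerance = 1e-10)
  expect_error(gen_bold_like(a[1:10, , drop = FALSE], fs, 0.5, k), "longer")
})

test_that("coupled cohorts are reproducible and respect their spec", {
  c1 <- gen_coupled_cohort(n_subjects = 4, n_nodes = 3, n_timepoints = 200,
                           n_sessions = 2, seed = 67)
  c2 <- gen_coupled_cohort(n_subjects = 4, n_nodes = 3, n_timepoints = 200,
                           n_sessions = 2, seed = 67)
  expect_identical(c1[[2]]$sessions[[2]], c2[[2]]$sessions[[2]])
  expect_length(c1, 4)
  expect_equal(dim(c1[[1]]$sessions[[1]]), c(200, 3))
  expect_error(gen_coupled_cohort(n_subjects = 3), "4 subjects")
  expect_error(gen_coupled_cohort(TR = 10), "Nyquist")
})

test_that("strong coupling induces the coarse-positive / fine-negative pattern", {
  cohort <- gen_coupled_cohort(n_subjects = 20, n_nodes = 10,
                               n_timepoints = 600, n_sessions = 1,
                               coupling = 1, seed = 68)
  out <- network_mse_fc_correlation(cohort, scales = c(1, 10, 16, 24))
  # finest scale (highest frequency): inverse association; coarse scales in
  # the shared low-frequency range: positive association
  expect_lt(out$r[out$scale == 1], 0)
  expect_true(all(out$r[out$scale >= 10] > 0))
})

test_that("node series round-trip through delimited text", {
  set.seed(69)
  ts <- matrix(rnorm(60), 20, 3)
  colnames(ts) <- c("roi1", "roi2", "roi3")
  f <- tempfile(fileext = ".csv")
  write_node_series(ts, f, fs = 2)
  back <- read_node_series(f)
  expect_equal(unclass(back), ts, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(attr(back, "fs"), 2)
  expect_equal(colnames(back), colnames(ts))
})
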