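test_that("confound regression residualizes against the design", {
  set.seed(51)
  ts <- matrix(rnorm(200), 50, 4)
  conf <- matrix(rnorm(100), 50, 2)
  res <- regress_confounds(ts, conf)
  # matches the normal-equations oracle
  design <- cbind(1, conf)
  expect_equal(res, oracle_residuals(ts, design), ignore_attr = TRUE,
               tolerance = 1e-10)
  # residuals orthogonal to the design
  expect_lt(max(abs(t(design) %*% res)), 1e-8)
  # a confound equal to a node's series wipes that node out
  res2 <- regress_confounds(ts, ts[, 2])
  expect_lt(max(abs(res2[, 2])), 1e-10)
})

test_that("confounds orthogonal to the data only demean it", {
  set.seed(52)
  ts <- matrix(rnorm(120), 40, 3)
  ts <- sweep(ts, 2, colMeans(ts)) # demean
  conf <- matrix(rnorm(40), 40, 1)
  conf <- conf - mean(conf)
  # orthogonalize the confound against every node
  conf <- conf - ts %*% solve(crossprod(ts), crossprod(ts, conf))
  res <- regress_confounds(ts, conf)
  expect_equal(res, ts, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("rank-deficient confound designs are rejected with the column named", {
  ts <- matrix(rnorm(60), 20, 3)
  conf <- cbind(a = rnorm(20), b = 1:20)
  conf <- cbind(conf, c = conf[, "a"] * 2)
  expect_error(regress_confounds(ts, conf), "collinear.*c")
})

test_that("bandpass keeps in-band tones and rejects out-of-band tones", {
  fs <- 200
  t <- seq(0, 10, by = 1 / fs)
  tone <- function(f) sin(2 * pi * f * t)
  inband <- bandpass(tone(10), fs, 5, 20)
  mid <- abs(inband[500:1500])
  expect_gt(max(mid), 0.95) # amplitude preserved within 5%
  out <- bandpass(tone(80), fs, 2, 8)
  expect_lt(max(abs(out[500:1500])), 0.1) # > 90% attenuation
  expect_error(bandpass(tone(1), fs, 50, 120), "fs/2")
})

test_that("band-passed white noise concentrates its spectrum in band", {
  set.seed(53)
  x <- rnorm(8000)
  fs <- 100
  y <- bandpass(x, fs, 5, 20)
  sp <- stats::spec.pgram(stats::ts(y, frequency = fs), plot = FALSE)
  inband <- sp$freq >= 5 & sp$freq <= 20
  expect_gt(sum(sp$spec[inband]) / sum(sp$spec), 0.8)
})

test_that("clean_lfp with no triggers reduces to filtering and decimation", {
  set.seed(54)
  fs <- 1000
  x <- rnorm(4000)
  y <- clean_lfp(x, fs, triggers = numeric(0), lowpass_hz = 100, fs_out = 50)
  expect_equal(length(y), 200)
  ref <- msefc:::zero_phase_lowpass(x, fs, 100)
  ref <- msefc:::zero_phase_lowpass(ref, fs, 20) # anti-alias at 0.4 * fs_out
  expect_equal(y, ref[seq(1, 4000, by = 20)], tolerance = 1e-10)
})

test_that("clean_lfp recovers the smooth ground truth under artifact windows", {
  fs <- 1000
  t <- seq(0, 8, by = 1 / fs)[-1]
  base <- sin(2 * pi * 3 * t) + 0.5 * sin(2 * pi * 7 * t)
  lfp <- gen_lfp_with_artifacts(base, fs, trigger_period_s = 1.5,
                                amplitude = 5, seed = 55)
  cleaned <- clean_lfp(lfp$signal, fs, lfp$triggers, fs_out = 50)
  truth <- clean_lfp(lfp$clean, fs, numeric(0), fs_out = 50)
  # RMS error over the artifact windows after cleaning
  amask <- rep(FALSE, length(truth))
  for (tt in lfp$triggers) {
    i0 <- floor(tt * 50) + 1
    amask[i0:min(i0 + 3, length(truth))] <- TRUE
  }
  rms <- sqrt(mean((cleaned[amask] - truth[amask])^2))
  expect_lt(rms, 0.1 * oracle_sd(truth))
  # a raw comparison without cleaning fails by a wide margin
  dirty <- clean_lfp(lfp$signal, fs, numeric(0), fs_out = 50)
  rms_dirty <- sqrt(mean((dirty[amask] - truth[amask])^2))
  expect_gt(rms_dirty, 5 * rms)
})

test_that("triggers whose windows leave the series are skipped with a warning", {
  fs <- 1000
  x <- rnorm(1000)
  expect_warning(y <- clean_lfp(x, fs, triggers = 0.999, fs_out = 100),
                 "skipped")
  expect_equal(length(y), 100)
  expect_warning(clean_lfp(x, fs, triggers = 0.001, fs_out = 100), "skipped")
})

test_that("cohort analyses validate their inputs", {
  subj <- function(i) subject_node_data(i, matrix(rnorm(400), 100, 4), TR = 1)
  expect_error(network_mse_fc_correlation(lapply(1:3, subj)), "4 subjects")
  one_node <- lapply(1:5, function(i)
    subject_node_data(i, matrix(rnorm(100), 100, 1), TR = 1))
  expect_error(network_mse_fc_correlation(one_node), "no connections")
})

test_that("identical subjects yield the undefined sentinel", {
  set.seed(56)
  base <- matrix(rnorm(400), 100, 4)
  cohort <- lapply(1:5, function(i) subject_node_data(i, base, TR = 1))
  out <- network_mse_fc_correlation(cohort, scales = 1:5)
  expect_true(all(is.na(out$r)))
})

test_that("decoupled cohorts flag nodes at roughly the nominal 5% rate", {
  cohort <- gen_coupled_cohort(n_subjects = 16, n_nodes = 8,
                               n_timepoints = 400, n_sessions = 1,
                               coupling = 0, seed = 59)
  out <- nodal_mse_fc_correlation(cohort, scales = 1:10)
  rate <- mean(out$significant)
  # 80 node-scale cells at alpha = 0.05: allow a generous binomial band
  # (cells are correlated across scales, so the effective n is smaller)
  expect_lt(rate, 0.25)
})

test_that("cohort analyses are invariant to node order and affine rescaling", {
  cohort <- gen_coupled_cohort(n_subjects = 6, n_nodes = 5, n_timepoints = 300,
                               n_sessions = 1, seed = 57)
  out1 <- network_mse_fc_correlation(cohort, scales = 1:6)
  perm <- c(3, 1, 5, 2, 4)
  cohort2 <- lapply(cohort, function(s) {
    s$sessions <- lapply(s$sessions, function(m) 2.5 * m[, perm] + 1)
    s
  })
  out2 <- network_mse_fc_correlation(cohort2, scales = 1:6)
  expect_equal(out1$r, out2$r, tolerance = 1e-8)
})

test_that("voxel extraction and MSE maps respect the mask", {
  set.seed(58)
  img <- array(rnorm(4 * 4 * 2 * 120), c(4, 4, 2, 120))
  mask <- array(FALSE, c(4, 4, 2))
  mask[1:2, 1, 1] <- TRUE
  ts <- nifti_node_series(img, mask)
  expect_equal(dim(ts), c(120, 2))
  expect_equal(ts[, 1], img[1, 1, 1, ])
  mp <- mse_voxel_map(img, mask, scales = 1:3)
  expect_equal(dim(mp), c(4, 4, 2, 3))
  expect_true(all(is.na(mp[3, , , ])))
  expect_true(all(is.finite(mp[1:2, 1, 1, ])))
})
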