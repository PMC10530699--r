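test_that("z-scored PSTHs have exactly zero mean over the delay", {
  p <- srnn_params(n_rec = 20)
  recs <- synthetic_records(20, 10, p, function(i, rule)
    0.02 + 0.01 * (rule == 1) * (i <= 5), seed = 2)
  tun <- psth_zscore(recs, p, units = "all")
  db <- tun$delay_bins
  for (i in 1:20) {
    if (tun$excluded[i]) next
    pooled <- c(tun$z[i, db, 1], tun$z[i, db, 2])
    expect_lt(abs(mean(pooled)), 1e-10)
  }
})

test_that("a planted rate bump is recovered at the right time and rule", {
  p <- srnn_params(n_rec = 30)
  # delay spans steps 151-350 (300-700 ms); plant a bump at 500 ms
  nt <- p$n_step
  prof <- 0.02 + 0.25 * exp(-((seq_len(nt) - 250)^2) / (2 * 10^2))
  recs <- synthetic_records(30, 25, p, function(i, rule) {
    if (i <= 3 && rule == 1) prof else 0.02
  }, seed = 3)
  tun <- psth_zscore(recs, p, units = "all")
  found <- find_tuned_units(tun, z_thresh = 2, min_fr = 2)
  lab <- found$table$label[1:3]
  expect_true(all(lab == "rule1"))
  # peak location within one bin of the planted centre (500 ms)
  expect_true(all(abs(found$table$peak_ms_r1[1:3] - 500) <= 8))
  # flat units below the rate floor are never tuned
  expect_true(all(found$table$label[
    found$table$mean_delay_fr < 2] == "none"))
  # infinite threshold empties the tuned set
  none <- find_tuned_units(tun, z_thresh = Inf)
  expect_true(all(none$table$label == "none"))
})

test_that("tuning false-positive rate on Poisson nulls is at most 5%", {
  # homogeneous 10-Hz units; any detected tuning is a false positive
  p <- srnn_params(n_rec = 400)
  recs <- synthetic_records(400, 25, p, function(i, rule) 0.02, seed = 11)
  tun <- psth_zscore(recs, p, units = "all")
  found <- find_tuned_units(tun, z_thresh = 2, min_fr = 2)
  fp <- mean(found$table$label != "none")
  expect_lte(fp, 0.05)
})

test_that("planted tuned fraction is recovered within 2 points", {
  p <- srnn_params(n_rec = 400)
  nt <- p$n_step
  prof <- function(center) 0.02 + 0.3 * exp(-((seq_len(nt) - center)^2) /
                                              (2 * 8^2))
  set.seed(4)
  centers <- sample(180:330, 40, replace = TRUE)
  recs <- synthetic_records(400, 25, p, function(i, rule) {
    if (i <= 40 && rule == 1) prof(centers[i]) else 0.02
  }, seed = 5)
  found <- find_tuned_units(psth_zscore(recs, p, units = "all"))
  frac <- mean(found$table$label != "none")
  expect_gte(frac, 0.08); expect_lte(frac, 0.12)
})

test_that("peak-to-noise ratio matches construction and handles nulls", {
  set.seed(6)
  # planted bump of z = 5 over unit-variance noise
  z <- rnorm(200)
  z <- (z - mean(z)) / sd(z)
  z[100] <- 5
  expect_gt(pnr(z, 4), 4.5); expect_lt(pnr(z, 4), 5.6)
  # degenerate flat series with one artifact: noise floor guard kicks in
  flat <- rep(0, 100); flat[50] <- 3
  expect_gt(pnr(flat, 4), 100)
  # white-noise null concentrates near the expected max-of-Gaussian scale
  vals <- replicate(200, pnr(rnorm(50), kernel_sd = 4))
  expect_gt(median(vals), 1)
  expect_lt(median(vals), 4)
})

test_that("sequentiality index reproduces the hand-worked example", {
  r <- rbind(c(4, 1, 1), c(1, 4, 1), c(1, 1, 4))
  si <- sequentiality_index(r, bin_ms = 8, peak_window_ms = 8)
  expect_equal(si$entropy, log(3), tolerance = 1e-12)
  expect_equal(si$ridge, log(4), tolerance = 1e-12)
  expect_equal(si$si, log(3) + log(4), tolerance = 1e-12)
})

test_that("SI entropy term hits its degenerate and maximal limits", {
  # all units peak in the same bin -> entropy 0
  m <- matrix(1, 6, 10); m[, 4] <- 5
  expect_equal(sequentiality_index(m)$entropy, 0)
  # peaks uniform over B bins -> entropy log B
  B <- 10
  m2 <- matrix(1, B, B) + 4 * diag(B)
  expect_equal(sequentiality_index(m2)$entropy, log(B))
  # entropy invariant to unit relabeling and circular bin shifts
  set.seed(8)
  m3 <- matrix(rexp(20 * 12), 20, 12)
  e0 <- sequentiality_index(m3)$entropy
  expect_equal(sequentiality_index(m3[sample(20), ])$entropy, e0)
  shift <- m3[, c(5:12, 1:4)]
  expect_equal(sequentiality_index(shift)$entropy, e0)
})

test_that("kinetic energy has its closed forms on designed trajectories", {
  # constant trajectory -> K = 0; linear ramp of slope s in PC1 -> s^2/2
  x_const <- matrix(2, 10, 3)
  expect_equal(0.5 * rowSums(diff(x_const)^2), rep(0, 9))
  s <- 0.7
  x_ramp <- cbind(s * (1:10), 0, 0)
  expect_equal(0.5 * rowSums(diff(x_ramp)^2), rep(s^2 / 2, 9))
  # kinetic energy of PCA trajectories is nonnegative
  p <- srnn_params(n_rec = 40)
  recs <- synthetic_records(40, 10, p, function(i, rule) 0.05, seed = 9)
  tr <- pca_trajectory(recs, p, n_pcs = 3)
  for (r in 1:2) expect_true(all(tr$kinetic_energy[[r]][-1] >= 0))
})

test_that("planted rule-specific modes separate in PC space", {
  p <- srnn_params(n_rec = 40)
  recs <- synthetic_records(40, 15, p, function(i, rule) {
    base <- 0.02
    if (i <= 10 && rule == 1) base <- 0.30
    if (i > 10 && i <= 20 && rule == 2) base <- 0.30
    base
  }, seed = 10)
  tr <- pca_trajectory(recs, p, n_pcs = 2)
  sep <- sqrt(rowSums((tr$trajectory[[1]] - tr$trajectory[[2]])^2))
  # within-rule bin-to-bin jitter is much smaller than the separation
  jit <- sqrt(rowSums(diff(tr$trajectory[[1]])^2))
  expect_gt(median(sep), 5 * median(jit))
  expect_error(pca_trajectory(recs[1:1], p), "trials")
})

test_that("correlograms reproduce constructed lags and conserve mass", {
  # trigger spacing wider than the window isolates the constructed lag
  trig <- seq(100, 4000, by = 200)
  cg <- correlogram(trig, trig + 4, max_lag_ms = 50, bin_ms = 2)
  expect_equal(cg$count[cg$lag_ms == 5], 1)  # +4 ms lies in the [4,6) bin
  expect_equal(sum(cg$count), 1)

  # mass conservation under binning changes
  set.seed(12)
  a <- sort(runif(80, 0, 2000)); b <- sort(runif(120, 0, 2000))
  m1 <- sum(correlogram(a, b, 50, 2)$count)
  m2 <- sum(correlogram(a, b, 50, 5)$count)
  expect_equal(m1, m2)

  # 20-Hz periodic train: autocorrelogram mass only at multiples of 50 ms
  per <- seq(0, 2000, by = 50)
  ac <- correlogram(per, max_lag_ms = 120, bin_ms = 2)
  pk <- ac$lag_ms[ac$count > 0]
  expect_true(all(abs(pk) %in% c(49, 51, 99, 101)))
  expect_error(correlogram(numeric(0), 1:3), "non-empty")
})

test_that("beta detection flags planted oscillations, not nulls", {
  set.seed(13)
  tt <- seq_len(200)                 # 400 ms at 2 ms
  osc_trials <- function(f_hz, n_trials = 30)
    t(replicate(n_trials, {
      ph <- runif(1, 0, 2 * pi)      # trial-varying phase
      rbinom(200, 1, 0.08 * (1 + 0.9 * sin(2 * pi * f_hz * tt * 2e-3 + ph)))
    }))
  hits <- replicate(20, detect_beta(osc_trials(20))$is_rhythmic)
  expect_gte(mean(hits), 0.9)
  freqs <- replicate(20, detect_beta(osc_trials(20))$freq)
  expect_lt(abs(median(freqs) - 20), 3)
  # out-of-band modulation is not beta
  hi <- replicate(20, detect_beta(osc_trials(55))$is_rhythmic)
  expect_lte(mean(hi), 0.1)
  # homogeneous Poisson: flagged in at most ~5% of nulls
  nulls <- replicate(200,
    detect_beta(matrix(rbinom(30 * 200, 1, 0.08), 30))$is_rhythmic)
  expect_lte(mean(nulls), 0.05)
  expect_error(detect_beta(rbinom(100, 1, 0.04)), "400 ms")
})

test_that("LFP proxy is the linear sum of synaptic currents", {
  set.seed(14)
  cur <- matrix(rnorm(50 * 400), 50, 400)
  lf <- lfp_proxy(cur)
  expect_equal(lf$trace, colSums(cur))
  # linearity over disjoint unit sets
  a <- lfp_proxy(cur[1:20, ]); b <- lfp_proxy(cur[21:50, ])
  expect_equal(a$trace + b$trace, lf$trace)
  # planted 20-Hz population modulation shows up in the spectrogram
  tt <- seq_len(400) * 2e-3
  cur2 <- matrix(rep(sin(2 * pi * 20 * tt), each = 50), 50, 400) +
    matrix(rnorm(50 * 400, sd = 0.1), 50, 400)
  lf2 <- lfp_proxy(cur2)
  pk <- lf2$freqs[which.max(rowMeans(lf2$power))]
  expect_lt(abs(pk - 20), 4)
})

test_that("population decoder separates separable data, not shuffled labels", {
  # planted: units 1-8 active under rule 1, 9-16 under rule 2
  p <- srnn_params(n_rec = 30)
  recs <- synthetic_records(30, 24, p, function(i, rule) {
    if (i <= 8 && rule == 1) 0.3
    else if (i > 8 && i <= 16 && rule == 2) 0.3
    else 0.02
  }, seed = 15)
  dec <- decode_population(recs, p, bin_ms = 40, n_pcs = 5, folds = 4,
                           epochs = 80, seed = 1)
  expect_gte(dec$accuracy, 0.9)

  # shuffled labels: chance
  recs_sh <- recs
  set.seed(16)
  rules <- sample(vapply(recs, function(r) r$spec$rule, 0L))
  for (i in seq_along(recs_sh)) recs_sh[[i]]$spec$rule <- rules[i]
  dec_sh <- decode_population(recs_sh, p, bin_ms = 40, n_pcs = 5,
                              folds = 4, epochs = 80, seed = 1)
  expect_lt(dec_sh$accuracy, 0.8)
  expect_gt(dec_sh$accuracy, 0.2)
})
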