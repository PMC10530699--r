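test_that("readout loss matches hand-computed cases", {
  # perfect match
  y <- matrix(c(0, 1), 2, 1)
  v <- array(rep(c(0, 1), 5), c(2, 1, 5))
  expect_equal(mse_loss(v, y), 0)
  # one trial, every residual 1 over the final 5 steps: (1/10) * 10 = 1
  v0 <- array(0, c(2, 1, 5))
  expect_equal(mse_loss(v0, matrix(1, 2, 1)), 1)
  # one perfect + one unit-residual trial: linearity over trials -> 0.5
  v2 <- array(0, c(2, 2, 5)); v2[, 1, ] <- 1
  expect_equal(mse_loss(v2, matrix(1, 2, 2)), 0.5)
})

test_that("firing-rate regularizer has the closed-form bin structure", {
  expect_equal(fr_regularizer(matrix(0, 10, 400)), 0)
  # all units firing every step: rate 500 Hz in each of 80 bins
  expect_equal(fr_regularizer(matrix(1, 10, 400)), 80 * 500^2)
  expect_error(fr_regularizer(matrix(0, 10, 401)), "divisible")
})

test_that("loss decomposition is exact", {
  p <- tiny_params()
  w <- init_network(p, seed = 1)
  ctl <- srnn_control(batch_size = 4, lambda = 1e-6)
  b <- make_batch(4, p, base_seed = 1)
  ba <- ruleSRNN:::batch_arrays(b)
  gr <- ruleSRNN:::batch_gradients(w, p, ba$X, ba$Y, ctl, 3)
  expect_identical(gr$loss$total - ctl$lambda * gr$loss$fr, gr$loss$mse)
})

test_that("BPTT gradients match finite differences of the smoothed model", {
  # 3-unit network, 5 steps; threshold replaced by the fast sigmoid
  set.seed(42)
  p <- srnn_params(n_rec = 3, phi_exc = 2 / 3)
  X <- array(rbinom(5 * 2 * 5, 1, 0.4), c(5, 2, 5))
  w_in <- matrix(rnorm(15, sd = 0.5), 3, 5)
  w_rec <- matrix(rnorm(9, sd = 0.5), 3, 3); diag(w_rec) <- 0
  w_out <- matrix(rnorm(4, sd = 0.5), 2, 2)
  amask <- c(1, 0, 1)
  asyn <- ruleSRNN:::alpha_syn_vec(p)
  ibase <- c(0.08, 0.09, 0.07)
  y <- matrix(c(0, 1, 1, 0), 2, 2)
  v0 <- matrix(runif(6, -65, -50), 3, 2)
  cp <- ruleSRNN:::cpp_par(p)
  lam <- 1e-3; scored <- 3; bs <- 1

  loss_of <- function(wi, wr, wo) {
    f <- ruleSRNN:::cpp_srnn_forward(X, wi, wr, wo, amask, asyn, ibase,
                                     cp, TRUE, 0, TRUE, FALSE, 1L, v0)
    ruleSRNN:::cpp_srnn_loss(f$S, f$v_dec, y, lam, scored, bs, p$dt)$total
  }
  f <- ruleSRNN:::cpp_srnn_forward(X, w_in, w_rec, w_out, amask, asyn,
                                   ibase, cp, TRUE, 0, TRUE, FALSE, 1L, v0)
  bw <- ruleSRNN:::cpp_srnn_backward(X, f$S, f$H, f$v_dec, y, w_rec,
                                     w_out, amask, asyn, cp, lam, scored,
                                     bs, FALSE)
  h <- 1e-6
  fd_of <- function(W, set) {
    g <- W * 0
    for (i in seq_along(W)) {
      Wp <- W; Wp[i] <- Wp[i] + h
      Wm <- W; Wm[i] <- Wm[i] - h
      g[i] <- (set(Wp) - set(Wm)) / (2 * h)
    }
    g
  }
  fd_rec <- fd_of(w_rec, function(W) loss_of(w_in, W, w_out))
  fd_in <- fd_of(w_in, function(W) loss_of(W, w_rec, w_out))
  fd_out <- fd_of(w_out, function(W) loss_of(w_in, w_rec, W))
  rel <- function(a, b) max(abs(a - b)) / max(abs(b))
  expect_lt(rel(bw$g_rec, fd_rec), 1e-4)
  expect_lt(rel(bw$g_in, fd_in), 1e-4)
  expect_lt(rel(bw$g_out, fd_out), 1e-4)
})

test_that("Dale projection is idempotent and survives training updates", {
  set.seed(5)
  m <- matrix(rnorm(64), 8, 8)
  once <- dale_project(m)
  expect_identical(dale_project(once), once)
  expect_true(all(once >= 0))
  expect_true(all(diag(once) == 0))

  # two real optimizer updates keep the effective sign pattern intact
  p <- tiny_params()
  ctl <- srnn_control(batch_size = 4, batches_per_epoch = 2,
                      max_epochs = 1, val_trials = 8)
  fit <- srnn(p, ctl, seed = 3)
  weff <- effective_wrec(fit$weights)
  expect_true(all(weff[, seq_len(p$n_exc)] >= 0))
  expect_true(all(weff[, (p$n_exc + 1):p$n_rec] <= 0))
  expect_true(all(diag(weff) == 0))
  expect_true(all(fit$weights$m_rec >= 0))
})

test_that("stronger rate regularization lowers population firing", {
  p <- tiny_params()
  rates <- vapply(c(1e-9, 1e-5, 1e-3), function(lam) {
    ctl <- srnn_control(batch_size = 8, batches_per_epoch = 10,
                        max_epochs = 2, lambda = lam, val_trials = 8)
    fit <- srnn(p, ctl, seed = 2)
    rec <- simulate(fit, nsim = 5, seed = 1)
    mean(vapply(rec, function(r) mean(r$raster), 0))
  }, 0)
  expect_true(all(diff(rates) <= 1e-12))
})

test_that("training history is recorded and deterministic", {
  p <- tiny_params()
  ctl <- srnn_control(batch_size = 4, batches_per_epoch = 3,
                      max_epochs = 2, val_trials = 8)
  f1 <- srnn(p, ctl, seed = 7)
  f2 <- srnn(p, ctl, seed = 7)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights$m_rec, f2$weights$m_rec)
  expect_equal(nrow(f1$history), 2)
  expect_named(f1$history,
               c("epoch", "delay_ms", "l_mse", "l_fr", "l_total",
                 "val_accuracy"))
})
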