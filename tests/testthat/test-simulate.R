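test_that("silent network produces no spikes and zero decoder output", {
  p <- tiny_params()
  w <- silent_weights(p)
  x <- matrix(0, 5, 100)
  rec <- run_trial(x, w, p, seed = 1, noise_scale = 0)
  expect_true(all(rec$raster == 0))
  expect_true(all(rec$decoder_v == 0))
})

test_that("simulation is bit-reproducible given a seed", {
  p <- tiny_params()
  w <- init_network(p, seed = 2)
  trial <- make_batch(1, p, base_seed = 3)[[1]]
  r1 <- run_trial(trial, w, p, seed = 5)
  r2 <- run_trial(trial, w, p, seed = 5)
  expect_identical(r1$raster, r2$raster)
  expect_identical(r1$decoder_v, r2$decoder_v)
  r3 <- run_trial(trial, w, p, seed = 6)
  expect_false(identical(r1$raster, r3$raster))
})

test_that("rasters are binary and respect the refractory period", {
  p <- small_params()
  w <- init_network(p, seed = 1)
  trial <- make_batch(1, p, base_seed = 1)[[1]]
  rec <- run_trial(trial, w, p, seed = 7)
  expect_true(all(rec$raster %in% c(0, 1)))
  ref_steps <- p$tau_ref / p$dt
  for (i in seq_len(nrow(rec$raster))) {
    tt <- which(rec$raster[i, ] == 1)
    if (length(tt) > 1) expect_true(min(diff(tt)) > ref_steps)
  }
})

test_that("the R reference stepper reproduces the fast simulator", {
  p <- tiny_params()
  w <- init_network(p, seed = 8)
  trial <- make_batch(1, p, base_seed = 2)[[1]]
  nt <- ncol(trial$spikes)
  st <- init_state(w, seed = 4)
  v0 <- matrix(st$v, p$n_rec, 1)

  fw <- ruleSRNN:::forward_batch(
    array(trial$spikes, c(5, 1, nt)), w, p, seed = 1, noise_scale = 0,
    v0 = v0)
  state <- c(st, list(s_prev = numeric(p$n_rec)))
  raster <- matrix(0, p$n_rec, nt)
  for (t in seq_len(nt)) {
    out <- srnn_step(state, trial$spikes[, t], w, p)
    state <- out$state
    raster[, t] <- out$spikes
  }
  expect_identical(raster, fw$S[, 1, ])
})

test_that("adaptation follows the closed-form decay and stays in [0, 1]", {
  p <- tiny_params()
  w <- init_network(p, seed = 1)
  phi <- exp(-p$dt / p$tau_a)
  st <- init_state(w, seed = 1)
  st$v[] <- p$v_rest            # keep units quiet
  st$i_base[] <- 0
  state <- c(st, list(s_prev = rep(1, p$n_rec)))  # one spike everywhere
  a <- numeric(20)
  for (k in 1:20) {
    out <- srnn_step(state, numeric(5), w, p)
    state <- out$state
    state$s_prev[] <- 0         # silence afterwards
    a[k] <- state$a[1]
  }
  expect_equal(a, (1 - phi) * phi^(0:19))
  expect_true(all(a >= 0 & a <= 1))
})

test_that("adaptation remains in [0, 1] for arbitrary spike histories", {
  p <- tiny_params()
  w <- init_network(p, seed = 3)
  set.seed(9)
  state <- c(init_state(w, seed = 2), list(s_prev = numeric(p$n_rec)))
  for (k in 1:200) {
    state$s_prev <- as.numeric(runif(p$n_rec) < 0.5)
    out <- srnn_step(state, as.numeric(runif(5) < 0.3), w, p)
    state <- out$state
    expect_true(all(state$a >= 0 & state$a <= 1))
  }
})

test_that("decision rule follows the voltage-target convention", {
  # [1, 0] codes the right choice, [0, 1] the left
  d <- decide(list(decoder_v = matrix(c(0.9, 0.1), 2, 1)))
  expect_equal(d$choice, "R")
  d <- decide(list(decoder_v = matrix(c(0.1, 0.9), 2, 1)))
  expect_equal(d$choice, "L")
  d <- decide(list(decoder_v = matrix(c(0.5, 0.5), 2, 1)))
  expect_equal(d$index, 1L)
  expect_true(d$tie)
  # 4AFC: softmax argmax
  d4 <- decide(list(decoder_v = matrix(c(0, 0.1, 2, 0.2), 4, 1)),
               srnn_params(n_outputs = 4))
  expect_equal(d4$choice, "AL")
  expect_equal(sum(d4$prob), 1)
})

test_that("untrained networks sit at chance on average", {
  # a single untrained network can be far from 50% (its random readout is
  # systematically aligned or anti-aligned with the stimulus channels),
  # but the ensemble is unbiased and rule-blind
  p <- small_params()
  accs <- vapply(11:16, function(s) {
    w <- init_network(p, seed = s)
    evaluate(w, p, n_trials = 100, seed = 5)$accuracy
  }, 0)
  expect_gt(mean(accs), 0.3)
  expect_lt(mean(accs), 0.7)
  w <- init_network(p, seed = 11)
  ev <- evaluate(w, p, n_trials = 100, seed = 5)
  ev2 <- evaluate(w, p, n_trials = 100, seed = 5)
  expect_identical(ev$accuracy, ev2$accuracy)
})
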