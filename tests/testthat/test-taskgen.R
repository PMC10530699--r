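test_that("trial structure renders the stated periods", {
  p <- srnn_params()
  sp <- trial_spec(1, "L", "R", seed = 3)
  x <- build_trial_inputs(sp, p)
  expect_equal(dim(x), c(5, 400))        # 800 ms at dt = 2

  per <- attr(x, "periods")
  expect_equal(per, c(100L, 50L, 200L, 50L))
  cue_idx <- 101:150
  stim_idx <- 351:400

  # cue mixture on channel 1 only; pure rule 1 cue
  expect_true(all(x[1, cue_idx] == p$cue_amp[1]))
  expect_true(all(x[2:5, cue_idx] == 0))
  # sensory drive on the channels matching the sides, zero elsewhere
  expect_true(all(x[2, stim_idx] == p$stim_amp))   # Vision/Left
  expect_true(all(x[5, stim_idx] == p$stim_amp))   # Audition/Right
  expect_true(all(x[c(1, 3, 4), stim_idx] == 0))

  # elongated delay
  sp8 <- trial_spec(1, "L", "R", delay_ms = 800)
  expect_equal(ncol(build_trial_inputs(sp8, p)), 600)
})

test_that("cue is a convex mixture of the rule waveforms, linear in q", {
  p <- srnn_params()
  cue_idx <- 101:150
  pure1 <- build_trial_inputs(trial_spec(1, "L", "L", mixture_q = 1), p)
  pure2 <- build_trial_inputs(trial_spec(1, "L", "L", mixture_q = 0), p)
  half <- build_trial_inputs(trial_spec(1, "L", "L", mixture_q = 0.5), p)
  expect_equal(half[1, cue_idx],
               (pure1[1, cue_idx] + pure2[1, cue_idx]) / 2)
  # total cue-channel energy linear in q
  qs <- c(0, 0.25, 0.5, 0.75, 1)
  e <- vapply(qs, function(q)
    sum(build_trial_inputs(trial_spec(1, "L", "L", mixture_q = q),
                           p)[1, cue_idx]), 0)
  expect_equal(e, e[1] + qs * (e[5] - e[1]))
})

test_that("trial spec derives the correct choice and validates inputs", {
  expect_equal(trial_spec(1, "L", "R")$correct_choice, "L")
  expect_equal(trial_spec(2, "L", "R")$correct_choice, "R")
  expect_error(trial_spec(1, "L", "R", mixture_q = 1.2), "mixture_q")
  expect_error(trial_spec(1, "L", "R", delay_ms = -5), "delay_ms")
  expect_error(srnn_params(dt = 3), "divide")
})

test_that("distractor pulse lands on the cue channel inside the delay", {
  p <- srnn_params()
  d <- list(onset_ms = 100, duration_ms = 50, amplitude = 2)
  sp <- trial_spec(1, "L", "R", distractor = d, seed = 5)
  x <- build_trial_inputs(sp, p)
  base <- build_trial_inputs(trial_spec(1, "L", "R", seed = 5), p)
  diffmat <- x - base
  hit <- which(diffmat[1, ] != 0)
  expect_equal(range(hit), c(201, 225))  # delay starts at step 151
  expect_equal(diffmat[1, hit], rep(2, 25), tolerance = 1e-12)
  expect_true(all(diffmat[2:5, ] == 0))
})

test_that("LIF encoder matches the closed-form inter-spike interval", {
  p <- srnn_params()
  # subthreshold and threshold currents never spike
  expect_true(all(encode_to_spikes(matrix(0, 5, 100), p) == 0))
  expect_true(all(encode_to_spikes(matrix(1, 1, 500), p) == 0))
  # suprathreshold: ISI = ceiling(tau * log(IR/(IR - vth)) / dt) steps
  for (amp in c(1.2, 1.5, 2, 3)) {
    s <- encode_to_spikes(matrix(amp, 1, 400), p)
    isi <- diff(which(s[1, ] == 1))
    k_exact <- p$enc_tau_m * log(amp / (amp - p$enc_v_th)) / p$dt
    expect_equal(unique(isi), ceiling(k_exact - 1e-12),
                 info = paste("amplitude", amp))
  }
  # binary output, deterministic given inputs
  x <- build_trial_inputs(trial_spec(1, "L", "R", seed = 11))
  s1 <- encode_to_spikes(x, p); s2 <- encode_to_spikes(x, p)
  expect_identical(s1, s2)
  expect_true(all(s1 %in% c(0, 1)))
})

test_that("batches are balanced, reproducible, with correct targets", {
  p <- small_params()
  b <- make_batch(200, p, balance = TRUE, base_seed = 7)
  rules <- vapply(b, function(t) t$spec$rule, 0L)
  expect_equal(as.vector(table(rules)), c(100, 100))

  b2 <- make_batch(200, p, balance = TRUE, base_seed = 7)
  expect_identical(lapply(b, `[[`, "spec"), lapply(b2, `[[`, "spec"))
  expect_identical(b[[17]]$spikes, b2[[17]]$spikes)

  # y convention: [0, 1] = left, [1, 0] = right
  for (t in b[1:20]) {
    expect_equal(t$y, if (t$spec$correct_choice == "L") c(0, 1)
                      else c(1, 0))
  }

  b3 <- make_batch(2, p, balance = TRUE, base_seed = 1)
  expect_setequal(vapply(b3, function(t) t$spec$rule, 0L), c(1L, 2L))
})

test_that("incongruent trials occur at the chance rate", {
  p <- small_params()
  b <- make_batch(1000, p, base_seed = 21)
  inc <- vapply(b, function(t)
    t$spec$visual_side != t$spec$auditory_side, TRUE)
  expect_gt(binom.test(sum(inc), 1000, 0.5)$p.value, 0.01)
})

test_that("four-alternative targets are one-hot on the correct port", {
  p <- srnn_params(n_rec = 10, n_outputs = 4)
  b <- make_batch(8, p, base_seed = 3)
  for (t in b) {
    expect_equal(sum(t$y), 1)
    port <- c("VL", "VR", "AL", "AR")[which(t$y == 1)]
    side <- substr(port, 2, 2)
    mod <- substr(port, 1, 1)
    expect_equal(side, t$spec$correct_choice)
    expect_equal(mod, if (t$spec$rule == 1) "V" else "A")
  }
})

test_that("incongruent batches always conflict", {
  p <- srnn_params(n_rec = 10)
  b <- make_batch(20, p, base_seed = 4, incongruent = TRUE)
  expect_true(all(vapply(b, function(t)
    t$spec$visual_side != t$spec$auditory_side, TRUE)))
})
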