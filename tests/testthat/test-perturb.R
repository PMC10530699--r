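p10 <- tiny_params()
w10 <- init_network(p10, seed = 1)

test_that("sparsification drops the exact count and is reproducible", {
  expect_identical(sparsify(w10, 0, seed = 1)$m_rec, w10$m_rec)
  nz0 <- sum(w10$m_rec != 0)
  sp <- sparsify(w10, 0.2, seed = 2)
  expect_equal(sum(sp$m_rec != 0), nz0 - floor(0.2 * nz0))
  # survivors unchanged -> Dale signs intact
  kept <- sp$m_rec != 0
  expect_identical(sp$m_rec[kept], w10$m_rec[kept])
  sp2 <- sparsify(w10, 0.2, seed = 2)
  expect_identical(sp$m_rec, sp2$m_rec)
  expect_false(identical(sparsify(w10, 0.2, seed = 3)$m_rec, sp$m_rec))
  expect_error(sparsify(w10, 1), "fraction")
})

test_that("block scaling touches exactly one block and keeps signs", {
  ne <- p10$n_exc
  up <- scale_block(w10, "EE", 2)
  expect_equal(up$m_rec[1:ne, 1:ne], 2 * w10$m_rec[1:ne, 1:ne])
  expect_identical(up$m_rec[(ne + 1):p10$n_rec, ],
                   w10$m_rec[(ne + 1):p10$n_rec, ])
  expect_identical(scale_block(w10, "IE", 1)$m_rec, w10$m_rec)
  weff <- effective_wrec(scale_block(w10, "EI", 3))
  expect_true(all(weff[, (ne + 1):p10$n_rec] <= 0))
  expect_error(scale_block(w10, "XX", 2))
  expect_error(scale_block(w10, "EE", -1), "positive")
})

test_that("sweep tables carry the full grid with confidence intervals", {
  tab <- sweep_mixture(w10, q_grid = c(0.5, 1), n_trials = 8, seed = 1)
  expect_equal(tab$q, c(0.5, 1))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
  expect_true(all(tab$ci_lo <= tab$accuracy & tab$accuracy <= tab$ci_hi))

  sd <- sweep_delay(w10, delays_ms = c(400, 600), n_trials = 8, seed = 1)
  expect_equal(sd$accuracy$delay_ms, c(400, 600))

  bs <- sweep_block_scaling(w10, "EE", factors = c(1, 2), n_trials = 8,
                            seed = 1)
  expect_equal(bs$factor, c(1, 2))
  expect_true(all(is.finite(bs$rate_exc)))

  nd <- sweep_noise_distractor(w10, noise_sds = c(0.05), windows_ms = 0,
                               amplitudes = c(0, 2), n_trials = 8,
                               seed = 1)
  expect_equal(nrow(nd$distractor), 2)
})

test_that("perturbations are pure functions of weights and seed", {
  a <- sweep_mixture(w10, q_grid = 0.8, n_trials = 8, seed = 4)
  b <- sweep_mixture(w10, q_grid = 0.8, n_trials = 8, seed = 4)
  expect_identical(a, b)
})
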