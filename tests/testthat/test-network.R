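test_that("Glorot initialization respects the uniform bound", {
  set.seed(1)
  w <- glorot_init(500, 500)
  b <- sqrt(6 / 1000)
  expect_equal(b, 0.07745967, tolerance = 1e-6)
  expect_true(all(abs(w) < b))
  expect_equal(dim(w), c(500, 500))

  w2 <- glorot_init(1, 2)
  expect_true(all(abs(w2) < sqrt(2)))

  set.seed(42); a <- glorot_init(20, 20)
  set.seed(42); b2 <- glorot_init(20, 20)
  expect_identical(a, b2)
})

test_that("spectral rescaling hits the target radius", {
  expect_equal(spectral_rescale(diag(5), g = 1.5), 1.5 * diag(5))
  expect_equal(spectral_rescale(diag(c(2, 0.5)), g = 1.5),
               0.75 * diag(c(2, 0.5)))
  set.seed(3)
  w <- glorot_init(200, 200)
  ws <- spectral_rescale(w, g = 1.5)
  rho <- max(Mod(eigen(ws, only.values = TRUE)$values))
  expect_equal(rho, 1.5, tolerance = 1e-9)
  expect_error(spectral_rescale(matrix(0, 3, 3)), "zero spectral radius")
})

test_that("Dale mask balances excitation and inhibition", {
  m <- build_dale_mask(500, 0.8)
  expect_equal(m$d_inh, -4)
  expect_equal(m$d_norm, sqrt(2000))
  expect_equal(m$constraint_sum, 0, tolerance = 1e-9)
  expect_true(all(diag(m$D) == 0))
  off <- row(m$D) != col(m$D)
  expect_equal(unique(m$D[, 1:400][off[, 1:400]]), 1 / sqrt(2000))
  expect_equal(unique(m$D[, 401:500][off[, 401:500]]), -4 / sqrt(2000))
  expect_equal(1 / sqrt(2000), 0.02236068, tolerance = 1e-7)
  expect_equal(-4 / sqrt(2000), -0.08944272, tolerance = 1e-7)

  s <- build_dale_mask(5, 0.8)
  expect_equal(s$n_exc, 4L); expect_equal(s$n_inh, 1L)
  expect_true(all(diag(s$D) == 0))
  expect_error(build_dale_mask(7, 0.8), "integer")
})

test_that("network initialization obeys sign, SFA and baseline contracts", {
  p <- small_params()
  w <- init_network(p, seed = 4)
  weff <- effective_wrec(w)
  expect_true(all(weff[, seq_len(p$n_exc)] >= 0))
  expect_true(all(weff[, (p$n_exc + 1):p$n_rec] <= 0))
  expect_true(all(diag(weff) == 0))
  expect_equal(sum(w$a_mask), floor(0.25 * p$n_rec))
  expect_true(all(w$i_base >= 0.041 * 1.8 & w$i_base <= 0.041 * 2.4))
  expect_equal(dim(w$w_out), c(2, p$n_exc))

  w2 <- init_network(p, seed = 4)
  expect_identical(w$m_rec, w2$m_rec)
  expect_identical(w$a_mask, w2$a_mask)

  st <- init_state(w, seed = 9)
  expect_true(all(st$v >= p$v_rest & st$v <= p$v_th))
  expect_true(all(st$a == 0))
  expect_true(all(st$refrac == 0))
})

test_that("SuperSpike surrogate has the fast-sigmoid profile", {
  expect_equal(superspike_grad(0, 0, beta = 1000), 1)
  expect_equal(superspike_grad(1e-3, 0, beta = 1000), 0.25)
  expect_equal(superspike_grad(-1e-3, 0, beta = 1000), 0.25)
  d <- runif(50, -0.01, 0.01)
  expect_equal(superspike_grad(d, 0), superspike_grad(-d, 0))
  expect_true(all(diff(superspike_grad(seq(0, 0.01, 1e-4), 0)) < 0))
})
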