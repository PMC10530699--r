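#' Glorot (Xavier) uniform initialization
#'
#' Entries are i.i.d. Uniform(-b, b) with `b = sqrt(6 / (fan_in + fan_out))`.
#'
#' @param fan_in,fan_out layer fan sizes (both >= 1).
#' @return a `fan_out x fan_in` matrix.
#' @export
glorot_init <- function(fan_in, fan_out) {
  stopifnot(fan_in >= 1, fan_out >= 1)
  b <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -b, b), fan_out, fan_in)
}

#' Rescale a square matrix to a target spectral radius
#'
#' Returns `(g / rho) * w` where `rho` is the largest modulus among the
#' (possibly complex) eigenvalues of `w`, so the result has spectral radius
#' exactly `g` up to floating-point error.
#'
#' @param w square numeric matrix.
#' @param g target spectral radius.
#' @export
spectral_rescale <- function(w, g = 1.5) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  rho <- max(Mod(eigen(w, only.values = TRUE)$values))
  if (rho == 0) stop("matrix has zero spectral radius; cannot rescale")
  (g / rho) * w
}

#' Dale's-principle sign-and-scale mask
#'
#' Each column (presynaptic unit) of the mask carries that unit's constraint
#' item: `d_exc = 1` for the excitatory columns and
#' `d_inh = -phi_exc / (1 - phi_exc)` for the inhibitory ones, so that
#' `sum_exc d_exc + sum_inh d_inh = 0` (excitation and inhibition balance),
#' normalized by `d_norm = sqrt(sum_exc d_exc^2 + sum_inh d_inh^2)`. The
#' diagonal is zero (no self-connections). The effective recurrent matrix is
#' the elementwise product of a nonnegative magnitude matrix with this mask.
#'
#' @param n_rec number of units.
#' @param phi_exc excitatory fraction; `phi_exc * n_rec` must be integral.
#' @return object of class `dale_mask`: list with the mask matrix `D`,
#'   `n_exc`, `n_inh`, `d_exc`, `d_inh`, `d_norm` and `constraint_sum`.
#' @examples
#' m <- build_dale_mask(500, 0.8)
#' m$d_inh           # -4
#' m$constraint_sum  # 0: 400 * 1 + 100 * (-4)
#' @export
build_dale_mask <- function(n_rec, phi_exc = 0.8) {
  if (phi_exc <= 0 || phi_exc >= 1) stop("phi_exc must be in (0, 1)")
  ne_real <- phi_exc * n_rec
  if (abs(ne_real - round(ne_real)) > 1e-9)
    stop("phi_exc * n_rec must be an integer")
  n_exc <- as.integer(round(ne_real))
  n_inh <- as.integer(n_rec - n_exc)
  d_exc <- 1
  d_inh <- -phi_exc / (1 - phi_exc)
  d_norm <- sqrt(n_exc * d_exc^2 + n_inh * d_inh^2)
  d_col <- c(rep(d_exc, n_exc), rep(d_inh, n_inh)) / d_norm
  D <- matrix(rep(d_col, each = n_rec), n_rec, n_rec)
  diag(D) <- 0
  structure(list(D = D, n_exc = n_exc, n_inh = n_inh, d_exc = d_exc,
                 d_inh = d_inh, d_norm = d_norm,
                 constraint_sum = n_exc * d_exc + n_inh * d_inh),
            class = "dale_mask")
}

#' Initialize the network weights
#'
#' The recurrent magnitude matrix is the absolute value of a Glorot-drawn
#' square matrix rescaled to spectral radius `g`; the Dale mask supplies
#' signs and normalization at use time. Input (cue + sensory) and output
#' weights are Glorot-initialized with unconstrained sign; the readout sees
#' excitatory units only. A random `sfa_fraction` of all units (excitatory
#' and inhibitory alike) is assigned spike-frequency adaptation, and each
#' unit receives a baseline current drawn once from the truncated-normal
#' recipe (fixed across all trials of the network).
#'
#' @param params a [srnn_params()].
#' @param seed integer seed.
#' @return object of class `srnn_weights`: `m_rec` (nonnegative magnitudes),
#'   `mask` ([build_dale_mask()] result), `w_cue` (`n_rec x 1`), `w_sens`
#'   (`n_rec x 4`), `w_out` (`n_outputs x n_exc`), `a_mask` (0/1 vector),
#'   `i_base` (nA), and `params`.
#' @export
init_network <- function(params = srnn_params(), seed = 1L) {
  set.seed(derive_seed(seed, "init"))
  n <- params$n_rec
  mask <- build_dale_mask(n, params$phi_exc)

  m_rec <- abs(spectral_rescale(glorot_init(n, n), params$g))
  diag(m_rec) <- 0

  w_in <- glorot_init(5, n)                    # joint cue+sensory draw
  w_out <- glorot_init(params$n_exc, params$n_outputs)

  n_sfa <- floor(params$sfa_fraction * n)
  a_mask <- numeric(n)
  a_mask[sample.int(n, n_sfa)] <- 1

  i_base <- params$i_base_scale *
    rtruncnorm(n, params$i_base_mu, params$i_base_sd,
               params$i_base_lo, params$i_base_hi)

  structure(list(m_rec = m_rec, mask = mask,
                 w_cue = w_in[, 1, drop = FALSE],
                 w_sens = w_in[, 2:5, drop = FALSE],
                 w_out = w_out, a_mask = a_mask, i_base = i_base,
                 params = params),
            class = "srnn_weights")
}

# truncated normal by rejection (tight bounds, cheap)
rtruncnorm <- function(n, mu, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n, mu, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Effective signed recurrent weight matrix
#'
#' Elementwise product of the nonnegative magnitudes with the Dale mask:
#' excitatory columns are nonnegative, inhibitory columns nonpositive, the
#' diagonal zero.
#'
#' @param weights an `srnn_weights` object.
#' @export
effective_wrec <- function(weights) {
  weights$m_rec * weights$mask$D
}

# combined (n_rec x 5) input matrix handed to the C++ forward pass
w_in_mat <- function(weights) {
  cbind(weights$w_cue, weights$w_sens)
}

#' Initialize the per-trial network state
#'
#' Membrane potentials start uniformly between rest and baseline threshold
#' (redrawn every trial); synaptic currents, adaptation and refractory
#' counters start at zero; the baseline current is the network's fixed
#' per-unit vector.
#'
#' @param weights an [init_network()] result.
#' @param seed integer seed for the membrane-potential draw.
#' @return list with `v`, `i_syn`, `a`, `refrac`, `i_base`.
#' @export
init_state <- function(weights, seed = 1L) {
  p <- weights$params
  set.seed(derive_seed(seed, "state"))
  list(v = runif(p$n_rec, p$v_rest, p$v_th),
       i_syn = numeric(p$n_rec), a = numeric(p$n_rec),
       refrac = integer(p$n_rec), i_base = weights$i_base)
}

#' SuperSpike fast-sigmoid surrogate derivative
#'
#' The pseudo-derivative `1 / (1 + beta * |v - v_th|)^2` substituted for the
#' Heaviside threshold derivative during backpropagation (the forward pass
#' keeps the hard threshold). Voltages are in volts per the SuperSpike
#' convention; the simulator converts its mV state accordingly, so at
#' `beta = 1000` the surrogate has a ~1-mV half-width.
#'
#' @param v membrane potential (V).
#' @param v_th effective threshold (V).
#' @param beta sharpness (per volt).
#' @return surrogate derivative values; 1 at threshold, 0.25 at
#'   `|v - v_th| = 1 / beta`.
#' @export
superspike_grad <- function(v, v_th, beta = 1000) {
  stopifnot(beta > 0)
  1 / (1 + beta * abs(v - v_th))^2
}
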