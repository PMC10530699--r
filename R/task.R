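#' Specify a single forced-choice trial
#'
#' A trial consists of a fixation period (white noise only), a 100-ms rule
#' cue, a delay (white noise only), and a 100-ms presentation of conflicting
#' visual and auditory targets. The rule determines which modality's side is
#' the correct choice. `mixture_q` is the fraction of the rule-1 cue waveform
#' in the cue-channel current (1 = pure rule-1 cue, 0 = pure rule-2 cue);
#' ambiguous cues (`q` near 0.5) emulate executive errors.
#'
#' The target convention follows the decoder code `[0, 1]` = left choice,
#' `[1, 0]` = right choice.
#'
#' @param rule 1 (attend vision) or 2 (attend audition).
#' @param visual_side,auditory_side `"L"` or `"R"`.
#' @param mixture_q fraction of rule-1 signal in the cue, in `[0, 1]`.
#'   Defaults to the pure cue of `rule`.
#' @param delay_ms delay duration (ms).
#' @param distractor optional `list(onset_ms=, duration_ms=, amplitude=)`
#'   pulse added to the cue channel, onset relative to delay start.
#' @param seed integer seed for the trial's input noise.
#' @return object of class `trial_spec` with derived field `correct_choice`.
#' @examples
#' trial_spec(rule = 2, visual_side = "L", auditory_side = "R")$correct_choice
#' @export
trial_spec <- function(rule, visual_side, auditory_side,
                       mixture_q = if (rule == 1) 1 else 0,
                       delay_ms = 400, distractor = NULL, seed = 1L) {
  stopifnot(rule %in% c(1L, 2L),
            visual_side %in% c("L", "R"), auditory_side %in% c("L", "R"))
  if (!is.numeric(mixture_q) || mixture_q < 0 || mixture_q > 1)
    stop("mixture_q must lie in [0, 1]")
  if (delay_ms <= 0) stop("delay_ms must be positive")
  if (!is.null(distractor)) {
    stopifnot(is.list(distractor),
              all(c("onset_ms", "amplitude") %in% names(distractor)))
    distractor$duration_ms <- distractor$duration_ms %||% 50
  }
  structure(list(rule = as.integer(rule), visual_side = visual_side,
                 auditory_side = auditory_side, mixture_q = mixture_q,
                 delay_ms = delay_ms, distractor = distractor,
                 correct_choice = if (rule == 1) visual_side else
                                  auditory_side,
                 seed = as.integer(seed)),
            class = "trial_spec")
}

#' Render a trial into continuous input currents
#'
#' Builds the 5-channel analog current matrix driving the input encoder:
#' channel 1 carries the rule cue, channels 2-5 the Vision/Left,
#' Vision/Right, Audition/Left and Audition/Right targets. During fixation
#' and delay all channels carry zero-mean white-noise current only; during
#' the cue window channel 1 carries the convex mixture
#' `q * cue1 + (1 - q) * cue2` of the two constant rule waveforms; during
#' the stimulus window the two channels matching the trial's sides carry a
#' constant drive. An optional distractor pulse is added to the cue channel
#' inside the delay.
#'
#' @param spec a [trial_spec()].
#' @param params a [srnn_params()]; `params$delay_ms` is overridden by
#'   `spec$delay_ms`.
#' @return matrix `5 x n_step` of input currents (model units) with
#'   attributes `dt` and `periods` (named step counts).
#' @export
build_trial_inputs <- function(spec, params = srnn_params()) {
  stopifnot(inherits(spec, "trial_spec"))
  dt <- params$dt
  per_ms <- c(fix = params$fixation_ms, cue = params$cue_ms,
              delay = spec$delay_ms, stim = params$stim_ms)
  if (any(abs(per_ms / dt - round(per_ms / dt)) > 1e-9))
    stop("dt must divide every period duration")
  per <- as.integer(round(per_ms / dt))
  nt <- sum(per)
  x <- matrix(0, 5, nt)

  idx_fix <- seq_len(per[1])
  idx_cue <- per[1] + seq_len(per[2])
  idx_delay <- per[1] + per[2] + seq_len(per[3])
  idx_stim <- per[1] + per[2] + per[3] + seq_len(per[4])

  # background white noise on all channels during fixation and delay
  set.seed(spec$seed)
  noisy <- c(idx_fix, idx_delay)
  x[, noisy] <- rnorm(5 * length(noisy), sd = params$input_noise_sd)

  # rule cue: convex mixture of the two constant waveforms
  q <- spec$mixture_q
  x[1, idx_cue] <- q * params$cue_amp[1] + (1 - q) * params$cue_amp[2]

  # sensory targets
  vis_ch <- if (spec$visual_side == "L") 2L else 3L
  aud_ch <- if (spec$auditory_side == "L") 4L else 5L
  x[vis_ch, idx_stim] <- params$stim_amp
  x[aud_ch, idx_stim] <- params$stim_amp

  if (!is.null(spec$distractor)) {
    d <- spec$distractor
    on <- as.integer(round(d$onset_ms / dt))
    len <- as.integer(round(d$duration_ms / dt))
    lo <- per[1] + per[2] + on + 1L
    hi <- min(per[1] + per[2] + on + len, per[1] + per[2] + per[3])
    if (lo <= hi) x[1, lo:hi] <- x[1, lo:hi] + d$amplitude
  }

  structure(x, dt = dt, periods = per)
}

#' Encode analog input currents into spike trains
#'
#' Five leaky integrate-and-fire encoder neurons (one per channel,
#' exponential-Euler integration, reset to rest on threshold crossing, no
#' refractory period) convert the continuous currents into binary spikes.
#' The encoder itself is noise-free: all stochasticity enters through the
#' white-noise component of the input currents.
#'
#' @param inputs current matrix from [build_trial_inputs()].
#' @param params a [srnn_params()] (encoder constants `enc_*` are used).
#' @return binary spike matrix of the same dimension as `inputs`.
#' @examples
#' # constant suprathreshold current: inter-spike interval matches the
#' # closed-form LIF period tau * log(IR / (IR - v_th)), rounded up to dt
#' p <- srnn_params()
#' s <- encode_to_spikes(matrix(2, 1, 50), p)
#' diff(which(s[1, ] == 1))  # all equal ceiling(5 * log(2) / 2) = 2 steps
#' @export
encode_to_spikes <- function(inputs, params = srnn_params()) {
  if (!all(is.finite(inputs))) stop("inputs must be finite")
  cpp_lif_encode(as.matrix(inputs), params$enc_tau_m, params$enc_v_rest,
                 params$enc_v_th, params$enc_r, params$dt)
}

#' Generate a batch of task trials
#'
#' Draws `n` trial specifications (rules balanced when `balance = TRUE`,
#' sides sampled independently with probability 1/2 each, so congruent and
#' incongruent trials are equally frequent), renders the input currents,
#' encodes them into spikes, and attaches the decoder target vector.
#'
#' @param n number of trials.
#' @param params a [srnn_params()].
#' @param balance logical; exactly balanced rule counts.
#' @param base_seed integer; the batch is a pure function of
#'   `(n, base_seed, arguments)`.
#' @param q optional cue ambiguity level: the fraction of the *nominal*
#'   rule's signal in the cue (`mixture_q = q` for rule-1 trials and
#'   `1 - q` for rule-2 trials). `NULL` means pure cues (`q = 1`).
#' @param delay_ms delay duration used for every trial.
#' @param distractor optional distractor passed to every [trial_spec()].
#' @param incongruent force visual and auditory sides to conflict on every
#'   trial (used by psychometric sweeps, where only incongruent trials
#'   reveal rule use).
#' @return list of class `srnn_batch`; each element has `spec`, `inputs`,
#'   `spikes` and target `y`.
#' @export
make_batch <- function(n, params = srnn_params(), balance = TRUE,
                       base_seed = 1L, q = NULL, delay_ms = NULL,
                       distractor = NULL, incongruent = FALSE) {
  stopifnot(n >= 1)
  delay_ms <- delay_ms %||% params$delay_ms
  set.seed(derive_seed(base_seed, "trial"))
  rules <- if (balance) {
    sample(rep(c(1L, 2L), length.out = n))
  } else sample(c(1L, 2L), n, replace = TRUE)
  vside <- sample(c("L", "R"), n, replace = TRUE)
  aside <- if (incongruent) ifelse(vside == "L", "R", "L") else
    sample(c("L", "R"), n, replace = TRUE)
  seeds <- sample.int(2^30, n)

  out <- vector("list", n)
  for (i in seq_len(n)) {
    mq <- if (is.null(q)) { if (rules[i] == 1) 1 else 0 }
          else { if (rules[i] == 1) q else 1 - q }
    sp <- trial_spec(rules[i], vside[i], aside[i], mixture_q = mq,
                     delay_ms = delay_ms, distractor = distractor,
                     seed = seeds[i])
    cur <- build_trial_inputs(sp, params)
    out[[i]] <- list(spec = sp, inputs = cur,
                     spikes = encode_to_spikes(cur, params),
                     y = choice_target(sp$correct_choice, params$n_outputs,
                                       sp))
  }
  class(out) <- "srnn_batch"
  out
}

# decoder target vector; 2AFC: [0,1] = left, [1,0] = right.
# 4AFC ports are ordered (Vision/L, Vision/R, Audition/L, Audition/R).
choice_target <- function(choice, n_outputs, spec = NULL) {
  if (n_outputs == 2L) {
    if (choice == "L") c(0, 1) else c(1, 0)
  } else {
    port <- port_index_4afc(spec)
    y <- numeric(4); y[port] <- 1; y
  }
}

port_index_4afc <- function(spec) {
  side <- spec$correct_choice
  if (spec$rule == 1) (if (side == "L") 1L else 2L)
  else (if (side == "L") 3L else 4L)
}

# stack a batch into the (5 x B x T) input cube and (n_out x B) target
# matrix consumed by the C++ kernels
batch_arrays <- function(batch) {
  nb <- length(batch)
  nt <- ncol(batch[[1]]$spikes)
  X <- array(0, dim = c(5L, nb, nt))
  Y <- matrix(0, length(batch[[1]]$y), nb)
  for (i in seq_len(nb)) {
    X[, i, ] <- batch[[i]]$spikes
    Y[, i] <- batch[[i]]$y
  }
  list(X = X, Y = Y)
}
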