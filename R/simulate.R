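#' Advance the recurrent network by one integration step (reference)
#'
#' A plain-R, noise-free reference implementation of the per-step update
#' used by the fast batched simulator; exposed for inspection, testing and
#' custom experiments. Update order: (1) synaptic currents decay and
#' accumulate last step's weighted spikes plus the baseline current; (2) the
#' membrane potential follows exponential-Euler leaky integration (an
#' optional externally supplied noise vector is added here); (3) the
#' adaptation variable and effective threshold are updated from last step's
#' spikes; (4) spikes are emitted where the potential reaches the effective
#' threshold and the unit is not refractory; (5) spiking units reset to rest
#' and enter the refractory period, during which the potential is clamped at
#' rest.
#'
#' @param state list as returned by [init_state()] plus element `s_prev`
#'   (last step's spike vector; zeros initially).
#' @param input_spikes length-5 binary vector of encoder spikes at this step.
#' @param weights an [init_network()] result.
#' @param params a [srnn_params()].
#' @param noise_v optional per-unit membrane noise (mV) added this step.
#' @return list `state` (updated, including `s_prev`) and `spikes`.
#' @export
srnn_step <- function(state, input_spikes, weights, params = weights$params,
                      noise_v = NULL) {
  n <- params$n_rec
  s_prev <- state$s_prev %||% numeric(n)
  a_syn <- alpha_syn_vec(params)
  a_m <- exp(-params$dt / params$tau_m)
  phi <- exp(-params$dt / params$tau_a)

  i_syn <- a_syn * state$i_syn +
    drop(w_in_mat(weights) %*% input_spikes) +
    drop(effective_wrec(weights) %*% s_prev) + state$i_base

  v <- params$v_rest + a_m * (state$v - params$v_rest) +
    (1 - a_m) * params$r_mohm * i_syn
  if (!is.null(noise_v)) v <- v + noise_v

  in_ref <- state$refrac > 0
  v[in_ref] <- params$v_rest
  refrac <- state$refrac
  refrac[in_ref] <- refrac[in_ref] - 1L

  a <- phi * state$a + (1 - phi) * s_prev
  theta <- params$v_th + params$psi * a * weights$a_mask

  s <- as.numeric(v >= theta & !in_ref)
  v[s == 1] <- params$v_rest
  refrac[s == 1] <- params$ref_steps

  if (any(!is.finite(v)))
    stop("non-finite membrane potential in srnn_step")

  list(state = list(v = v, i_syn = i_syn, a = a, refrac = refrac,
                    i_base = state$i_base, s_prev = s),
       spikes = s)
}

# Batched forward pass (fast path). X: (5 x B x T) spike cube.
# Returns the raw C++ output plus decisions.
forward_batch <- function(X, weights, params = weights$params, seed = 1L,
                          noise_scale = 1, smooth = FALSE,
                          want_grad = FALSE, want_state = FALSE, v0 = NULL) {
  fw <- cpp_srnn_forward(X, w_in_mat(weights), effective_wrec(weights),
                         weights$w_out, weights$a_mask,
                         alpha_syn_vec(params), weights$i_base,
                         cpp_par(params), smooth, noise_scale, want_grad,
                         want_state,
                         as.integer(derive_seed(seed, "noise")),
                         if (is.null(v0)) matrix(0, 0, 0) else v0)
  fw
}

#' Simulate one full trial
#'
#' Rolls the network over every step of the trial's input spike train and
#' the decoder over the excitatory spike output, and applies the decision
#' rule to the final decoder voltages.
#'
#' @param trial one element of a [make_batch()] (fields `spec`, `spikes`,
#'   `y`), or a bare spike matrix.
#' @param weights an [init_network()] result (possibly trained).
#' @param params a [srnn_params()].
#' @param seed integer seed for the trial's noise and initial potentials.
#' @param noise_scale multiplier on both network noise sources (0 = off).
#' @param record keep membrane-potential and synaptic-current traces.
#' @return object of class `trial_record`: `raster` (`n_rec x n_step`
#'   binary), `decoder_v` (`n_outputs x n_step`), `decision`, `tie`,
#'   `currents`/`voltages` when `record = TRUE`, and `spec`.
#' @export
run_trial <- function(trial, weights, params = weights$params, seed = 1L,
                      noise_scale = 1, record = FALSE) {
  spikes <- if (is.matrix(trial)) trial else trial$spikes
  spec <- if (is.matrix(trial)) NULL else trial$spec
  if (nrow(spikes) != 5)
    stop("input spike matrix must have 5 channel rows")
  X <- array(spikes, dim = c(5L, 1L, ncol(spikes)))
  fw <- forward_batch(X, weights, params, seed = seed,
                      noise_scale = noise_scale, want_state = record)
  rec <- structure(list(raster = fw$S[, 1, ], decoder_v = fw$v_dec[, 1, ],
                        spec = spec), class = "trial_record")
  if (record) {
    rec$currents <- fw$I[, 1, ]
    rec$voltages <- fw$V[, 1, ]
  }
  d <- decide(rec, params)
  rec$decision <- d$choice
  rec$tie <- d$tie
  rec
}

#' Decision rule from decoder voltages
#'
#' Two-alternative trials take the argmax of the two decoder voltages at
#' the final step (`[0, 1]` = left, `[1, 0]` = right, so output 1 codes the
#' right choice); four-alternative trials apply a softmax over the four
#' final voltages and take the most probable port. Exact ties resolve to
#' the first output and are flagged.
#'
#' @param record a `trial_record` (or any list with `decoder_v`).
#' @param params a [srnn_params()].
#' @return list `choice` (port label), `index`, `tie`, `prob` (4AFC softmax
#'   probabilities, or normalized voltages for 2AFC).
#' @export
decide <- function(record, params = srnn_params()) {
  v <- record$decoder_v
  v_final <- if (is.matrix(v)) v[, ncol(v)] else v
  n_out <- length(v_final)
  idx <- which.max(v_final)               # ties resolve to first output
  tie <- sum(v_final == max(v_final)) > 1
  if (n_out == 2L) {
    labels <- c("R", "L")
    prob <- if (all(v_final == 0)) rep(0.5, 2) else v_final / sum(abs(v_final))
  } else {
    labels <- c("VL", "VR", "AL", "AR")
    e <- exp(v_final - max(v_final))
    prob <- e / sum(e)
  }
  list(choice = labels[idx], index = idx, tie = tie, prob = prob)
}

# correct-port label for a spec under the decision rule's label set
correct_label <- function(spec, n_outputs) {
  if (n_outputs == 2L) spec$correct_choice
  else c("VL", "VR", "AL", "AR")[port_index_4afc(spec)]
}

#' Run many trials and score accuracy
#'
#' Evaluation protocol: simulate a balanced set of freshly generated trials
#' through the (typically trained) network and report the fraction of
#' correct decisions, overall and split by rule and by stimulus congruency,
#' with a Wilson binomial confidence interval.
#'
#' @param weights an `srnn_weights` object (possibly trained).
#' @param params a [srnn_params()].
#' @param n_trials number of evaluation trials.
#' @param seed integer seed governing both trial generation and network
#'   noise.
#' @param q,delay_ms,distractor,incongruent forwarded to [make_batch()].
#' @param noise_scale network noise multiplier.
#' @param chunk trials are simulated in batches of this size.
#' @return object of class `srnn_evaluation`: `accuracy`, `ci`, `n`,
#'   `by_rule`, `by_congruency` and the per-trial `table`.
#' @export
evaluate <- function(weights, params = weights$params, n_trials = 200,
                     seed = 1L, q = NULL, delay_ms = NULL, distractor = NULL,
                     noise_scale = 1, chunk = 64L, incongruent = FALSE) {
  stopifnot(n_trials >= 1)
  batch <- make_batch(n_trials, params, balance = TRUE,
                      base_seed = derive_seed(seed, "eval"), q = q,
                      delay_ms = delay_ms, distractor = distractor,
                      incongruent = incongruent)
  rows <- vector("list", n_trials)
  done <- 0L
  ci <- 0L
  while (done < n_trials) {
    take <- seq(done + 1L, min(done + chunk, n_trials))
    ba <- batch_arrays(batch[take])
    fw <- forward_batch(ba$X, weights, params,
                        seed = derive_seed(seed, "eval", index = ci + 1L),
                        noise_scale = noise_scale)
    for (j in seq_along(take)) {
      sp <- batch[[take[j]]]$spec
      d <- decide(list(decoder_v = fw$v_dec[, j, , drop = TRUE]), params)
      rows[[take[j]]] <- data.frame(
        trial = take[j], rule = sp$rule,
        congruent = sp$visual_side == sp$auditory_side,
        correct = d$choice == correct_label(sp, params$n_outputs),
        choice = d$choice, target = correct_label(sp, params$n_outputs),
        tie = d$tie)
    }
    done <- max(take); ci <- ci + 1L
  }
  tab <- do.call(rbind, rows)
  acc <- mean(tab$correct)
  by_rule <- tapply(tab$correct, tab$rule, mean)
  by_cong <- tapply(tab$correct, tab$congruent, mean)
  structure(list(accuracy = acc,
                 ci = binom_ci(sum(tab$correct), nrow(tab)),
                 n = nrow(tab), by_rule = by_rule, by_congruency = by_cong,
                 table = tab),
            class = "srnn_evaluation")
}

#' @export
print.srnn_evaluation <- function(x, ...) {
  cat(sprintf("Choice accuracy: %.1f%% (n = %d, 95%% CI %.1f-%.1f%%)\n",
              100 * x$accuracy, x$n, 100 * x$ci["lo"], 100 * x$ci["hi"]))
  cat(sprintf("  by rule: 1 -> %.1f%%, 2 -> %.1f%%\n",
              100 * x$by_rule["1"], 100 * x$by_rule["2"]))
  invisible(x)
}
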