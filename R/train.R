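#' Mean-squared-error readout loss
#'
#' `1 / (2 * scored * n_batch)` times the sum of squared residuals between
#' the target vector and the decoder voltages over the final `scored` steps
#' of every trial in the batch.
#'
#' @param decoder_v `n_outputs x n_batch x n_step` array (or
#'   `n_outputs x n_step` matrix for a single trial) of decoder voltages.
#' @param y `n_outputs x n_batch` target matrix.
#' @param scored number of final steps entering the loss.
#' @return scalar loss.
#' @examples
#' # one trial, every residual 1 over 2 outputs x 5 steps -> loss 1
#' v <- array(0, c(2, 1, 5)); y <- matrix(1, 2, 1)
#' mse_loss(v, y)
#' @export
mse_loss <- function(decoder_v, y, scored = 5) {
  if (length(dim(decoder_v)) == 2)
    decoder_v <- array(decoder_v, c(nrow(decoder_v), 1, ncol(decoder_v)))
  nb <- dim(decoder_v)[2]
  nt <- dim(decoder_v)[3]
  stopifnot(nt >= scored, ncol(y) == nb)
  tot <- 0
  for (t in (nt - scored + 1):nt)
    tot <- tot + sum((y - decoder_v[, , t])^2)
  tot / (2 * scored * nb)
}

#' Population firing-rate regularizer
#'
#' Sum over temporal bins of the squared population-and-batch mean
#' instantaneous firing rate (Hz). One bin spans `bin_steps` integration
#' steps (10 ms at the defaults), so a default 800-ms trial has
#' `n_step / 5 = 80` bins.
#'
#' @param rasters `n_rec x n_batch x n_step` binary array (or
#'   `n_rec x n_step` matrix for one trial).
#' @param bin_steps steps per bin; must divide `n_step`.
#' @param dt integration step (ms).
#' @return scalar regularizer value.
#' @export
fr_regularizer <- function(rasters, bin_steps = 5, dt = 2) {
  if (length(dim(rasters)) == 2)
    rasters <- array(rasters, c(nrow(rasters), 1, ncol(rasters)))
  nt <- dim(rasters)[3]
  if (nt %% bin_steps != 0)
    stop("n_step must be divisible by bin_steps")
  n <- dim(rasters)[1]; nb <- dim(rasters)[2]
  bin_sec <- bin_steps * dt / 1000
  n_bin <- nt %/% bin_steps
  tot <- 0
  for (b in seq_len(n_bin)) {
    idx <- ((b - 1) * bin_steps + 1):(b * bin_steps)
    m <- sum(rasters[, , idx]) / (bin_sec * n * nb)
    tot <- tot + m^2
  }
  tot
}

# one Adam step; st holds m, v, t
adam_step <- function(w, g, st, eta, b1, b2, eps) {
  st$t <- st$t + 1
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g^2
  mh <- st$m / (1 - b1^st$t)
  vh <- st$v / (1 - b2^st$t)
  list(w = w - eta * mh / (sqrt(vh) + eps), st = st)
}

adam_init <- function(w) list(m = 0 * w, v = 0 * w, t = 0)

#' Project recurrent magnitudes onto the Dale-feasible set
#'
#' Clips the magnitude matrix at zero elementwise (and keeps the diagonal
#' zero), so the effective signed matrix never violates Dale's principle.
#' Idempotent.
#'
#' @param m_rec magnitude matrix.
#' @export
dale_project <- function(m_rec) {
  m_rec[m_rec < 0] <- 0
  diag(m_rec) <- 0
  m_rec
}

# gradients for one batch: fused forward (hard threshold, noise on) +
# surrogate BPTT backward in C++. Returns grads and the loss breakdown.
batch_gradients <- function(weights, params, X, Y, control, seed) {
  g <- cpp_srnn_grad(X, w_in_mat(weights), effective_wrec(weights),
                     weights$w_out, weights$a_mask, alpha_syn_vec(params),
                     weights$i_base, cpp_par(params), Y, control$lambda,
                     control$scored_steps, control$reg_bin_steps, 1,
                     as.integer(derive_seed(seed, "noise")))
  list(g_m = g$g_rec * weights$mask$D,   # d(effective)/d(magnitude) = D
       g_in = g$g_in, g_out = g$g_out,
       loss = list(mse = g$mse, fr = g$fr, total = g$total))
}

#' Train a spiking recurrent network on the forced-choice task
#'
#' Fits an excitatory-inhibitory spiking recurrent network to the
#' rule-dependent forced-choice task by backpropagation through time with
#' the SuperSpike fast-sigmoid surrogate in place of the threshold
#' derivative. Adam updates the recurrent magnitudes and the input and
#' output matrices jointly; after every update the magnitudes are clipped at
#' zero so the Dale sign pattern is preserved exactly. Training stops early
#' once held-out validation accuracy stays at or above
#' `control$val_target` for `control$patience` consecutive epochs.
#'
#' @param params a [srnn_params()] describing the network and task.
#' @param control a [srnn_control()] with the optimization settings. With
#'   `control$sfa = FALSE` the adaptation-to-threshold coupling is disabled
#'   during training and evaluation (ablation control).
#' @param seed integer seed governing initialization, batches and noise.
#' @param verbose print a line per epoch (overrides `control$verbose`).
#' @return object of class `srnn`: the trained `weights`, `params`,
#'   `control`, per-epoch `history` (`l_mse`, `l_fr`, `l_total`,
#'   `val_accuracy`), `converged`, `epochs`, and final `val_accuracy`.
#' @examples
#' \donttest{
#' ps <- srnn_preset_small(max_epochs = 2)
#' fit <- srnn(ps$params, ps$control, seed = 1)
#' }
#' @export
srnn <- function(params = srnn_params(), control = srnn_control(),
                 seed = 1L, verbose = control$verbose) {
  attempts <- max(1L, as.integer(control$restarts))
  fit <- NULL
  for (r in seq_len(attempts)) {
    aseed <- if (r == 1L) as.integer(seed) else
      derive_seed(seed, "init", index = 1000L + r)
    if (isTRUE(verbose) && attempts > 1L)
      message(sprintf("-- training attempt %d/%d (seed %d)", r, attempts,
                      aseed))
    cand <- srnn_attempt(params, control, aseed, verbose)
    if (is.null(fit) || cand$val_accuracy > fit$val_accuracy) fit <- cand
    if (fit$converged) break
  }
  fit$seed <- seed
  fit$call <- match.call()
  fit
}

srnn_attempt <- function(params, control, seed, verbose) {
  weights <- init_network(params, seed = seed)
  if (!control$sfa) weights$a_mask <- numeric(params$n_rec)

  st <- list(m = adam_init(weights$m_rec),
             i = adam_init(w_in_mat(weights)),
             o = adam_init(weights$w_out))
  hist <- list()
  streak <- 0L
  converged <- FALSE
  epoch <- 0L

  # working-memory delay curriculum: train at shorter delays first,
  # advance on validation criterion; the last stage is the nominal delay
  stages <- c(control$delay_curriculum, params$delay_ms)
  stage <- 1L
  eta <- control$eta
  annealing <- FALSE
  stage_best <- -1
  stage_stale <- 0L
  best <- list(acc = -1, weights = NULL, epoch = NA_integer_)

  while (epoch < control$max_epochs && !converged) {
    epoch <- epoch + 1L
    ep_mse <- ep_fr <- 0
    for (b in seq_len(control$batches_per_epoch)) {
      bseed <- derive_seed(seed, "batch",
                           index = (epoch - 1L) * control$batches_per_epoch + b)
      batch <- make_batch(control$batch_size, params, balance = TRUE,
                          base_seed = bseed, delay_ms = stages[stage])
      ba <- batch_arrays(batch)
      gr <- batch_gradients(weights, params, ba$X, ba$Y, control, bseed)
      if (!is.finite(gr$loss$total))
        stop("training diverged (non-finite loss) at epoch ", epoch)

      # global gradient-norm clipping (BPTT gradients explode once the
      # trained recurrent gain exceeds one)
      gnorm <- sqrt(sum(gr$g_m^2) + sum(gr$g_in^2) + sum(gr$g_out^2))
      if (is.finite(control$grad_clip) && gnorm > control$grad_clip) {
        sc <- control$grad_clip / gnorm
        gr$g_m <- gr$g_m * sc
        gr$g_in <- gr$g_in * sc
        gr$g_out <- gr$g_out * sc
      }

      up <- adam_step(weights$m_rec, gr$g_m, st$m, eta,
                      control$adam_beta1, control$adam_beta2,
                      control$adam_eps)
      weights$m_rec <- dale_project(up$w); st$m <- up$st

      w_in <- w_in_mat(weights)
      up <- adam_step(w_in, gr$g_in, st$i, eta,
                      control$adam_beta1, control$adam_beta2,
                      control$adam_eps)
      weights$w_cue <- up$w[, 1, drop = FALSE]
      weights$w_sens <- up$w[, 2:5, drop = FALSE]
      st$i <- up$st

      up <- adam_step(weights$w_out, gr$g_out, st$o, eta,
                      control$adam_beta1, control$adam_beta2,
                      control$adam_eps)
      weights$w_out <- up$w; st$o <- up$st

      ep_mse <- ep_mse + gr$loss$mse
      ep_fr <- ep_fr + gr$loss$fr
    }
    ev <- evaluate(weights, params, n_trials = control$val_trials,
                   seed = derive_seed(seed, "val", index = epoch),
                   delay_ms = stages[stage])
    l_mse <- ep_mse / control$batches_per_epoch
    l_fr <- ep_fr / control$batches_per_epoch
    hist[[epoch]] <- data.frame(epoch = epoch, delay_ms = stages[stage],
                                l_mse = l_mse, l_fr = l_fr,
                                l_total = l_mse + control$lambda * l_fr,
                                val_accuracy = ev$accuracy)
    if (isTRUE(verbose))
      message(sprintf("epoch %3d  delay %3.0f  L_mse %.4f  L_fr %.1f  val acc %.3f",
                      epoch, stages[stage], l_mse, l_fr, ev$accuracy))
    at_final <- stage == length(stages)
    if (at_final && ev$accuracy > best$acc)
      best <- list(acc = ev$accuracy, weights = weights, epoch = epoch)

    # learning-rate anneal: consolidate once the stage is nearly solved or
    # its best validation accuracy has stagnated; the rate resets when the
    # curriculum advances and is floored at eta / 10
    if (ev$accuracy > stage_best + 0.01) {
      stage_best <- ev$accuracy
      stage_stale <- 0L
    } else {
      stage_stale <- stage_stale + 1L
    }
    if (ev$accuracy >= control$anneal_start ||
        stage_stale > control$stage_patience) annealing <- TRUE
    if (annealing)
      eta <- max(eta * control$eta_decay, control$eta / 10)

    if (!at_final) {
      if (ev$accuracy >= control$stage_criterion) {
        stage <- stage + 1L
        stage_best <- -1
        stage_stale <- 0L
        annealing <- FALSE
        eta <- control$eta
        if (isTRUE(control$adam_reset_on_stage))
          st <- list(m = adam_init(weights$m_rec),
                     i = adam_init(w_in_mat(weights)),
                     o = adam_init(weights$w_out))
      }
    } else {
      streak <- if (ev$accuracy >= control$val_target) streak + 1L else 0L
      if (streak >= control$patience) converged <- TRUE
    }
  }

  # return the weights with the best nominal-delay validation accuracy
  val_acc <- history_val <- NULL
  if (!is.null(best$weights) && best$acc >= hist[[epoch]]$val_accuracy) {
    weights <- best$weights
    val_acc <- best$acc
  } else {
    val_acc <- hist[[epoch]]$val_accuracy
    best$epoch <- epoch
  }
  history <- do.call(rbind, hist)
  structure(list(weights = weights, params = params, control = control,
                 history = history, converged = converged, epochs = epoch,
                 best_epoch = best$epoch, val_accuracy = val_acc,
                 seed = seed, call = match.call()),
            class = "srnn")
}
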