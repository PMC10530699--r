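#' Simulation parameters for the spiking recurrent network
#'
#' Collects every neuron, synapse, noise and task-timing constant in one
#' validated object. Defaults are the full-scale values: a 500-unit network
#' (80% excitatory), 2-ms integration step, leaky integrate-and-fire dynamics
#' with membrane time constant 20 ms, excitatory/inhibitory synaptic time
#' constants of 35/40 ms, a 400-ms adaptation time constant, 6-ms absolute
#' refractory period, and the noise levels that maintain baseline firing.
#'
#' Units: voltages in mV, currents in nA, time in ms. `r_mohm` is the
#' membrane resistance in megaohm (10 MOhm = 1e-2 GOhm), so `I * r_mohm`
#' is a depolarization in mV. The surrogate-gradient sharpness `beta`
#' follows the SuperSpike convention of acting on a voltage expressed in
#' volts, so `beta = 1000` gives the fast sigmoid a ~1-mV half-width.
#'
#' @param n_rec number of recurrent units.
#' @param phi_exc fraction of excitatory units (0 < phi_exc < 1); the first
#'   `ceiling(phi_exc * n_rec)` units are excitatory.
#' @param dt integration step (ms).
#' @param v_rest,v_th resting potential and baseline spike threshold (mV).
#' @param tau_m membrane time constant (ms).
#' @param tau_syn_exc,tau_syn_inh synaptic time constants (ms) of excitatory
#'   and inhibitory units (applied postsynaptically).
#' @param tau_a adaptation time constant (ms).
#' @param tau_ref absolute refractory period (ms); must be a multiple of `dt`.
#' @param r_mohm membrane resistance (megaohm).
#' @param psi adaptation-to-threshold scale (mV).
#' @param g target spectral radius of the initial recurrent matrix.
#' @param beta surrogate-gradient sharpness (per volt).
#' @param sigma_m diffusion amplitude of the membrane voltage noise
#'   (mV per sqrt-second); the simulator adds Gaussian noise with SD
#'   `sigma_m * sqrt(dt)` each step (Euler-Maruyama).
#' @param sigma_base diffusion amplitude of the baseline-current random
#'   walk (nA per sqrt-second), discretized the same way.
#' @param i_base_scale,i_base_mu,i_base_sd,i_base_lo,i_base_hi baseline
#'   current recipe: `i_base_scale * TruncNormal(i_base_mu, i_base_sd^2)`
#'   truncated to `[i_base_lo, i_base_hi]` before scaling.
#' @param sfa_fraction fraction of units (drawn over the whole population)
#'   carrying spike-frequency adaptation.
#' @param n_outputs number of decoder readout units (2 for 2AFC, 4 for 4AFC).
#' @param enc_tau_m,enc_v_rest,enc_v_th,enc_r encoder LIF constants
#'   (ms, mV, mV, ohm-scale model units).
#' @param dec_tau_m,dec_tau_syn decoder LIF constants (ms).
#' @param fixation_ms,cue_ms,delay_ms,stim_ms task period durations (ms):
#'   fixation with white noise only, rule cue, working-memory delay, and
#'   target stimulus presentation.
#' @param cue_amp length-2 vector of constant cue-current amplitudes for
#'   rule 1 and rule 2 (model units); chosen so both drive the encoder above
#'   threshold at distinct rates.
#' @param stim_amp constant current on the active sensory channels.
#' @param input_noise_sd SD of the zero-mean white-noise current on all input
#'   channels during fixation and delay.
#' @return an object of class `srnn_params` (a validated named list) with
#'   derived fields `n_exc`, `n_inh`, `n_step` and `ref_steps`.
#' @examples
#' p <- srnn_params(n_rec = 160)
#' p$n_exc   # 128
#' p$n_step  # 400 steps = 800 ms / 2 ms
#' @export
srnn_params <- function(n_rec = 500, phi_exc = 0.8, dt = 2,
                        v_rest = -65, v_th = -50, tau_m = 20,
                        tau_syn_exc = 35, tau_syn_inh = 40, tau_a = 400,
                        tau_ref = 6, r_mohm = 10, psi = 1.6, g = 1.5,
                        beta = 1000, sigma_m = 4, sigma_base = 2e-3,
                        i_base_scale = 0.041, i_base_mu = 2,
                        i_base_sd = 0.1, i_base_lo = 1.8, i_base_hi = 2.4,
                        sfa_fraction = 0.25, n_outputs = 2,
                        enc_tau_m = 5, enc_v_rest = 0, enc_v_th = 1,
                        enc_r = 1,
                        dec_tau_m = 5, dec_tau_syn = 20,
                        fixation_ms = 200, cue_ms = 100, delay_ms = 400,
                        stim_ms = 100, cue_amp = c(2.0, 1.2),
                        stim_amp = 2.0, input_noise_sd = 0.05) {
  p <- as.list(environment())

  stopifnot(n_rec >= 2, dt > 0, v_th > v_rest,
            tau_m > 0, tau_syn_exc > 0, tau_syn_inh > 0, tau_a > 0,
            tau_ref >= 0, enc_v_th > enc_v_rest, enc_tau_m > 0,
            dec_tau_m > 0, dec_tau_syn > 0,
            sfa_fraction >= 0, sfa_fraction <= 1,
            n_outputs %in% c(2L, 4L), length(cue_amp) == 2)
  if (phi_exc <= 0 || phi_exc >= 1)
    stop("phi_exc must lie strictly between 0 and 1")
  if (abs(tau_ref / dt - round(tau_ref / dt)) > 1e-9)
    stop("tau_ref must be an integer multiple of dt")
  per <- c(fixation_ms, cue_ms, delay_ms, stim_ms)
  if (any(per <= 0)) stop("all task period durations must be positive")
  if (any(abs(per / dt - round(per / dt)) > 1e-9))
    stop("dt must divide every task period duration")
  if (tau_a <= tau_m || tau_a <= max(tau_syn_exc, tau_syn_inh))
    stop("tau_a must exceed the membrane and synaptic time constants")

  p$n_exc <- as.integer(ceiling(phi_exc * n_rec))
  p$n_inh <- as.integer(n_rec - p$n_exc)
  p$ref_steps <- as.integer(round(tau_ref / dt))
  p$n_step <- as.integer(round(sum(per) / dt))
  class(p) <- "srnn_params"
  p
}

#' @export
print.srnn_params <- function(x, ...) {
  cat(sprintf("SRNN parameters: %d units (%dE + %dI), dt = %g ms\n",
              x$n_rec, x$n_exc, x$n_inh, x$dt))
  cat(sprintf("  trial: %g fix + %g cue + %g delay + %g stim ms (%d steps)\n",
              x$fixation_ms, x$cue_ms, x$delay_ms, x$stim_ms, x$n_step))
  cat(sprintf("  LIF: v_rest %g, v_th %g mV, tau_m %g, tau_syn %g/%g,",
              x$v_rest, x$v_th, x$tau_m, x$tau_syn_exc, x$tau_syn_inh))
  cat(sprintf(" tau_a %g, tau_ref %g ms\n", x$tau_a, x$tau_ref))
  cat(sprintf("  SFA on %.0f%% of units (psi = %g mV); g = %g; beta = %g\n",
              100 * x$sfa_fraction, x$psi, x$g, x$beta))
  invisible(x)
}

# parameter list handed to the C++ kernels. The noise SDs are diffusion
# amplitudes (per sqrt-second); Euler-Maruyama scaling converts them to
# per-step SDs at the integration step.
cpp_par <- function(params, n_step = NULL) {
  sdt <- sqrt(params$dt / 1000)
  list(dt = params$dt, tau_m = params$tau_m, r_eff = params$r_mohm,
       v_rest = params$v_rest, v_th = params$v_th, psi = params$psi,
       tau_a = params$tau_a, beta = params$beta,
       sigma_m = params$sigma_m * sdt,
       sigma_base = params$sigma_base * sdt,
       ref_steps = params$ref_steps,
       dec_tau_syn = params$dec_tau_syn, dec_tau_m = params$dec_tau_m,
       n_exc = params$n_exc)
}

# per-unit synaptic decay factors (E units then I units)
alpha_syn_vec <- function(params) {
  c(rep(exp(-params$dt / params$tau_syn_exc), params$n_exc),
    rep(exp(-params$dt / params$tau_syn_inh), params$n_inh))
}

#' Training control settings
#'
#' @param eta Adam learning rate.
#' @param grad_clip maximum global L2 norm of the gradient (jointly over
#'   the recurrent, input and output matrices); gradients above it are
#'   rescaled before the Adam update. `Inf` (the default) disables
#'   clipping: Adam's per-parameter normalization already absorbs the
#'   large dynamic range of backpropagated spiking-network gradients.
#' @param restarts number of independent training attempts (fresh
#'   initialization and batch stream, seeds derived from `seed`); the
#'   attempt with the best nominal-delay validation accuracy is returned,
#'   and remaining attempts are skipped once one converges. Non-convex
#'   spiking-network training has visible attempt-to-attempt variability,
#'   so a small number of restarts markedly improves the expected outcome.
#' @param adam_reset_on_stage reset the Adam moment estimates whenever the
#'   delay curriculum advances; the gradient scale changes by orders of
#'   magnitude across stages, and stale second moments destabilize the
#'   first updates after a transition.
#' @param lambda weight of the population firing-rate regularizer.
#' @param batch_size trials per gradient update.
#' @param batches_per_epoch gradient updates per epoch.
#' @param max_epochs epoch budget.
#' @param scored_steps number of final stimulus-window steps entering the
#'   mean-squared-error loss.
#' @param reg_bin_steps steps per firing-rate regularizer bin (5 steps =
#'   10 ms at dt = 2).
#' @param sfa logical; train with spike-frequency adaptation enabled.
#' @param val_trials held-out trials used for the per-epoch validation
#'   accuracy.
#' @param val_target,patience early stopping: stop once validation accuracy
#'   is at least `val_target` for `patience` consecutive epochs.
#' @param delay_curriculum optional increasing vector of training delay
#'   durations (ms). Training starts at the first stage and advances to the
#'   next once validation accuracy at the current stage reaches
#'   `stage_criterion`; the final stage is always the task's nominal delay.
#'   Validation, early stopping and all evaluation happen at the nominal
#'   delay once the final stage is reached. `NULL` trains at the nominal
#'   delay throughout.
#' @param stage_criterion validation accuracy required to advance a
#'   curriculum stage.
#' @param eta_decay multiplicative per-epoch decay of the learning rate,
#'   applied at the nominal-delay stage once validation accuracy first
#'   reaches `anneal_start` (consolidation); 1 disables annealing.
#' @param anneal_start validation accuracy that triggers the learning-rate
#'   anneal within a curriculum stage.
#' @param stage_patience number of epochs without improvement of the
#'   stage-best validation accuracy after which the anneal starts
#'   (consolidation when a stage stagnates); the learning rate resets to
#'   `eta` on every stage advance and never anneals below `eta / 10`.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decays and epsilon
#'   (canonical defaults).
#' @param verbose print a line per epoch.
#' @return an object of class `srnn_control`.
#' @export
srnn_control <- function(eta = 3e-4, grad_clip = Inf, lambda = 1e-9,
                         batch_size = 64,
                         batches_per_epoch = 200, max_epochs = 60,
                         scored_steps = 5, reg_bin_steps = 5, sfa = TRUE,
                         val_trials = 64, val_target = 0.99, patience = 3,
                         delay_curriculum = NULL, stage_criterion = 0.95,
                         restarts = 1L, adam_reset_on_stage = TRUE,
                         eta_decay = 1, anneal_start = 0.95,
                         stage_patience = 6L,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8, verbose = FALSE) {
  stopifnot(eta > 0, grad_clip > 0, lambda >= 0, batch_size >= 1,
            batches_per_epoch >= 1,
            max_epochs >= 1, scored_steps >= 1, reg_bin_steps >= 1,
            patience >= 1, stage_criterion > 0, stage_criterion <= 1,
            eta_decay > 0, eta_decay <= 1)
  if (!is.null(delay_curriculum) && is.unsorted(delay_curriculum))
    stop("delay_curriculum must be non-decreasing")
  structure(as.list(environment()), class = "srnn_control")
}

#' Scaled-down preset for desk-scale experiments
#'
#' A 160-unit network (128 excitatory + 32 inhibitory) trained with
#' 32-trial batches and 50 batches per epoch; all neuron constants keep
#' their full-scale values. Two optimization settings are adapted to the
#' reduced scale: a larger Adam learning rate (3e-3) and a working-memory
#' delay curriculum (50, 100, 200, 300 ms stages before the nominal
#' 400 ms), without which desk-scale training does not escape the
#' rule-ignoring plateau within a practical budget. Held-out evaluation is
#' always at the nominal delay.
#'
#' @param ... overrides forwarded to [srnn_params()] (for `$params`) and
#'   [srnn_control()] (for `$control`) by matching argument names.
#' @return list with elements `params` and `control`.
#' @export
srnn_preset_small <- function(...) {
  dots <- list(...)
  pn <- names(formals(srnn_params))
  cn <- names(formals(srnn_control))
  pargs <- dots[names(dots) %in% pn]
  cargs <- dots[names(dots) %in% cn]
  bad <- setdiff(names(dots), c(pn, cn))
  if (length(bad)) stop("unknown arguments: ", paste(bad, collapse = ", "))
  params <- do.call(srnn_params, modifyList(list(n_rec = 160), pargs))
  curriculum <- c(50, 100, 150, 200, 250, 300, 350)
  curriculum <- curriculum[curriculum < params$delay_ms]
  control <- do.call(srnn_control,
                     modifyList(list(batch_size = 32, batches_per_epoch = 50,
                                     max_epochs = 30, restarts = 3L,
                                     eta = 3e-3, lambda = 1e-4,
                                     eta_decay = 0.93, val_trials = 96,
                                     delay_curriculum = curriculum),
                                cargs))
  list(params = params, control = control)
}
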