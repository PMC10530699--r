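#' @export
print.srnn <- function(x, ...) {
  p <- x$params
  cat(sprintf("Spiking recurrent network (%dE + %dI units, %d-way choice)\n",
              p$n_exc, p$n_inh, p$n_outputs))
  cat(sprintf("  trained %d epoch(s); %s; validation accuracy %.1f%%\n",
              x$epochs,
              if (x$converged) "converged (early stop)" else "epoch budget",
              100 * x$val_accuracy))
  cat(sprintf("  SFA %s; eta %.1e; lambda %.1e; batch %d x %d/epoch\n",
              if (x$control$sfa) "on" else "off", x$control$eta,
              x$control$lambda, x$control$batch_size,
              x$control$batches_per_epoch))
  invisible(x)
}

#' @export
summary.srnn <- function(object, n_trials = 200, seed = 1L, ...) {
  ev <- evaluate(object$weights, object$params, n_trials = n_trials,
                 seed = seed)
  out <- list(fit = object, evaluation = ev)
  class(out) <- "summary.srnn"
  out
}

#' @export
print.summary.srnn <- function(x, ...) {
  print(x$fit)
  cat("\nHeld-out evaluation:\n")
  print(x$evaluation)
  invisible(x)
}

#' Extract the network weight matrices
#'
#' @param object a fitted [srnn()] object.
#' @param ... unused.
#' @return list with the effective signed recurrent matrix `w_rec`, the
#'   nonnegative magnitudes `m_rec`, the Dale mask, `w_cue`, `w_sens`,
#'   `w_out`, the SFA assignment `a_mask` and the baseline currents.
#' @export
coef.srnn <- function(object, ...) {
  w <- object$weights
  list(w_rec = effective_wrec(w), m_rec = w$m_rec, dale_mask = w$mask$D,
       w_cue = w$w_cue, w_sens = w$w_sens, w_out = w$w_out,
       a_mask = w$a_mask, i_base = w$i_base)
}

#' Predict choices for new trials
#'
#' @param object a fitted [srnn()] object.
#' @param newdata a data frame with columns `rule`, `visual_side`,
#'   `auditory_side` and optionally `mixture_q`, `delay_ms`; or a list of
#'   [trial_spec()] objects; or `NULL` to draw `n` fresh balanced trials.
#' @param n number of trials when `newdata` is `NULL`.
#' @param seed integer seed.
#' @param ... unused.
#' @return data frame with the trial descriptors, predicted `choice`, and
#'   `correct` flag.
#' @export
predict.srnn <- function(object, newdata = NULL, n = 20, seed = 1L, ...) {
  p <- object$params
  specs <- if (is.null(newdata)) {
    lapply(make_batch(n, p, base_seed = seed), `[[`, "spec")
  } else if (is.data.frame(newdata)) {
    lapply(seq_len(nrow(newdata)), function(i) {
      r <- newdata[i, ]
      trial_spec(r$rule, r$visual_side, r$auditory_side,
                 mixture_q = if ("mixture_q" %in% names(newdata))
                   r$mixture_q else if (r$rule == 1) 1 else 0,
                 delay_ms = if ("delay_ms" %in% names(newdata))
                   r$delay_ms else p$delay_ms,
                 seed = derive_seed(seed, "trial", index = i))
    })
  } else newdata
  rows <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    trial <- list(spec = sp,
                  spikes = encode_to_spikes(build_trial_inputs(sp, p), p))
    rec <- run_trial(trial, object$weights, p,
                     seed = derive_seed(seed, "eval", index = i))
    data.frame(rule = sp$rule, visual_side = sp$visual_side,
               auditory_side = sp$auditory_side, mixture_q = sp$mixture_q,
               choice = rec$decision,
               correct = rec$decision == correct_label(sp, p$n_outputs))
  })
  do.call(rbind, rows)
}

#' Simulate trials through a fitted network
#'
#' @param object a fitted [srnn()] object.
#' @param nsim number of trials.
#' @param seed integer seed.
#' @param q,delay_ms,distractor forwarded to [make_batch()].
#' @param record keep current/voltage traces on each record.
#' @param noise_only zero out all input spike trains (white-noise-only
#'   condition: the network runs on its intrinsic noise; used as the
#'   chance-level control for sequence statistics).
#' @param ... unused.
#' @return list of `trial_record` objects (class `srnn_records`).
#' @export
simulate.srnn <- function(object, nsim = 50, seed = 1L, q = NULL,
                          delay_ms = NULL, distractor = NULL,
                          record = FALSE, noise_only = FALSE, ...) {
  p <- object$params
  batch <- make_batch(nsim, p, base_seed = derive_seed(seed, "trial"),
                      q = q, delay_ms = delay_ms, distractor = distractor)
  out <- lapply(seq_along(batch), function(i) {
    trial <- batch[[i]]
    if (noise_only) trial$spikes[] <- 0
    run_trial(trial, object$weights, p,
              seed = derive_seed(seed, "noise", index = i),
              record = record)
  })
  class(out) <- "srnn_records"
  out
}

#' Plot training history or a spike raster
#'
#' @param x a fitted [srnn()] object.
#' @param which `"history"` (loss and validation accuracy per epoch) or
#'   `"raster"` (spike raster of one freshly simulated trial).
#' @param seed seed for the raster trial.
#' @param ... forwarded to the base plotting calls.
#' @export
plot.srnn <- function(x, which = c("history", "raster"), seed = 1L, ...) {
  which <- match.arg(which)
  if (which == "history") {
    h <- x$history
    op <- par(mfrow = c(1, 2)); on.exit(par(op))
    plot(h$epoch, h$l_mse, type = "b", xlab = "epoch", ylab = "MSE loss",
         main = "readout loss", ...)
    plot(h$epoch, h$val_accuracy, type = "b", ylim = c(0, 1),
         xlab = "epoch", ylab = "validation accuracy",
         main = "held-out accuracy", ...)
    abline(h = 0.5, lty = 3)
  } else {
    rec <- simulate(x, nsim = 1, seed = seed)[[1]]
    sp <- which(rec$raster == 1, arr.ind = TRUE)
    plot(sp[, 2] * x$params$dt, sp[, 1], pch = ".", cex = 2,
         xlab = "time (ms)", ylab = "unit",
         main = sprintf("trial raster (rule %d)", rec$spec$rule), ...)
    abline(v = cumsum(c(x$params$fixation_ms, x$params$cue_ms,
                        rec$spec$delay_ms)), lty = 3)
    abline(h = x$params$n_exc + 0.5, col = 2, lty = 2)
  }
  invisible(x)
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("Trial record: %d units x %d steps, %d spikes, decision %s\n",
              nrow(x$raster), ncol(x$raster), sum(x$raster),
              x$decision %||% "?"))
  if (!is.null(x$spec))
    cat(sprintf("  rule %d, V/%s A/%s, correct %s\n", x$spec$rule,
                x$spec$visual_side, x$spec$auditory_side,
                x$spec$correct_choice))
  invisible(x)
}
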