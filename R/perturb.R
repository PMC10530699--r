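# Test-time manipulations of a trained network. All perturbations are pure
# functions of (weights, spec, seed) and never touch the Dale sign pattern:
# they act on the nonnegative magnitude matrix, so the mask keeps signs
# intact by construction.

resolve_weights <- function(object) {
  if (inherits(object, "srnn")) object$weights
  else if (inherits(object, "srnn_weights")) object
  else stop("expected an 'srnn' fit or an 'srnn_weights' object")
}

#' Psychometric sweep over rule-cue ambiguity
#'
#' Evaluates choice accuracy while the cue carries a convex mixture of the
#' two rule waveforms. `q` is the proportion of the nominal rule's signal:
#' `q = 1` is a clean cue, `q = 0.5` maximally ambiguous. Trials are
#' incongruent (conflicting sides) by default, since congruent trials are
#' solved without the rule and would pin the psychometric floor at 75%
#' rather than chance.
#'
#' @param object an [srnn()] fit or `srnn_weights`.
#' @param q_grid ambiguity levels.
#' @param n_trials trials per grid point (>= 50 recommended).
#' @param seed integer seed.
#' @param params simulation parameters (defaults to the fit's).
#' @param incongruent restrict to incongruent trials.
#' @return data frame (`q`, `accuracy`, `ci_lo`, `ci_hi`, `n`).
#' @export
sweep_mixture <- function(object, q_grid = seq(0.5, 1, by = 0.1),
                          n_trials = 100, seed = 1L, params = NULL,
                          incongruent = TRUE) {
  w <- resolve_weights(object)
  params <- params %||% w$params
  rows <- lapply(seq_along(q_grid), function(i) {
    ev <- evaluate(w, params, n_trials = n_trials,
                   seed = derive_seed(seed, "perturb", index = i),
                   q = q_grid[i], incongruent = incongruent)
    data.frame(q = q_grid[i], accuracy = ev$accuracy,
               ci_lo = ev$ci["lo"], ci_hi = ev$ci["hi"], n = ev$n)
  })
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}

#' Accuracy and tuning persistence under delay elongation
#'
#' Re-tests the trained network with longer working-memory delays (no
#' retraining). Optionally compares rule tuning between the baseline and the
#' longest delay: units tuned at baseline whose peak time is preserved
#' (within `peak_tol_ms` inside the original delay window) versus units
#' newly peaked in the extended window.
#'
#' @param object an [srnn()] fit or `srnn_weights`.
#' @param delays_ms delay durations to test; the first is the baseline.
#' @param n_trials trials per delay.
#' @param seed integer seed.
#' @param params simulation parameters.
#' @param tuning_report also classify per-unit tuning persistence (simulates
#'   `tuning_trials` extra trials at the first and last delay).
#' @param tuning_trials trials per rule for the tuning comparison.
#' @param peak_tol_ms tolerance for calling a peak time preserved.
#' @return list with `accuracy` data frame and (optionally) `persistence`
#'   (fractions of all units preserving/gaining tuning).
#' @export
sweep_delay <- function(object, delays_ms = c(400, 600, 800),
                        n_trials = 100, seed = 1L, params = NULL,
                        tuning_report = FALSE, tuning_trials = 25,
                        peak_tol_ms = 24) {
  w <- resolve_weights(object)
  params <- params %||% w$params
  rows <- lapply(seq_along(delays_ms), function(i) {
    ev <- evaluate(w, params, n_trials = n_trials,
                   seed = derive_seed(seed, "perturb", index = 100 + i),
                   delay_ms = delays_ms[i])
    data.frame(delay_ms = delays_ms[i], accuracy = ev$accuracy,
               ci_lo = ev$ci["lo"], ci_hi = ev$ci["hi"], n = ev$n)
  })
  out <- list(accuracy = do.call(rbind, rows))
  rownames(out$accuracy) <- NULL
  if (tuning_report) {
    base_ms <- delays_ms[1]; long_ms <- delays_ms[length(delays_ms)]
    recs <- lapply(c(base_ms, long_ms), function(dm) {
      fit_like <- list(weights = w, params = params)
      class(fit_like) <- "srnn"
      simulate(fit_like, nsim = 2 * tuning_trials,
               seed = derive_seed(seed, "analysis", index = dm),
               delay_ms = dm)
    })
    tun <- lapply(recs, function(rc)
      find_tuned_units(psth_zscore(rc, params)))
    t0 <- tun[[1]]$table; t1 <- tun[[2]]$table
    tuned0 <- t0$label != "none"
    # preserved: tuned at baseline, still tuned, peak within tolerance
    pk0 <- pmin(t0$peak_ms_r1, t0$peak_ms_r2, na.rm = TRUE)
    pk1 <- pmin(t1$peak_ms_r1, t1$peak_ms_r2, na.rm = TRUE)
    preserved <- tuned0 & t1$label != "none" &
      !is.na(pk0) & !is.na(pk1) & abs(pk1 - pk0) <= peak_tol_ms
    # newly peaked: untuned at baseline, peak in the extended window
    fix_cue <- params$fixation_ms + params$cue_ms
    late <- !tuned0 & t1$label != "none" &
      (pmax(t1$peak_ms_r1, t1$peak_ms_r2, na.rm = TRUE) - fix_cue) > base_ms
    out$persistence <- c(frac_preserved = mean(preserved, na.rm = TRUE),
                         frac_new_late = mean(late, na.rm = TRUE))
  }
  out
}

#' Randomly sparsify the recurrent weights
#'
#' Sets exactly `floor(fraction * nnz)` randomly chosen nonzero recurrent
#' magnitude entries to zero; surviving entries (and hence Dale signs) are
#' untouched. Reapplying with the same seed reproduces the same weights.
#'
#' @param weights an `srnn_weights` object (or [srnn()] fit).
#' @param fraction fraction of nonzero entries to drop, in `[0, 1)`.
#' @param seed integer seed.
#' @return modified `srnn_weights`.
#' @export
sparsify <- function(weights, fraction, seed = 1L) {
  w <- resolve_weights(weights)
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  nz <- which(w$m_rec != 0)
  k <- floor(fraction * length(nz))
  if (k > 0) {
    set.seed(derive_seed(seed, "perturb"))
    w$m_rec[sample(nz, k)] <- 0
  }
  w
}

#' Scale one cell-type connectivity block
#'
#' Multiplies the recurrent magnitudes of one block (`EE`, `EI`, `IE`, `II`;
#' first letter = postsynaptic population, second = presynaptic) by a
#' factor. Scaling magnitudes preserves the Dale projection by construction.
#'
#' @param weights an `srnn_weights` object (or [srnn()] fit).
#' @param block `"EE"`, `"EI"`, `"IE"` or `"II"`.
#' @param factor positive scale factor.
#' @return modified `srnn_weights`.
#' @export
scale_block <- function(weights, block = c("EE", "EI", "IE", "II"),
                        factor) {
  w <- resolve_weights(weights)
  block <- match.arg(block)
  if (!is.numeric(factor) || factor <= 0) stop("factor must be positive")
  ne <- w$params$n_exc
  n <- w$params$n_rec
  e <- seq_len(ne); i <- (ne + 1):n
  rows <- if (substr(block, 1, 1) == "E") e else i
  cols <- if (substr(block, 2, 2) == "E") e else i
  w$m_rec[rows, cols] <- w$m_rec[rows, cols] * factor
  w
}

#' Accuracy and population rates under E/I block scaling
#'
#' Applies [scale_block()] over a factor grid and reports choice accuracy
#' together with the mean delay-period firing rates of the excitatory and
#' inhibitory populations.
#'
#' @param object an [srnn()] fit or `srnn_weights`.
#' @param block connectivity block to scale.
#' @param factors scale factors.
#' @param n_trials trials per factor.
#' @param seed integer seed.
#' @param params simulation parameters.
#' @return data frame (`factor`, `accuracy`, `ci_lo`, `ci_hi`, `rate_exc`,
#'   `rate_inh`).
#' @export
sweep_block_scaling <- function(object, block = "EE",
                                factors = c(0.5, 1, 2, 5), n_trials = 60,
                                seed = 1L, params = NULL) {
  w0 <- resolve_weights(object)
  params <- params %||% w0$params
  rows <- lapply(seq_along(factors), function(i) {
    w <- scale_block(w0, block, factors[i])
    ev <- evaluate(w, params, n_trials = n_trials,
                   seed = derive_seed(seed, "perturb", index = 200 + i))
    fit_like <- structure(list(weights = w, params = params),
                          class = "srnn")
    recs <- simulate(fit_like, nsim = 10,
                     seed = derive_seed(seed, "analysis", index = 200 + i))
    re <- mean(vapply(recs, function(r)
      mean(r$raster[seq_len(params$n_exc), delay_steps(r, params)]), 0)) /
      (params$dt / 1000)
    ri <- mean(vapply(recs, function(r)
      mean(r$raster[params$n_exc + seq_len(params$n_inh),
                    delay_steps(r, params)]), 0)) / (params$dt / 1000)
    data.frame(factor = factors[i], accuracy = ev$accuracy,
               ci_lo = ev$ci["lo"], ci_hi = ev$ci["hi"],
               rate_exc = re, rate_inh = ri, n = ev$n)
  })
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}

#' Accuracy under input-noise and delay-distractor manipulations
#'
#' Varies the background white-noise SD of the input channels and injects a
#' 50-ms pulse distractor on the cue channel during chosen windows of the
#' delay, reporting accuracy per condition.
#'
#' @param object an [srnn()] fit or `srnn_weights`.
#' @param noise_sds input white-noise SD grid (`NULL` skips the noise
#'   sweep).
#' @param windows_ms distractor onset windows (ms after delay start); the
#'   pulse starts at the window start.
#' @param amplitudes distractor amplitude grid (`NULL` skips).
#' @param n_trials trials per condition.
#' @param seed integer seed.
#' @param params simulation parameters.
#' @return list of data frames `noise` and `distractor`.
#' @export
sweep_noise_distractor <- function(object, noise_sds = c(0.05, 0.5, 1),
                                   windows_ms = c(0, 100, 200, 300),
                                   amplitudes = c(0, 1, 2), n_trials = 60,
                                   seed = 1L, params = NULL) {
  w <- resolve_weights(object)
  params <- params %||% w$params
  noise_tab <- NULL
  if (!is.null(noise_sds)) {
    rows <- lapply(seq_along(noise_sds), function(i) {
      p2 <- params; p2$input_noise_sd <- noise_sds[i]
      ev <- evaluate(w, p2, n_trials = n_trials,
                     seed = derive_seed(seed, "perturb", index = 300 + i))
      data.frame(noise_sd = noise_sds[i], accuracy = ev$accuracy,
                 ci_lo = ev$ci["lo"], ci_hi = ev$ci["hi"], n = ev$n)
    })
    noise_tab <- do.call(rbind, rows); rownames(noise_tab) <- NULL
  }
  dist_tab <- NULL
  if (!is.null(amplitudes)) {
    grid <- expand.grid(window_ms = windows_ms, amplitude = amplitudes)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      d <- if (grid$amplitude[i] == 0) NULL else
        list(onset_ms = grid$window_ms[i], duration_ms = 50,
             amplitude = grid$amplitude[i])
      ev <- evaluate(w, params, n_trials = n_trials,
                     seed = derive_seed(seed, "perturb", index = 400 + i),
                     distractor = d)
      data.frame(window_ms = grid$window_ms[i],
                 amplitude = grid$amplitude[i], accuracy = ev$accuracy,
                 ci_lo = ev$ci["lo"], ci_hi = ev$ci["hi"], n = ev$n)
    })
    dist_tab <- do.call(rbind, rows); rownames(dist_tab) <- NULL
  }
  list(noise = noise_tab, distractor = dist_tab)
}
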