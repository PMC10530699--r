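# Shared fixtures. Everything is generated in code; the expensive trained
# networks are built once per test session and reused across test files.

small_params <- function(...) srnn_params(n_rec = 160, ...)

tiny_params <- function(...) srnn_params(n_rec = 10, phi_exc = 0.8, ...)

# a weights object with everything zeroed: the silent network
silent_weights <- function(params = tiny_params()) {
  w <- init_network(params, seed = 1)
  w$m_rec[] <- 0
  w$w_cue[] <- 0
  w$w_sens[] <- 0
  w$w_out[] <- 0
  w$i_base[] <- 0
  w
}

# synthetic trial records with prescribed rasters (for analysis-module
# oracles): `rate_fun(unit, rule)` returns per-step spike probabilities
synthetic_records <- function(n_units, n_trials_per_rule, params,
                              rate_fun, seed = 1) {
  set.seed(seed)
  nt <- params$n_step
  out <- list()
  for (rule in 1:2) {
    for (k in seq_len(n_trials_per_rule)) {
      raster <- matrix(0, n_units, nt)
      for (i in seq_len(n_units)) {
        pr <- rate_fun(i, rule)
        pr <- rep_len(pr, nt)
        raster[i, ] <- rbinom(nt, 1, pmin(pr, 1))
      }
      spec <- trial_spec(rule, "L", "R", delay_ms = params$delay_ms,
                        seed = k)
      rec <- structure(list(raster = raster, spec = spec,
                            decoder_v = matrix(0, 2, nt)),
                       class = "trial_record")
      out[[length(out) + 1]] <- rec
    }
  }
  class(out) <- "srnn_records"
  out
}

# ---- session-cached trained networks (scaled-down study conditions) ----
.fit_cache <- new.env(parent = emptyenv())

trained_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    ps <- srnn_preset_small()
    .fit_cache$fit <- srnn(ps$params, ps$control, seed = 1)
  }
  .fit_cache$fit
}

# ablation control: one training attempt without SFA under the same
# per-attempt epoch budget the selected SFA network used
sfa_off_fit <- function() {
  if (is.null(.fit_cache$off)) {
    budget <- max(10L, trained_fit()$epochs)
    ps <- srnn_preset_small(sfa = FALSE, restarts = 1,
                            max_epochs = budget)
    .fit_cache$off <- srnn(ps$params, ps$control, seed = 1)
  }
  .fit_cache$off
}
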