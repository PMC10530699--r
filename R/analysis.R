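#' Trial-averaged binned firing rates during the delay period
#'
#' Helper shared by the sequence, trajectory and decoding analyses: bins each
#' unit's delay-period spikes and converts to rates in Hz.
#'
#' @param records an `srnn_records` list from [simulate.srnn()] or a list of
#'   [run_trial()] results (trials must share the delay duration).
#' @param params the [srnn_params()] the records were simulated under.
#' @param bin_ms bin width (ms); must divide the delay duration.
#' @param units `"exc"`, `"inh"` or `"all"`.
#' @param rule restrict to trials of one rule (`NULL` = all trials).
#' @param average trial-average (matrix `units x bins`) or per-trial array
#'   (`units x bins x trials`).
#' @export
binned_delay_rates <- function(records, params, bin_ms = 8, units = "exc",
                               rule = NULL, average = TRUE) {
  if (!is.null(rule))
    records <- Filter(function(r) r$spec$rule == rule, records)
  if (!length(records)) stop("no trials left after rule filtering")
  uidx <- switch(units, exc = seq_len(params$n_exc),
                 inh = params$n_exc + seq_len(params$n_inh),
                 all = seq_len(params$n_rec),
                 stop("units must be 'exc', 'inh' or 'all'"))
  dwin <- delay_steps(records[[1]], params)
  steps_per_bin <- bin_ms / params$dt
  if (abs(steps_per_bin - round(steps_per_bin)) > 1e-9)
    stop("dt must divide bin_ms")
  steps_per_bin <- as.integer(round(steps_per_bin))
  if (length(dwin) %% steps_per_bin != 0)
    stop("bin_ms must divide the delay duration")
  n_bin <- length(dwin) %/% steps_per_bin
  bin_sec <- bin_ms / 1000
  grp <- rep(seq_len(n_bin), each = steps_per_bin)
  arr <- vapply(records, function(r) {
    x <- r$raster[uidx, dwin, drop = FALSE]
    t(rowsum(t(x), grp)) / bin_sec
  }, matrix(0, length(uidx), n_bin))
  if (average) apply(arr, c(1, 2), mean) else arr
}

# step indices of the delay period for a record's trial structure
delay_steps <- function(record, params) {
  delay_ms <- if (!is.null(record$spec)) record$spec$delay_ms else
    params$delay_ms
  start <- (params$fixation_ms + params$cue_ms) / params$dt
  start + seq_len(delay_ms / params$dt)
}

# Gaussian smoothing along a vector, kernel SD in bins; the kernel is
# renormalized where it is truncated at the edges
gauss_smooth <- function(x, sd_bins) {
  if (sd_bins <= 0) return(x)
  half <- ceiling(4 * sd_bins)
  k <- dnorm(-half:half, sd = sd_bins)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    kk <- k[(lo - i + half + 1):(hi - i + half + 1)]
    out[i] <- sum(x[lo:hi] * kk) / sum(kk)
  }
  out
}

#' Z-scored peri-stimulus time histograms per unit and rule
#'
#' For each unit and rule the spikes of all trials are binned (8-ms bins),
#' converted to rates and convolved with a Gaussian kernel (SD = `kernel_sd`
#' bins). The smoothed series is z-scored against the delay period pooled
#' across both rules: the pooled delay mean of the smoothed series is
#' subtracted (so every retained z-series has exactly zero delay mean), and
#' the result is divided by the pooled delay SD of the *unsmoothed* binned
#' PSTH. Normalizing by the raw-rate variability calibrates the peak
#' criterion: a z = 2 threshold then flags at most ~5% of homogeneous
#' (untuned) units, whereas normalizing by the smoothed series' own SD
#' would make threshold crossings of pure noise commonplace. Units whose
#' pooled raw delay SD is zero are flagged and excluded from tuning
#' analysis.
#'
#' @param records an `srnn_records` list containing trials of both rules.
#' @param params the [srnn_params()] used for simulation.
#' @param bin_ms PSTH bin width (ms).
#' @param kernel_sd Gaussian kernel SD in bins.
#' @param units `"exc"`, `"inh"` or `"all"`.
#' @return object of class `srnn_tuning`: arrays `z` and `rate`
#'   (`units x bins x rules`, full trial length), `mean_delay_fr`
#'   (`units x rules`, unsmoothed Hz), pooled `delay_fr`, logical `excluded`,
#'   bin metadata and the unit index map.
#' @export
psth_zscore <- function(records, params, bin_ms = 8, kernel_sd = 4,
                        units = "all") {
  by_rule <- lapply(1:2, function(r)
    Filter(function(x) x$spec$rule == r, records))
  if (any(vapply(by_rule, length, 0L) < 2))
    stop("need at least 2 trials per rule")
  uidx <- switch(units, exc = seq_len(params$n_exc),
                 inh = params$n_exc + seq_len(params$n_inh),
                 all = seq_len(params$n_rec))
  nu <- length(uidx)
  steps_per_bin <- as.integer(round(bin_ms / params$dt))
  nt <- ncol(records[[1]]$raster)
  n_bin <- nt %/% steps_per_bin
  grp <- rep(seq_len(n_bin), each = steps_per_bin)[seq_len(nt)]
  bin_sec <- bin_ms / 1000
  dwin <- delay_steps(records[[1]], params)
  delay_bins <- unique(grp[dwin])

  rate <- array(0, c(nu, n_bin, 2))      # smoothed spike-density (Hz)
  raw <- array(0, c(nu, n_bin, 2))       # unsmoothed binned PSTH (Hz)
  for (r in 1:2) {
    acc <- matrix(0, nu, n_bin)
    for (rec in by_rule[[r]]) {
      x <- rec$raster[uidx, seq_len(steps_per_bin * n_bin), drop = FALSE]
      acc <- acc + t(rowsum(t(x), grp[seq_len(steps_per_bin * n_bin)]))
    }
    raw[, , r] <- acc / (length(by_rule[[r]]) * bin_sec)
    rate[, , r] <- t(apply(raw[, , r], 1, gauss_smooth,
                           sd_bins = kernel_sd))
  }

  # z-score: delay mean of the smoothed series, delay SD of the raw PSTH,
  # both pooled over the two rules
  z <- array(NA_real_, c(nu, n_bin, 2))
  excluded <- logical(nu)
  for (i in seq_len(nu)) {
    s <- sd(c(raw[i, delay_bins, 1], raw[i, delay_bins, 2]))
    mu <- mean(c(rate[i, delay_bins, 1], rate[i, delay_bins, 2]))
    if (!is.finite(s) || s == 0) { excluded[i] <- TRUE; next }
    z[i, , ] <- (rate[i, , ] - mu) / s
  }

  # unsmoothed mean delay rate (Hz) per rule
  mean_delay_fr <- vapply(1:2, function(r) {
    vapply(by_rule[[r]], function(rec)
      rowMeans(rec$raster[uidx, dwin, drop = FALSE]), numeric(nu)) |>
      rowMeans() / (params$dt / 1000)
  }, numeric(nu))

  structure(list(z = z, rate = rate, mean_delay_fr = mean_delay_fr,
                 delay_fr = rowMeans(mean_delay_fr), excluded = excluded,
                 bin_ms = bin_ms, kernel_sd = kernel_sd,
                 delay_bins = delay_bins, units = uidx,
                 n_exc = params$n_exc,
                 bin_time_ms = (seq_len(n_bin) - 0.5) * bin_ms),
            class = "srnn_tuning")
}

# local maxima of a z-series above a threshold (runs of ties count once)
find_peaks <- function(z, thresh) {
  n <- length(z)
  if (n < 3) return(integer(0))
  idx <- which(z[2:(n - 1)] > z[1:(n - 2)] & z[2:(n - 1)] >= z[3:n]) + 1L
  idx[z[idx] >= thresh]
}

#' Classify units by rule-specific delay tuning
#'
#' A unit is tuned to a rule if its pooled delay-period firing rate is at
#' least `min_fr` Hz and its z-scored delay PSTH under that rule has at
#' least one local peak with z >= `z_thresh`. Units tuned under both rules
#' are labelled `"both"`.
#'
#' @param tuning a [psth_zscore()] result.
#' @param z_thresh z-score threshold for genuine peaks.
#' @param min_fr minimum pooled delay firing rate (Hz).
#' @return object of class `srnn_tuned_units`: per-unit data frame `table`
#'   (label, peak counts, peak times, PNR per rule) and `summary` with tuned
#'   fractions of the excitatory population.
#' @export
find_tuned_units <- function(tuning, z_thresh = 2, min_fr = 2) {
  nu <- dim(tuning$z)[1]
  db <- tuning$delay_bins
  rows <- vector("list", nu)
  for (i in seq_len(nu)) {
    res <- list(unit = tuning$units[i],
                is_exc = tuning$units[i] <= tuning$n_exc,
                mean_delay_fr = tuning$delay_fr[i])
    if (tuning$excluded[i] || tuning$delay_fr[i] < min_fr) {
      rows[[i]] <- data.frame(res, label = "none", n_peaks_r1 = 0L,
                              n_peaks_r2 = 0L, peak_ms_r1 = NA_real_,
                              peak_ms_r2 = NA_real_, pnr_r1 = NA_real_,
                              pnr_r2 = NA_real_)
      next
    }
    pk <- lapply(1:2, function(r)
      find_peaks(tuning$z[i, db, r], z_thresh))
    tuned <- vapply(pk, length, 0L) > 0
    label <- c("none", "rule1", "rule2", "both")[
      1 + tuned[1] + 2 * tuned[2]]
    pkms <- vapply(1:2, function(r) {
      if (!length(pk[[r]])) return(NA_real_)
      best <- pk[[r]][which.max(tuning$z[i, db, r][pk[[r]]])]
      tuning$bin_time_ms[db[best]]
    }, 0)
    rows[[i]] <- data.frame(res, label = label,
                            n_peaks_r1 = length(pk[[1]]),
                            n_peaks_r2 = length(pk[[2]]),
                            peak_ms_r1 = pkms[1], peak_ms_r2 = pkms[2],
                            pnr_r1 = pnr(tuning$z[i, db, 1],
                                         tuning$kernel_sd),
                            pnr_r2 = pnr(tuning$z[i, db, 2],
                                         tuning$kernel_sd))
  }
  tab <- do.call(rbind, rows)
  e <- tab[tab$is_exc, ]
  summary <- c(frac_tuned_exc = mean(e$label != "none"),
               frac_rule1_exc = mean(e$label == "rule1"),
               frac_rule2_exc = mean(e$label == "rule2"),
               frac_both_exc = mean(e$label == "both"))
  structure(list(table = tab, summary = summary,
                 z_thresh = z_thresh, min_fr = min_fr),
            class = "srnn_tuned_units")
}

#' @export
print.srnn_tuned_units <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Tuned excitatory units: %.1f%% (rule 1 %.1f%%, rule 2 %.1f%%, both %.1f%%)\n",
    100 * s[1], 100 * s[2], 100 * s[3], 100 * s[4]))
  invisible(x)
}

#' Peak-to-noise ratio of a delay-period z-series
#'
#' Peak = maximum z during the delay; noise = SD of the series excluding a
#' region of +/- 2 smoothing-kernel SDs around the peak. A floor guards the
#' noise estimate for degenerate (near-flat) series; an empty non-peak
#' region yields `NA`.
#'
#' @param z delay-period z-scored rate series (one rule).
#' @param kernel_sd smoothing kernel SD in bins (defines the excluded
#'   region).
#' @param noise_floor lower bound on the noise SD.
#' @return scalar PNR.
#' @export
pnr <- function(z, kernel_sd = 4, noise_floor = 1e-6) {
  z <- as.numeric(z)
  if (!length(z) || anyNA(z)) return(NA_real_)
  ipk <- which.max(z)
  excl <- max(1, ipk - 2 * kernel_sd):min(length(z), ipk + 2 * kernel_sd)
  rest <- z[-excl]
  if (length(rest) < 2) return(NA_real_)
  z[ipk] / max(sd(rest), noise_floor)
}

#' Sequentiality index of a population delay response
#'
#' SI = entropy of the distribution of per-unit peak-response times plus the
#' mean log ridge-to-background ratio, where the ridge is each unit's mean
#' rate inside a window centred on its peak bin and the background its mean
#' rate outside. High SI indicates transient peaks tiling the delay; the
#' entropy term is 0 when all units peak together and `log(n_bins)` when
#' peaks are uniform.
#'
#' @param delay_rates matrix `units x bins` of delay firing rates (Hz).
#' @param bin_ms bin width (ms).
#' @param peak_window_ms window around each unit's peak (total width); the
#'   default 50 ms spans ~3 bins at 8-ms bins.
#' @param rate_floor floor (Hz) applied inside and outside the window before
#'   the log ratio.
#' @return object of class `srnn_si`: `si`, `entropy`, `ridge`,
#'   `p_peak` (peak-time distribution) and `peak_bin` per unit.
#' @examples
#' r <- rbind(c(4, 1, 1), c(1, 4, 1), c(1, 1, 4))
#' sequentiality_index(r, bin_ms = 8, peak_window_ms = 8)$si  # log 3 + log 4
#' @export
sequentiality_index <- function(delay_rates, bin_ms = 8,
                                peak_window_ms = 50, rate_floor = 0.1) {
  m <- as.matrix(delay_rates)
  active <- rowSums(m) > 0
  m <- m[active, , drop = FALSE]
  if (nrow(m) < 2) stop("need at least 2 units with nonzero delay activity")
  n_bin <- ncol(m)
  half <- max(0L, as.integer(round((peak_window_ms / bin_ms - 1) / 2)))
  peak_bin <- apply(m, 1, which.max)
  p <- tabulate(peak_bin, n_bin) / nrow(m)
  entropy <- -sum(p[p > 0] * log(p[p > 0]))
  ridge <- vapply(seq_len(nrow(m)), function(i) {
    win <- max(1, peak_bin[i] - half):min(n_bin, peak_bin[i] + half)
    inside <- max(mean(m[i, win]), rate_floor)
    outside <- if (length(win) == n_bin) rate_floor else
      max(mean(m[i, -win]), rate_floor)
    log(inside / outside)
  }, 0)
  structure(list(si = entropy + mean(ridge), entropy = entropy,
                 ridge = mean(ridge), p_peak = p, peak_bin = peak_bin),
            class = "srnn_si")
}

#' @export
print.srnn_si <- function(x, ...) {
  cat(sprintf("Sequentiality index %.3f (entropy %.3f + mean log ridge %.3f)\n",
              x$si, x$entropy, x$ridge))
  invisible(x)
}

#' Row-normalized sequence heat map matrix
#'
#' Orders tuned units by their delay peak time and rescales each unit's
#' trial-averaged delay rate to `[0, 1]` (rows with zero range stay 0).
#'
#' @param delay_rates matrix `units x bins`.
#' @return list `heat` (reordered, normalized matrix) and `order`.
#' @export
sequence_heatmap <- function(delay_rates) {
  m <- as.matrix(delay_rates)
  ord <- order(apply(m, 1, which.max))
  m <- m[ord, , drop = FALSE]
  rng <- apply(m, 1, function(r) diff(range(r)))
  heat <- sweep(m, 1, apply(m, 1, min))
  heat <- sweep(heat, 1, ifelse(rng > 0, rng, 1), "/")
  list(heat = heat, order = ord)
}

#' Principal-component trajectories and kinetic energy
#'
#' Fits PCA to the binned delay-period rates of the excitatory population
#' (all trials concatenated, bins as observations), projects each rule's
#' trial-averaged response into the leading components, and computes the
#' kinetic energy `K(t) = 0.5 * ||dx/dt||^2` of the latent trajectory via
#' finite differences (per-bin time units).
#'
#' @param records an `srnn_records` list with trials of both rules.
#' @param params the [srnn_params()] used for simulation.
#' @param n_pcs number of components kept.
#' @param bin_ms bin width (ms).
#' @return object of class `srnn_trajectory`: `trajectory` and
#'   `kinetic_energy` per rule, the PC `rotation`, `center`, `sdev`,
#'   variance fractions and bin metadata.
#' @export
pca_trajectory <- function(records, params, n_pcs = 3, bin_ms = 8) {
  per_trial <- binned_delay_rates(records, params, bin_ms, units = "exc",
                                  average = FALSE)
  nu <- dim(per_trial)[1]
  if (nu < n_pcs) stop("fewer units than requested components")
  n_trial <- dim(per_trial)[3]
  if (n_trial < 2) stop("fewer trials than requested components")
  # observations: trial x bin rows, unit columns
  obs <- do.call(rbind, lapply(seq_len(n_trial), function(k)
    t(per_trial[, , k])))
  pc <- prcomp(obs, center = TRUE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pc$rotation))
  rules <- vapply(records, function(r) r$spec$rule, 0L)
  traj <- ke <- vector("list", 2)
  for (r in 1:2) {
    sel <- which(rules == r)
    if (!length(sel)) next
    avg <- apply(per_trial[, , sel, drop = FALSE], c(1, 2), mean)
    x <- scale(t(avg), center = pc$center, scale = FALSE) %*%
      pc$rotation[, seq_len(n_pcs), drop = FALSE]
    traj[[r]] <- x
    ke[[r]] <- c(NA, 0.5 * rowSums(diff(x)^2))
  }
  structure(list(trajectory = traj, kinetic_energy = ke,
                 rotation = pc$rotation[, seq_len(n_pcs), drop = FALSE],
                 center = pc$center, sdev = pc$sdev,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2),
                 bin_ms = bin_ms, n_pcs = n_pcs),
            class = "srnn_trajectory")
}

#' Spike-time cross-correlogram
#'
#' Counts target spikes at each lag relative to every trigger spike,
#' normalized per trigger spike. With `target` missing (or identical to
#' `trigger`) the auto-correlogram is computed and self-pairs (zero lag of a
#' spike with itself) are excluded.
#'
#' @param trigger,target spike time vectors (ms).
#' @param max_lag_ms maximum absolute lag (ms).
#' @param bin_ms lag bin width (ms).
#' @return object of class `srnn_correlogram`: `lag_ms` (bin centres),
#'   `count` (per-trigger normalized counts), `n_trigger`, `auto`.
#' @export
correlogram <- function(trigger, target = NULL, max_lag_ms = 50,
                        bin_ms = 2) {
  auto <- is.null(target)
  if (auto) target <- trigger
  if (!length(trigger) || !length(target))
    stop("spike trains must be non-empty")
  breaks <- seq(-max_lag_ms, max_lag_ms, by = bin_ms)
  d <- outer(target, trigger, "-")
  if (auto) d <- d[outer(seq_along(target), seq_along(trigger), "!=")]
  d <- d[d >= -max_lag_ms & d < max_lag_ms]
  counts <- tabulate(findInterval(d, breaks), length(breaks) - 1)
  structure(list(lag_ms = breaks[-length(breaks)] + bin_ms / 2,
                 count = counts / length(trigger),
                 n_trigger = length(trigger), auto = auto),
            class = "srnn_correlogram")
}

#' Detect delay-period beta-band rhythmicity
#'
#' Takes delay-period activity of one unit — preferably a matrix of
#' per-trial spike-count series (`trials x samples` at `dt_ms` resolution),
#' or a single pooled series — removes each trial's mean, and averages the
#' per-trial periodograms (Bartlett averaging; phase differences across
#' trials do not cancel the rhythm). The unit is flagged rhythmic if the
#' maximum averaged power inside the beta band is at least `ratio` times
#' the median power over all frequencies up to `f_max`. Trial averaging is
#' what calibrates the threshold: on a single raw periodogram the band
#' maximum exceeds twice the median for most unstructured series.
#'
#' @param series per-trial matrix (`trials x samples`) or numeric vector of
#'   delay-period activity at `dt_ms` spacing.
#' @param dt_ms sample spacing (ms).
#' @param band beta band limits (Hz).
#' @param ratio detection threshold on band peak / median power.
#' @param f_max upper frequency (Hz) of the spectrum considered.
#' @return object of class `srnn_beta`: `is_rhythmic`, `freq` (band peak
#'   frequency, Hz), `power_ratio`, and the spectrum (`freqs`, `power`).
#' @export
detect_beta <- function(series, dt_ms = 2, band = c(15, 30), ratio = 2,
                        f_max = 100) {
  if (!is.matrix(series)) series <- matrix(series, 1)
  n <- ncol(series)
  if (n * dt_ms < 400)
    stop("delay window must be at least 400 ms for beta detection")
  pw <- rep(0, n)
  for (k in seq_len(nrow(series))) {
    x <- series[k, ] - mean(series[k, ])
    pw <- pw + Mod(fft(x))^2 / n
  }
  pw <- pw / nrow(series)
  freqs <- (seq_len(n) - 1) / (n * dt_ms / 1000)
  keep <- freqs > 0 & freqs <= f_max
  freqs <- freqs[keep]; pw <- pw[keep]
  inband <- freqs >= band[1] & freqs <= band[2]
  med <- median(pw)
  if (med <= 0 || !any(inband))
    return(structure(list(is_rhythmic = FALSE, freq = NA_real_,
                          power_ratio = NA_real_, freqs = freqs,
                          power = pw), class = "srnn_beta"))
  pr <- max(pw[inband]) / med
  structure(list(is_rhythmic = pr >= ratio,
                 freq = freqs[inband][which.max(pw[inband])],
                 power_ratio = pr, freqs = freqs, power = pw),
            class = "srnn_beta")
}

#' Local-field-potential proxy
#'
#' Sums the synaptic currents of all units at each step (the standard LFP
#' surrogate for point-neuron networks) and computes a short-time Fourier
#' spectrogram of the summed trace for visualization.
#'
#' @param currents matrix `units x steps` of synaptic currents (from
#'   [run_trial()] with `record = TRUE`).
#' @param dt_ms integration step (ms).
#' @param window_ms,step_ms spectrogram window length and hop.
#' @return object of class `srnn_lfp`: `trace`, `time_ms`, and spectrogram
#'   `power` (`freq x windows`), `freqs`, `t_centers`.
#' @export
lfp_proxy <- function(currents, dt_ms = 2, window_ms = 128, step_ms = 16) {
  trace <- colSums(currents)
  nt <- length(trace)
  time_ms <- seq_len(nt) * dt_ms
  wlen <- as.integer(round(window_ms / dt_ms))
  hop <- max(1L, as.integer(round(step_ms / dt_ms)))
  if (nt >= wlen) {
    starts <- seq(1L, nt - wlen + 1L, by = hop)
    han <- 0.5 - 0.5 * cos(2 * pi * seq_len(wlen) / (wlen + 1))
    spec <- vapply(starts, function(s) {
      seg <- trace[s:(s + wlen - 1)]
      seg <- (seg - mean(seg)) * han
      (Mod(fft(seg))^2 / wlen)[seq_len(wlen %/% 2)]
    }, numeric(wlen %/% 2))
    freqs <- (seq_len(wlen %/% 2) - 1) / (wlen * dt_ms / 1000)
    t_centers <- (starts + wlen / 2) * dt_ms
  } else {
    spec <- NULL; freqs <- NULL; t_centers <- NULL
  }
  structure(list(trace = trace, time_ms = time_ms, power = spec,
                 freqs = freqs, t_centers = t_centers),
            class = "srnn_lfp")
}
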