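# Compact two-layer recurrent sequence classifier (tanh units, per-step
# sigmoid readout) trained by BPTT with Adam, inverted dropout and L2 weight
# decay. Sized for the population-decoding analysis: inputs are short
# sequences of principal-component scores, so a small hand-rolled network
# trains in seconds.

rnn_init <- function(n_in, hidden, seed) {
  set.seed(seed)
  g <- function(fi, fo) matrix(runif(fi * fo, -1, 1) * sqrt(6 / (fi + fo)),
                               fo, fi)
  list(W1 = g(n_in, hidden[1]), U1 = g(hidden[1], hidden[1]),
       b1 = numeric(hidden[1]),
       W2 = g(hidden[1], hidden[2]), U2 = g(hidden[2], hidden[2]),
       b2 = numeric(hidden[2]),
       w = numeric(hidden[2]), b = 0)
}

# X: (n_in x B x T), y in {0,1}^B. Returns per-step probabilities (B x T)
rnn_forward <- function(par, X, drop_masks = NULL) {
  d <- dim(X); B <- d[2]; Tn <- d[3]
  h1 <- array(0, c(nrow(par$W1), B, Tn))
  h2 <- array(0, c(nrow(par$W2), B, Tn))
  p <- matrix(0, B, Tn)
  h1p <- matrix(0, nrow(par$W1), B)
  h2p <- matrix(0, nrow(par$W2), B)
  for (t in seq_len(Tn)) {
    a1 <- par$W1 %*% X[, , t, drop = TRUE] + par$U1 %*% h1p + par$b1
    h1t <- tanh(a1)
    h1d <- if (is.null(drop_masks)) h1t else h1t * drop_masks$m1[, , t]
    a2 <- par$W2 %*% h1d + par$U2 %*% h2p + par$b2
    h2t <- tanh(a2)
    h2d <- if (is.null(drop_masks)) h2t else h2t * drop_masks$m2[, , t]
    p[, t] <- 1 / (1 + exp(-(drop(crossprod(h2d, par$w)) + par$b)))
    h1[, , t] <- h1t; h2[, , t] <- h2t
    h1p <- h1t; h2p <- h2t
  }
  list(p = p, h1 = h1, h2 = h2)
}

# gradients of final-step binary cross-entropy + L2; loss at last step only
rnn_backward <- function(par, X, y, fw, drop_masks, l2) {
  d <- dim(X); B <- d[2]; Tn <- d[3]
  g <- lapply(par, function(w) w * 0)
  m1 <- drop_masks$m1; m2 <- drop_masks$m2
  h2d_T <- fw$h2[, , Tn, drop = TRUE] * m2[, , Tn]
  dz <- (fw$p[, Tn] - y) / B                       # B
  g$w <- drop(h2d_T %*% dz)
  g$b <- sum(dz)
  dh2 <- (par$w %o% dz) * m2[, , Tn]               # into h2(T)
  dh1 <- matrix(0, nrow(par$W1), B)
  for (t in rev(seq_len(Tn))) {
    h2t <- fw$h2[, , t, drop = TRUE]
    da2 <- (1 - h2t^2) * dh2
    h1d <- fw$h1[, , t, drop = TRUE] * m1[, , t]
    g$W2 <- g$W2 + da2 %*% t(h1d)
    if (t > 1) g$U2 <- g$U2 + da2 %*% t(fw$h2[, , t - 1, drop = TRUE])
    g$b2 <- g$b2 + rowSums(da2)
    dh1 <- dh1 + (crossprod(par$W2, da2)) * m1[, , t]
    h1t <- fw$h1[, , t, drop = TRUE]
    da1 <- (1 - h1t^2) * dh1
    g$W1 <- g$W1 + da1 %*% t(X[, , t, drop = TRUE])
    if (t > 1) g$U1 <- g$U1 + da1 %*% t(fw$h1[, , t - 1, drop = TRUE])
    g$b1 <- g$b1 + rowSums(da1)
    dh2 <- if (t > 1) crossprod(par$U2, da2) else dh2 * 0
    dh1 <- if (t > 1) crossprod(par$U1, da1) else dh1 * 0
  }
  for (nm in c("W1", "U1", "W2", "U2", "w"))
    g[[nm]] <- g[[nm]] + 2 * l2 * par[[nm]]
  g
}

rnn_train <- function(X, y, hidden = c(16, 16), epochs = 120,
                      dropout = 0.2, l2 = 1e-3, eta = 5e-3, seed = 1L) {
  par <- rnn_init(dim(X)[1], hidden, seed)
  ad <- lapply(par, function(w) list(m = w * 0, v = w * 0))
  tstep <- 0
  d <- dim(X); B <- d[2]; Tn <- d[3]
  set.seed(seed + 1L)
  keep <- 1 - dropout
  for (ep in seq_len(epochs)) {
    dm <- list(
      m1 = array(rbinom(hidden[1] * B * Tn, 1, keep) / keep,
                 c(hidden[1], B, Tn)),
      m2 = array(rbinom(hidden[2] * B * Tn, 1, keep) / keep,
                 c(hidden[2], B, Tn)))
    fw <- rnn_forward(par, X, dm)
    g <- rnn_backward(par, X, y, fw, dm, l2)
    tstep <- tstep + 1
    for (nm in names(par)) {
      ad[[nm]]$m <- 0.9 * ad[[nm]]$m + 0.1 * g[[nm]]
      ad[[nm]]$v <- 0.999 * ad[[nm]]$v + 0.001 * g[[nm]]^2
      mh <- ad[[nm]]$m / (1 - 0.9^tstep)
      vh <- ad[[nm]]$v / (1 - 0.999^tstep)
      par[[nm]] <- par[[nm]] - eta * mh / (sqrt(vh) + 1e-8)
    }
  }
  par
}

#' Decode the task rule from population activity
#'
#' Reads out the rule from excitatory delay-period activity: spike counts in
#' non-overlapping bins are projected onto the leading principal components,
#' and a two-layer recurrent sequence classifier (tanh units, dropout 0.2,
#' L2 1e-3, trained by backpropagation through time) predicts the rule from
#' the component scores. Accuracy is estimated by repeated 90/10
#' cross-validation and reported cumulatively over delay time (the
#' classifier's per-step readout evaluated on each sequence prefix).
#'
#' @param records an `srnn_records` list with trials of both rules (at least
#'   20 per rule).
#' @param params the [srnn_params()] used for simulation.
#' @param bin_ms spike-count bin (ms), typically 20 or 50.
#' @param n_pcs number of principal components used as features.
#' @param folds number of 90/10 cross-validation splits.
#' @param hidden sizes of the two recurrent layers.
#' @param epochs training epochs per fold.
#' @param threshold classification threshold on the readout probability.
#' @param seed integer seed (fold splits, dropout, initialization).
#' @return object of class `srnn_decoding`: `accuracy_by_time` (mean CV
#'   accuracy per delay bin), `accuracy` (final bin), `time_ms`, `folds`.
#' @export
decode_population <- function(records, params, bin_ms = 20, n_pcs = 15,
                              folds = 10, hidden = c(16, 16), epochs = 120,
                              threshold = 0.5, seed = 1L) {
  rules <- vapply(records, function(r) r$spec$rule, 0L)
  if (min(table(rules)) < 20)
    stop("need at least 20 trials per rule")
  per_trial <- binned_delay_rates(records, params, bin_ms, units = "exc",
                                  average = FALSE)
  nu <- dim(per_trial)[1]; n_bin <- dim(per_trial)[2]
  n_trial <- dim(per_trial)[3]
  obs <- do.call(rbind, lapply(seq_len(n_trial), function(k)
    t(per_trial[, , k])))
  pc <- prcomp(obs, center = TRUE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pc$rotation))
  # feature cube: n_pcs x trials x bins, rescaled for optimization
  feat <- array(0, c(n_pcs, n_trial, n_bin))
  for (k in seq_len(n_trial)) {
    x <- scale(t(per_trial[, , k]), center = pc$center, scale = FALSE) %*%
      pc$rotation[, seq_len(n_pcs), drop = FALSE]
    feat[, k, ] <- t(x)
  }
  sc <- max(abs(feat)); if (sc > 0) feat <- feat / sc
  y <- as.numeric(rules == 1)

  set.seed(derive_seed(seed, "decode"))
  acc <- matrix(NA_real_, folds, n_bin)
  n_test <- max(1L, round(0.1 * n_trial))
  for (f in seq_len(folds)) {
    test <- sample.int(n_trial, n_test)
    train <- setdiff(seq_len(n_trial), test)
    par <- rnn_train(feat[, train, , drop = FALSE], y[train],
                     hidden = hidden, epochs = epochs,
                     seed = derive_seed(seed, "decode", index = f))
    fw <- rnn_forward(par, feat[, test, , drop = FALSE])
    pred <- fw$p > threshold
    acc[f, ] <- colMeans(pred == matrix(y[test], n_test, n_bin))
  }
  structure(list(accuracy_by_time = colMeans(acc),
                 accuracy = mean(acc[, n_bin]),
                 time_ms = seq_len(n_bin) * bin_ms, per_fold = acc,
                 bin_ms = bin_ms, n_pcs = n_pcs, folds = folds),
            class = "srnn_decoding")
}

#' @export
print.srnn_decoding <- function(x, ...) {
  cat(sprintf(
    "Population decoding (%d-ms bins, %d PCs, %d folds): %.1f%% at end of delay\n",
    x$bin_ms, x$n_pcs, x$folds, 100 * x$accuracy))
  invisible(x)
}
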