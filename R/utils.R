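# Seed fan-out: one user-facing seed deterministically derives independent
# sub-stream seeds for initialization, batches, noise, masks etc. All derived
# seeds stay below 2^31.
derive_seed <- function(seed, stream, index = 0L) {
  ids <- c(init = 11L, state = 23L, batch = 37L, val = 53L, eval = 71L,
           trial = 89L, analysis = 101L, perturb = 127L, decode = 151L,
           noise = 173L)
  id <- ids[[stream]]
  if (is.null(id)) stop("unknown seed stream: ", stream)
  as.integer((as.double(seed) * 69069 + id * 104729 + index * 7919) %%
               2147483629) + 1L
}

# Wilson binomial confidence interval
binom_ci <- function(k, n, level = 0.95) {
  if (n == 0) return(c(lo = NA_real_, hi = NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lo = max(0, ctr - hw), hi = min(1, ctr + hw))
}

# FNV-1a 32-bit hash of a character string (manifest fingerprints),
# carried in doubles; the xor only ever touches the low byte.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  mulmod32 <- function(a, b) {
    lo <- a %% 65536
    hi <- (a - lo) / 65536
    (((hi * b) %% 65536) * 65536 + lo * b) %% 4294967296
  }
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- mulmod32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
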