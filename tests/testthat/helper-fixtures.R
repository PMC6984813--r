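# In-code fixtures shared across test files. Everything is generated at test
# time; no binary data ships with the package.

FS_HZ <- 10000

# alpha-function PSC (negative-going), onset at `onset_s`
alpha_event <- function(n, onset_s, tau_ms = 2, amp = -50, fs = FS_HZ) {
  t <- ((seq_len(n) - 1) / fs - onset_s) * 1000   # ms relative to onset
  x <- numeric(n)
  pos <- t >= 0
  x[pos] <- amp * (t[pos] / tau_ms) * exp(1 - t[pos] / tau_ms)
  x
}

# evoked voltage-clamp sweep with a planted alpha event, optional noise
evoked_sweep <- function(amp = -50, latency_ms = 7, noise_sd = 0, stim = 0.6,
                         dur = 1, tau_ms = 2, fs = FS_HZ, seed = NULL) {
  n <- dur * fs
  x <- if (noise_sd > 0) with_seed(seed, rnorm(n, 0, noise_sd)) else numeric(n)
  x <- x + alpha_event(n, stim + 0.002 + latency_ms / 1000, tau_ms, amp, fs)
  sweep_trace(x, fs, "current", stimulus_times = stim,
              artifact_windows = list(c(stim, stim + 0.002)), holding = -70)
}

with_seed <- phystype:::with_seed

# exhaustive greedy ESS-increase agglomeration: the Ward oracle
brute_ward_heights <- function(x) {
  ess <- function(idx) {
    m <- colMeans(x[idx, , drop = FALSE])
    sum(sweep(x[idx, , drop = FALSE], 2, m)^2)
  }
  clusters <- as.list(seq_len(nrow(x)))
  hts <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- NULL
    for (i in 1:(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      d <- ess(c(clusters[[i]], clusters[[j]])) - ess(clusters[[i]]) - ess(clusters[[j]])
      if (d < best) { best <- d; bi <- c(i, j) }
    }
    hts <- c(hts, best)
    clusters[[bi[1]]] <- c(clusters[[bi[1]]], clusters[[bi[2]]])
    clusters[[bi[2]]] <- NULL
  }
  hts
}

# labels of the 2-cluster stage of the brute-force agglomeration
brute_ward_k2 <- function(x) {
  ess <- function(idx) {
    m <- colMeans(x[idx, , drop = FALSE])
    sum(sweep(x[idx, , drop = FALSE], 2, m)^2)
  }
  clusters <- as.list(seq_len(nrow(x)))
  while (length(clusters) > 2) {
    best <- Inf; bi <- NULL
    for (i in 1:(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      d <- ess(c(clusters[[i]], clusters[[j]])) - ess(clusters[[i]]) - ess(clusters[[j]])
      if (d < best) { best <- d; bi <- c(i, j) }
    }
    clusters[[bi[1]]] <- c(clusters[[bi[1]]], clusters[[bi[2]]])
    clusters[[bi[2]]] <- NULL
  }
  lab <- integer(nrow(x))
  for (k in seq_along(clusters)) lab[clusters[[k]]] <- k
  lab
}
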