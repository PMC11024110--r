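# Independent brute-force oracles. These deliberately share no code with the
# package: plain double loops and direct transcriptions of the defining
# formulas, for cross-checking the vectorised implementations.

# per-sample spatial standard deviation, naive loop
naive_gfp <- function(x) {
  out <- numeric(ncol(x))
  for (t in seq_len(ncol(x))) {
    m <- 0
    for (i in seq_len(nrow(x))) m <- m + x[i, t]
    m <- m / nrow(x)
    s <- 0
    for (i in seq_len(nrow(x))) s <- s + (x[i, t] - m)^2
    out[t] <- sqrt(s / nrow(x))
  }
  out
}

# exhaustive strict local maxima (no spacing constraint)
naive_peaks <- function(v) {
  out <- integer()
  for (t in 2:(length(v) - 1)) {
    if (v[t] > v[t - 1] && v[t] > v[t + 1]) out <- c(out, t)
  }
  out
}

# recurrence matrix by double loop over embedded points, Chebyshev norm
naive_rp <- function(series, m, tau, eps) {
  n <- length(series) - (m - 1) * tau
  R <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- 0
      for (k in 0:(m - 1)) {
        d <- max(d, abs(series[i + k * tau] - series[j + k * tau]))
      }
      R[i, j] <- as.integer(eps - d >= 0)   # Heaviside(0) = 1
    }
  }
  R
}

# walk every diagonal above/below the LOI, counting maximal runs of ones
naive_diag_hist <- function(R, theiler) {
  n <- nrow(R)
  lens <- integer()
  for (d in seq(-(n - 1), n - 1)) {
    if (d == 0 || abs(d) <= theiler) next
    run <- 0L
    for (i in seq_len(n)) {
      j <- i + d
      v <- if (j >= 1 && j <= n) R[i, j] else 0L
      if (v == 1L) run <- run + 1L
      if ((v == 0L || i == n) && run > 0L) { lens <- c(lens, run); run <- 0L }
    }
  }
  lens
}

naive_vert_hist <- function(R) {
  lens <- integer()
  for (j in seq_len(ncol(R))) {
    run <- 0L
    for (i in seq_len(nrow(R))) {
      if (R[i, j] == 1L) run <- run + 1L
      if ((R[i, j] == 0L || i == nrow(R)) && run > 0L) {
        lens <- c(lens, run); run <- 0L
      }
    }
  }
  lens
}

naive_rec_times <- function(R) {
  gaps <- integer()
  for (j in seq_len(ncol(R))) {
    starts <- integer()
    prev <- 0L
    for (i in seq_len(nrow(R))) {
      if (R[i, j] == 1L && prev == 0L) starts <- c(starts, i)
      prev <- R[i, j]
    }
    if (length(starts) >= 2) gaps <- c(gaps, diff(starts))
  }
  gaps
}

# the eight features, straight from their defining ratios
naive_rqa <- function(series, m, tau, eps, theiler, l_min, v_min) {
  R <- naive_rp(series, m, tau, eps)
  n <- nrow(R)
  rr <- sum(R) / n^2
  dl <- naive_diag_hist(R, theiler)
  det <- if (sum(dl) > 0 && any(dl >= l_min)) {
    sum(dl[dl >= l_min]) / sum(dl)
  } else 0
  l_max <- if (length(dl)) max(dl) else 0
  sel <- dl[dl >= l_min]
  l_mean <- if (length(sel)) mean(sel) else 0
  entr <- if (length(sel)) {
    p <- table(sel) / length(sel)
    -sum(p * log(p))
  } else 0
  vl <- naive_vert_hist(R)
  selv <- vl[vl >= v_min]
  tt <- if (length(selv)) mean(selv) else 0
  v_max <- if (length(vl)) max(vl) else 0
  gaps <- naive_rec_times(R)
  rpde <- if (length(gaps) && max(gaps) > 1) {
    p <- table(gaps) / length(gaps)
    -sum(p * log(p)) / log(max(gaps))
  } else 0
  c(rr = rr, det = det, l_mean = l_mean, l_max = l_max, entr = entr,
    tt = tt, v_max = v_max, rpde = rpde)
}

# direct two-line GEV summation
naive_gev <- function(x, maps, labels) {
  num <- 0; den <- 0
  for (t in seq_len(ncol(x))) {
    v <- x[, t]
    g2 <- sum((v - mean(v))^2) / length(v)
    cc <- stats::cor(v, maps[labels[t], ])
    num <- num + g2 * cc^2
    den <- den + g2
  }
  num / den
}

# small synthetic recording shared by several test files
small_sim <- function(seed = 11, snr = 10, n_trials = 4, trial_s = 5,
                      n_channels = 16, K = 4) {
  simulate_eeg(synthetic_spec(n_channels = n_channels, K = K, snr = snr,
                              n_trials_per_class = n_trials,
                              trial_length_s = trial_s, seed = seed))
}

# label agreement allowing state permutation (greedy matching is enough at
# the accuracies asserted)
permuted_agreement <- function(truth, est) {
  tab <- table(truth, est)
  sum(apply(tab, 1, max)) / length(truth)
}
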