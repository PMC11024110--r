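#' Orthonormal synthetic microstate templates
#'
#' K orthonormal scalp topographies obtained from the QR decomposition of a
#' seeded Gaussian matrix. Used as planted prototypes by [simulate_eeg()].
#'
#' @param K number of templates (`K <= n_channels`).
#' @param n_channels electrode count.
#' @param seed RNG seed.
#' @return A `K x n_channels` matrix with orthonormal rows.
#' @export
make_templates <- function(K, n_channels, seed = 1) {
  assert_that(K >= 1 && K <= n_channels, "need 1 <= K <= n_channels")
  withr::with_seed(seed, {
    M <- matrix(stats::rnorm(n_channels * n_channels), n_channels)
    Q <- qr.Q(qr(M))
    t(Q[, seq_len(K), drop = FALSE])
  })
}

#' Specification of a synthetic attention experiment
#'
#' Defaults encode the study conditions the pipeline targets: 64-channel EEG at
#' 256 Hz, four quasi-stable topographies whose dwell times sit in the
#' 80-120 ms microstate band, and an attention effect carried purely by state
#' *dynamics* — mean dwell 100 ms when attending speaker 1 versus 60 ms for
#' speaker 2 — with 20 trials of 50 s per class at a linear SNR of 10.
#'
#' @param n_channels electrode count.
#' @param K planted state count.
#' @param templates optional `K x n_channels` unit-norm template matrix;
#'   auto-generated orthonormal maps when `NULL`.
#' @param mean_duration_ms named list/vector of per-class mean state dwell
#'   times (ms) for `SPK1` and `SPK2`.
#' @param duration_jitter fractional uniform jitter on each dwell time.
#' @param snr linear amplitude ratio of signal to sensor noise.
#' @param sfreq sampling rate (Hz).
#' @param n_trials_per_class trials per attended-speaker class.
#' @param trial_length_s trial duration (s).
#' @param seed RNG seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_channels = 64, K = 4, templates = NULL,
                           mean_duration_ms = c(SPK1 = 100, SPK2 = 60),
                           duration_jitter = 0.3, snr = 10, sfreq = 256,
                           n_trials_per_class = 20, trial_length_s = 50,
                           seed = 1) {
  assert_that(snr > 0, "`snr` must be positive")
  assert_that(all(mean_duration_ms >= 2000 / sfreq),
              "mean dwell must span at least 2 samples")
  assert_that(all(c("SPK1", "SPK2") %in% names(mean_duration_ms)),
              "mean_duration_ms needs SPK1 and SPK2 entries")
  if (is.null(templates)) {
    templates <- make_templates(K, n_channels, seed = derive_seed(seed, "templates"))
  }
  assert_that(nrow(templates) == K && ncol(templates) == n_channels,
              "templates must be K x n_channels")
  nrm <- sqrt(rowSums(templates^2))
  templates <- templates / nrm
  structure(list(n_channels = n_channels, K = K, templates = templates,
                 mean_duration_ms = mean_duration_ms,
                 duration_jitter = duration_jitter, snr = snr, sfreq = sfreq,
                 n_trials_per_class = n_trials_per_class,
                 trial_length_s = trial_length_s, seed = seed),
            class = "synthetic_spec")
}

# one trial's semi-Markov state sequence
sample_state_sequence <- function(n_samples, K, mean_dur_samp, jitter) {
  labels <- integer(n_samples)
  run_id <- integer(n_samples)
  pos <- 1L; state <- sample.int(K, 1); rid <- 0L
  while (pos <= n_samples) {
    dur <- max(2L, as.integer(round(mean_dur_samp * stats::runif(1, 1 - jitter, 1 + jitter))))
    end <- min(n_samples, pos + dur - 1L)
    rid <- rid + 1L
    labels[pos:end] <- state
    run_id[pos:end] <- rid
    pos <- end + 1L
    if (K > 1) {
      nxt <- sample.int(K - 1, 1)
      state <- if (nxt >= state) nxt + 1L else nxt
    }
  }
  list(labels = labels, run_id = run_id)
}

#' Simulate EEG with planted microstate dynamics
#'
#' Each trial is a semi-Markov sequence over the K planted topographies; the
#' attended-speaker class only changes the mean dwell time, so the class
#' signal lives in the state dynamics, not in the maps. Within a run the
#' active template is amplitude-modulated by a half-sine envelope (GFP peaks
#' mid-state), then Gaussian sensor noise is added at the requested SNR
#' (linear RMS ratio). Trials alternate SPK1/SPK2 in one continuous recording.
#'
#' @param spec a [synthetic_spec()].
#' @return A list: `recording` (an [eeg_recording()]), `state_labels`
#'   (per-sample planted state, whole recording), and `truth` (tibble of
#'   per-trial class and per-sample run bookkeeping nested per trial).
#' @export
simulate_eeg <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_tr <- spec$n_trials_per_class * 2L
  n_win <- as.integer(round(spec$trial_length_s * spec$sfreq))
  classes <- rep(c("SPK1", "SPK2"), spec$n_trials_per_class)
  withr::with_seed(derive_seed(spec$seed, "simulate"), {
    data <- matrix(0, spec$n_channels, n_tr * n_win)
    state_labels <- integer(n_tr * n_win)
    trial_rows <- vector("list", n_tr)
    for (t in seq_len(n_tr)) {
      cls <- classes[t]
      md <- spec$mean_duration_ms[[cls]] * spec$sfreq / 1000
      sq <- sample_state_sequence(n_win, spec$K, md, spec$duration_jitter)
      env <- numeric(n_win)
      for (r in unique(sq$run_id)) {
        idx <- which(sq$run_id == r)
        env[idx] <- sin(pi * (seq_along(idx) - 0.5) / length(idx))
      }
      sig <- t(spec$templates[sq$labels, , drop = FALSE]) *
        rep(env, each = spec$n_channels)
      sig_rms <- sqrt(mean(sig^2))
      noise <- matrix(stats::rnorm(length(sig), sd = sig_rms / spec$snr),
                      nrow(sig))
      off <- (t - 1L) * n_win
      data[, off + seq_len(n_win)] <- sig + noise
      state_labels[off + seq_len(n_win)] <- sq$labels
      trial_rows[[t]] <- tibble(trial = t, class = cls,
                                start = off + 1L, end = off + n_win + 1L)
    }
  })
  truth <- bind_rows(trial_rows)
  ch <- paste0("E", formatC(seq_len(spec$n_channels), width = 2, flag = "0"))
  if (spec$n_channels >= 2) ch[c(1, 2)] <- c("TP7", "TP8")
  rec <- eeg_recording(data, spec$sfreq, ch,
                       tibble(start = truth$start, end = truth$end,
                              label = truth$class))
  list(recording = rec, state_labels = state_labels, truth = truth,
       templates = spec$templates)
}

#' Toy scalar series for recurrence analysis fixtures
#'
#' @param kind `"constant"`, `"periodic"` (sine, or square when
#'   `params$square`), `"noise"` (Gaussian) or `"logistic"` map.
#' @param n series length (`>= 4`).
#' @param params list; `value` (constant), `period`/`square` (periodic),
#'   `sd` (noise), `r`/`x0` (logistic).
#' @param seed RNG seed (noise only).
#' @return Numeric vector of length `n`.
#' @export
make_toy_series <- function(kind = c("constant", "periodic", "noise", "logistic"),
                            n, params = list(), seed = 1) {
  kind <- match.arg(kind)
  assert_that(n >= 4, "`n` must be at least 4")
  switch(kind,
    constant = rep(params$value %||% 1, n),
    periodic = {
      period <- params$period %||% 2
      assert_that(period >= 2, "period must be >= 2")
      if (isTRUE(params$square) || period == 2) {
        # exact square wave: a sampled sine at period 2 is all floating-point
        # noise around zero
        ifelse(((seq_len(n) - 1) %% period) < period / 2, 1, -1)
      } else {
        sin(2 * pi * (seq_len(n) - 1) / period)
      }
    },
    noise = withr::with_seed(seed, stats::rnorm(n, sd = params$sd %||% 1)),
    logistic = {
      r <- params$r %||% 4
      assert_that(r > 0 && r <= 4, "logistic r must be in (0, 4]")
      x <- numeric(n); x[1] <- params$x0 %||% 0.3
      for (i in seq_len(n - 1)) x[i + 1] <- r * x[i] * (1 - x[i])
      x
    })
}

#' Separable two-class Gaussian feature benchmark
#'
#' Two isotropic Gaussian classes (sd 1) whose means are offset by
#' `+separation_sd` and `-separation_sd` noise standard deviations from the
#' origin along a seeded random direction, labelled SPK1/SPK2 and grouped into
#' synthetic "trials" of 10 consecutive rows so trial-granular splitting is
#' exercised. At the default separation of 4 the classes barely overlap
#' (Bayes accuracy ~1), so any competent classifier should approach perfect
#' held-out accuracy; `separation_sd = 0` gives chance-level data.
#'
#' @param n_per_class rows per class (`>= 10`).
#' @param dim feature dimensionality.
#' @param separation_sd class mean separation in units of the noise sd.
#' @param seed RNG seed.
#' @return A feature tibble (`window_id`, `trial_id`, `label`, `f1..fdim`)
#'   as produced by [build_features()].
#' @export
make_separable_features <- function(n_per_class = 100, dim = 8,
                                    separation_sd = 4, seed = 1) {
  assert_that(n_per_class >= 10 && n_per_class %% 10 == 0,
              "`n_per_class` must be a positive multiple of 10")
  withr::with_seed(seed, {
    dir <- stats::rnorm(dim); dir <- dir / sqrt(sum(dir^2))
    X1 <- matrix(stats::rnorm(n_per_class * dim), n_per_class) +
      matrix(dir * separation_sd, n_per_class, dim, byrow = TRUE)
    X2 <- matrix(stats::rnorm(n_per_class * dim), n_per_class) -
      matrix(dir * separation_sd, n_per_class, dim, byrow = TRUE)
  })
  # classes kept in blocks so every 10-row "trial" is class-pure
  X <- rbind(X1, X2)
  lab <- rep(c("SPK1", "SPK2"), each = n_per_class)
  colnames(X) <- paste0("f", seq_len(dim))
  out <- as_tibble(X)
  out <- mutate(out,
                window_id = dplyr::row_number(),
                trial_id = (dplyr::row_number() - 1L) %/% 10L + 1L,
                label = lab, .before = 1)
  attr(out, "window_length_s") <- NA_real_
  out
}
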