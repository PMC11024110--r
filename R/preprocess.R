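#' Resample a recording
#'
#' Rational-factor polyphase resampling with anti-alias filtering on the way
#' down (via [signal::resample()]). Trial boundaries are rescaled to the new
#' rate. The standard analysis rate for this pipeline is 256 Hz.
#'
#' @param rec an [eeg_recording()].
#' @param target_sfreq new sampling rate (Hz).
#' @return The resampled [eeg_recording()].
#' @export
resample_recording <- function(rec, target_sfreq) {
  stopifnot(inherits(rec, "eeg_recording"))
  assert_that(is_scalar_num(target_sfreq) && target_sfreq > 0,
              "`target_sfreq` must be positive")
  if (isTRUE(all.equal(target_sfreq, rec$sfreq))) return(rec)
  fr <- MASS_fractions(target_sfreq / rec$sfreq)
  p <- fr[1]; q <- fr[2]
  n_new <- ceiling(ncol(rec$data) * p / q)
  out <- matrix(0, nrow(rec$data), n_new)
  for (i in seq_len(nrow(rec$data))) {
    y <- signal::resample(rec$data[i, ], p, q)
    out[i, ] <- y[seq_len(n_new)]
  }
  ratio <- target_sfreq / rec$sfreq
  trials <- rec$trials
  trials$start <- pmax(1L, as.integer(round((trials$start - 1L) * ratio)) + 1L)
  trials$end <- pmin(n_new + 1L, as.integer(round((trials$end - 1L) * ratio)) + 1L)
  eeg_recording(out, target_sfreq, rec$channel_names, trials)
}

# small rational approximation for the resampling factor
MASS_fractions <- function(x, max_den = 1024L) {
  best <- c(1L, 1L); best_err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(x * q)
    if (p < 1) next
    err <- abs(x - p / q)
    if (err < best_err - 1e-15) { best <- c(as.integer(p), q); best_err <- err }
    if (best_err < 1e-12) break
  }
  best
}

#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) FIR band-pass applied forward and backward
#' ([signal::filtfilt()]) so the net phase is zero. The default 0.5-70 Hz band
#' keeps the rhythms microstate analysis relies on and removes DC and drift.
#' The order is chosen from the low transition bandwidth (about 3.3 cycles of
#' the low edge) unless given; the order actually used is stored in
#' `attr(, "fir_order")`.
#'
#' @param rec an [eeg_recording()].
#' @param lo,hi band edges in Hz; requires `0 < lo < hi < sfreq/2`.
#' @param order even FIR order, or `NULL` to derive from `lo`.
#' @return The filtered [eeg_recording()].
#' @export
bandpass_filter <- function(rec, lo = 0.5, hi = 70, order = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sfreq / 2
  assert_that(is_scalar_num(lo) && is_scalar_num(hi) && lo > 0 && hi > lo,
              "need 0 < lo < hi")
  assert_that(hi < nyq, sprintf("hi (%g Hz) must be below Nyquist (%g Hz)", hi, nyq))
  if (is.null(order)) {
    order <- ceiling(3.3 * rec$sfreq / lo)
    order <- min(order, ncol(rec$data) %/% 3 * 2)   # filtfilt needs 3x headroom
  }
  if (order %% 2 == 1) order <- order + 1
  assert_that(order >= 4, "recording too short for a band-pass filter")
  b <- signal::Ma(signal::fir1(order, c(lo, hi) / nyq, type = "pass"))
  out <- rec$data
  for (i in seq_len(nrow(out))) {
    x <- out[i, ] - mean(out[i, ])
    out[i, ] <- signal::filtfilt(b, x)
  }
  res <- eeg_recording(out, rec$sfreq, rec$channel_names, rec$trials)
  attr(res, "fir_order") <- order
  res
}

#' Re-reference to the average of reference electrodes
#'
#' Subtracts, at every sample, the mean of the named reference channels from
#' every channel. The pipeline default is the average of TP7 and TP8 (linked
#' mastoid-adjacent reference). Missing reference channels raise an error;
#' there is no silent fallback.
#'
#' @param rec an [eeg_recording()].
#' @param ref_channels channel names to average as the reference.
#' @return The re-referenced [eeg_recording()].
#' @export
rereference <- function(rec, ref_channels = c("TP7", "TP8")) {
  stopifnot(inherits(rec, "eeg_recording"))
  idx <- match(ref_channels, rec$channel_names)
  if (anyNA(idx)) {
    abort(sprintf("reference channel(s) not found: %s",
                  paste(ref_channels[is.na(idx)], collapse = ", ")),
          class = "msrqa_channel_error")
  }
  ref <- colMeans(rec$data[idx, , drop = FALSE])
  out <- sweep(rec$data, 2, ref, "-")
  eeg_recording(out, rec$sfreq, rec$channel_names, rec$trials)
}

#' Cut a recording into fixed-length analysis windows
#'
#' Windows tile each trial independently and never span a trial boundary;
#' trailing partial windows are dropped. Each window inherits its trial's
#' attended-speaker label. The headline analysis uses non-overlapping 1 s
#' windows (256 samples at 256 Hz).
#'
#' @param rec an [eeg_recording()].
#' @param length_s window length in seconds (`length_s * sfreq >= 2`).
#' @param overlap fraction of the window shared with its successor, in `[0, 1)`.
#' @return A tibble with one row per window: `window_id`, `trial_id`,
#'   `start_s`, `length_s`, `label`, and `data` (list column of
#'   channels x samples matrices).
#' @export
segment_windows <- function(rec, length_s, overlap = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  win <- as.integer(round(length_s * rec$sfreq))
  assert_that(win >= 2, "window must span at least 2 samples")
  assert_that(is_scalar_num(overlap) && overlap >= 0 && overlap < 1,
              "`overlap` must be in [0, 1)")
  step <- max(1L, as.integer(round(win * (1 - overlap))))
  rows <- list()
  for (ti in seq_len(nrow(rec$trials))) {
    tr <- rec$trials[ti, ]
    tr_len <- tr$end - tr$start
    if (tr_len < win) {
      warn(sprintf("trial %d (%.2f s) shorter than window (%.2f s); skipped",
                   ti, tr_len / rec$sfreq, length_s))
      next
    }
    starts <- seq.int(tr$start, tr$end - win, by = step)
    for (s in starts) {
      rows[[length(rows) + 1L]] <- tibble(
        trial_id = ti,
        start_s = (s - 1L) / rec$sfreq,
        length_s = win / rec$sfreq,
        label = tr$label,
        data = list(rec$data[, seq.int(s, s + win - 1L), drop = FALSE])
      )
    }
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(trial_id = integer(), start_s = double(), length_s = double(),
           label = character(), data = list())
  out <- mutate(out, window_id = dplyr::row_number(), .before = 1)
  attr(out, "sfreq") <- rec$sfreq
  out
}

#' Run the standard preprocessing chain
#'
#' Resample to `sfreq`, zero-phase FIR band-pass `band[1]`-`band[2]` Hz,
#' re-reference to the average of `ref` (skipped when the montage lacks them
#' and `ref_required = FALSE`).
#'
#' @param rec an [eeg_recording()].
#' @param sfreq target rate, Hz.
#' @param band band-pass edges, Hz.
#' @param ref reference channels; `NULL` to skip re-referencing.
#' @param ref_required error (rather than skip) when `ref` channels are absent.
#' @return The preprocessed [eeg_recording()].
#' @export
preprocess <- function(rec, sfreq = 256, band = c(0.5, 70),
                       ref = c("TP7", "TP8"), ref_required = FALSE) {
  rec <- resample_recording(rec, sfreq)
  rec <- bandpass_filter(rec, band[1], band[2])
  if (!is.null(ref)) {
    if (all(ref %in% rec$channel_names)) {
      rec <- rereference(rec, ref)
    } else if (ref_required) {
      rec <- rereference(rec, ref)    # raises the channel error
    }
  }
  rec
}
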