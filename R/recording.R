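#' Multichannel EEG recording
#'
#' Container for a channels-by-samples EEG signal with sampling rate, channel
#' names and trial annotations. Trials are half-open sample intervals
#' `[start, end)` in 1-based sample indices, each carrying the attended-speaker
#' label (`"SPK1"`, `"SPK2"` or `"NONE"`).
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param sfreq sampling rate in Hz.
#' @param channel_names character vector, one name per channel (10-20 labels
#'   where applicable).
#' @param trials tibble with columns `start`, `end` (1-based, half-open on
#'   `end`) and `label`; defaults to a single all-`NONE` trial spanning the
#'   recording.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sfreq, channel_names = NULL, trials = NULL) {
  assert_that(is.matrix(data) && is.numeric(data), "`data` must be a numeric matrix")
  assert_that(is_scalar_num(sfreq) && sfreq > 0, "`sfreq` must be a positive number")
  n_ch <- nrow(data)
  n_samp <- ncol(data)
  if (is.null(channel_names)) channel_names <- paste0("CH", seq_len(n_ch))
  assert_that(length(channel_names) == n_ch,
              "length(channel_names) must equal nrow(data)")
  if (is.null(trials)) {
    trials <- tibble(start = 1L, end = n_samp + 1L, label = "NONE")
  }
  trials <- as_tibble(trials)
  assert_that(all(c("start", "end", "label") %in% names(trials)),
              "trials needs columns start, end, label")
  trials$label <- as.character(trials$label)
  assert_that(all(trials$label %in% spk_levels),
              "trial labels must be SPK1, SPK2 or NONE")
  assert_that(all(trials$start >= 1) && all(trials$end <= n_samp + 1) &&
                all(trials$end > trials$start),
              "trial intervals must lie within the recording")
  o <- order(trials$start)
  trials <- trials[o, ]
  if (nrow(trials) > 1) {
    assert_that(all(trials$end[-nrow(trials)] <= trials$start[-1]),
                "trial intervals must not overlap")
  }
  assert_that(all(is.finite(data)), "data must be free of NaN/Inf")
  structure(
    list(data = data, sfreq = sfreq,
         channel_names = as.character(channel_names), trials = trials),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d trial(s)\n",
              nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq,
              nrow(x$trials)))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

trial_labels_to_samples <- function(rec) {
  lab <- rep("NONE", ncol(rec$data))
  for (i in seq_len(nrow(rec$trials))) {
    tr <- rec$trials[i, ]
    lab[seq.int(tr$start, tr$end - 1L)] <- tr$label
  }
  lab
}

# ---- native text bundle (JSON) ---------------------------------------------

#' Write / read a recording as the package's native JSON bundle
#'
#' A single self-describing JSON file holding the signal matrix at full double
#' precision (read-back agrees to ~1e-15 relative) plus sampling rate, channel
#' names and trials.
#'
#' @param rec an [eeg_recording()].
#' @param path file path (conventionally `.json`).
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an [eeg_recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  obj <- list(
    format = "msrqa-recording-v1",
    sfreq = rec$sfreq,
    channel_names = rec$channel_names,
    n_channels = nrow(rec$data),
    n_samples = ncol(rec$data),
    data = as.vector(rec$data),        # column-major channels x samples
    trials = rec$trials
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "msrqa-recording-v1")) {
    abort(sprintf("'%s' is not an msrqa recording bundle", path),
          class = "msrqa_format_error")
  }
  data <- matrix(obj$data, nrow = obj$n_channels, ncol = obj$n_samples)
  eeg_recording(data, obj$sfreq, obj$channel_names, as_tibble(obj$trials))
}

# ---- EDF / BDF --------------------------------------------------------------

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write an EDF or BioSemi BDF file
#'
#' EDF stores 16-bit samples, BDF 24-bit; both scale through the header's
#' physical/digital ranges, so the round trip is exact only to quantisation.
#' A single data record spanning the whole recording is written.
#'
#' @param rec an [eeg_recording()]. Trial annotations are not stored in the
#'   EDF/BDF container; keep them in a label sidecar (see [read_label_sidecar()]).
#' @param path output path.
#' @param format `"edf"` or `"bdf"`; default inferred from the file extension.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, format = c("auto", "edf", "bdf")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bdf$", path, ignore.case = TRUE)) "bdf" else "edf"
  }
  bdf <- format == "bdf"
  n_ch <- nrow(rec$data); n_samp <- ncol(rec$data)
  dig_max <- if (bdf) 8388607 else 32767
  dig_min <- if (bdf) -8388608 else -32768
  phys_min <- apply(rec$data, 1, min); phys_max <- apply(rec$data, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1   # avoid zero physical span
  con <- file(path, "wb")
  on.exit(close(con))
  if (bdf) {
    writeBin(as.raw(255L), con)
    writeChar("BIOSEMI", con, nchars = 7, eos = NULL)
  } else {
    writeChar(pad_field("0", 8), con, nchars = 8, eos = NULL)
  }
  writeChar(pad_field("X X X X", 80), con, nchars = 80, eos = NULL)
  writeChar(pad_field("Startdate X X X X", 80), con, nchars = 80, eos = NULL)
  writeChar(pad_field("01.01.00", 8), con, nchars = 8, eos = NULL)
  writeChar(pad_field("00.00.00", 8), con, nchars = 8, eos = NULL)
  writeChar(pad_field(256 * (n_ch + 1), 8), con, nchars = 8, eos = NULL)
  reserved <- if (bdf) "24BIT" else ""
  writeChar(pad_field(reserved, 44), con, nchars = 44, eos = NULL)
  writeChar(pad_field(1, 8), con, nchars = 8, eos = NULL)           # n records
  writeChar(pad_field(format(n_samp / rec$sfreq, digits = 7), 8), con,
            nchars = 8, eos = NULL)                                  # record dur
  writeChar(pad_field(n_ch, 4), con, nchars = 4, eos = NULL)
  wr_each <- function(vals, width) {
    for (v in vals) writeChar(pad_field(v, width), con, nchars = width, eos = NULL)
  }
  wr_each(rec$channel_names, 16)
  wr_each(rep("", n_ch), 80)                                         # transducer
  wr_each(rep("uV", n_ch), 8)                                        # phys dim
  wr_each(formatC(phys_min, digits = 7, width = 8), 8)
  wr_each(formatC(phys_max, digits = 7, width = 8), 8)
  wr_each(rep(dig_min, n_ch), 8)
  wr_each(rep(dig_max, n_ch), 8)
  wr_each(rep("", n_ch), 80)                                         # prefilter
  wr_each(rep(n_samp, n_ch), 8)                                      # samp/rec
  wr_each(rep("", n_ch), 32)
  # samples, signal by signal within the single record
  for (i in seq_len(n_ch)) {
    dig <- round((rec$data[i, ] - phys_min[i]) / (phys_max[i] - phys_min[i]) *
                   (dig_max - dig_min) + dig_min)
    if (bdf) {
      u <- as.integer(dig)
      u[u < 0] <- u[u < 0] + 16777216L                               # two's complement, 24-bit
      bytes <- rbind(u %% 256L, (u %/% 256L) %% 256L, (u %/% 65536L) %% 256L)
      writeBin(as.raw(as.vector(bytes)), con)
    } else {
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_header_field <- function(con, width) {
  trimws(readChar(con, width, useBytes = TRUE))
}

#' Read an EDF or BioSemi BDF file
#'
#' Detects the variant from the 8-byte magic. Returns all signals that share
#' the modal sampling rate (annotation channels are dropped with a warning).
#'
#' @param path file path.
#' @return An [eeg_recording()] with a single all-`NONE` trial; attach labels
#'   with [read_label_sidecar()] / [load_recording()].
#' @export
read_edf <- function(path) {
  assert_that(file.exists(path), sprintf("file '%s' does not exist", path),
              class = "msrqa_format_error")
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  bdf <- magic[1] == as.raw(255) && rawToChar(magic[-1]) == "BIOSEMI"
  if (!bdf && trimws(rawToChar(magic)) != "0") {
    abort(sprintf("'%s' is neither EDF nor BDF (bad magic)", path),
          class = "msrqa_format_error")
  }
  readBin(con, "raw", 160)                       # patient + recording id
  readBin(con, "raw", 16)                        # date + time
  header_bytes <- as.numeric(read_header_field(con, 8))
  read_header_field(con, 44)
  n_records <- as.numeric(read_header_field(con, 8))
  record_dur <- as.numeric(read_header_field(con, 8))
  n_ch <- as.integer(read_header_field(con, 4))
  if (!isTRUE(n_ch > 0) || !isTRUE(is.finite(n_records))) {
    abort(sprintf("'%s': corrupt EDF/BDF header", path), class = "msrqa_format_error")
  }
  if (sz < 256 * (n_ch + 1)) {
    abort(sprintf("'%s': file truncated inside the header", path),
          class = "msrqa_format_error")
  }
  rd <- function(width) vapply(seq_len(n_ch), function(i) read_header_field(con, width), "")
  labels <- rd(16); rd(80); rd(8)
  phys_min <- as.numeric(rd(8)); phys_max <- as.numeric(rd(8))
  dig_min <- as.numeric(rd(8)); dig_max <- as.numeric(rd(8))
  rd(80)
  samp_per_rec <- as.integer(rd(8)); rd(32)
  bps <- if (bdf) 3L else 2L
  expected <- header_bytes + n_records * sum(samp_per_rec) * bps
  if (is.na(expected) || sz < expected) {
    abort(sprintf("'%s': file truncated (%d bytes, expected %d)", path, sz, expected),
          class = "msrqa_format_error")
  }
  keep <- samp_per_rec == max(samp_per_rec) & !grepl("Annotation", labels)
  if (!all(keep)) warn("dropping non-signal / mismatched-rate channels")
  out <- matrix(0, sum(keep), n_records * max(samp_per_rec))
  row_of <- cumsum(keep)
  for (r in seq_len(n_records)) {
    for (i in seq_len(n_ch)) {
      ns <- samp_per_rec[i]
      if (bdf) {
        bytes <- as.integer(readBin(con, "raw", ns * 3L))
        u <- bytes[seq(1, length(bytes), 3)] +
          256 * bytes[seq(2, length(bytes), 3)] +
          65536 * bytes[seq(3, length(bytes), 3)]
        dig <- ifelse(u >= 8388608, u - 16777216, u)
      } else {
        dig <- readBin(con, "integer", ns, size = 2, endian = "little", signed = TRUE)
      }
      if (keep[i]) {
        phys <- (dig - dig_min[i]) / (dig_max[i] - dig_min[i]) *
          (phys_max[i] - phys_min[i]) + phys_min[i]
        out[row_of[i], seq.int((r - 1L) * ns + 1L, r * ns)] <- phys
      }
    }
  }
  sfreq <- max(samp_per_rec) / record_dur
  eeg_recording(out, sfreq, labels[keep])
}

# ---- label sidecar and the front-door loader --------------------------------

#' Attach trial labels from a JSON sidecar
#'
#' The sidecar is a JSON array of objects `{start_s, end_s, label}` with times
#' in seconds from recording onset and labels in `SPK1`/`SPK2`/`NONE`.
#'
#' @param rec an [eeg_recording()].
#' @param path sidecar path.
#' @return The recording with its `trials` table replaced.
#' @export
read_label_sidecar <- function(rec, path) {
  tab <- as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  assert_that(all(c("start_s", "end_s", "label") %in% names(tab)),
              "label sidecar needs start_s, end_s, label")
  trials <- tibble(
    start = as.integer(round(tab$start_s * rec$sfreq)) + 1L,
    end = as.integer(round(tab$end_s * rec$sfreq)) + 1L,
    label = as.character(tab$label)
  )
  eeg_recording(rec$data, rec$sfreq, rec$channel_names, trials)
}

#' @rdname read_label_sidecar
#' @param trials trial tibble of an [eeg_recording()].
#' @export
write_label_sidecar <- function(trials, path, sfreq) {
  out <- tibble(start_s = (trials$start - 1L) / sfreq,
                end_s = (trials$end - 1L) / sfreq,
                label = trials$label)
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Load an EEG recording from disk
#'
#' Front door for the supported containers: EDF, BioSemi BDF, and the package's
#' native JSON bundle. If `labels` is `NULL` and a file `<path>.labels.json`
#' exists it is used; if no sidecar is found the recording is returned with all
#' labels `NONE` and a warning (bundles carry their own trials).
#'
#' @param path recording path.
#' @param format one of `"auto"`, `"edf"`, `"bdf"`, `"bundle"`.
#' @param labels optional label sidecar path.
#' @return An [eeg_recording()].
#' @export
load_recording <- function(path, format = c("auto", "edf", "bdf", "bundle"),
                           labels = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "bundle"
    else if (grepl("\\.bdf$", path, ignore.case = TRUE)) "bdf" else "edf"
  }
  rec <- if (format == "bundle") read_recording(path) else read_edf(path)
  if (is.null(labels)) {
    cand <- paste0(path, ".labels.json")
    if (file.exists(cand)) labels <- cand
  }
  if (!is.null(labels)) {
    rec <- read_label_sidecar(rec, labels)
  } else if (format != "bundle" && all(rec$trials$label == "NONE")) {
    warn("no label sidecar found; all trial labels set to NONE")
  }
  rec
}
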