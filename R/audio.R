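# Optional audio path: minimal 16-bit PCM WAV I/O, a small Welch
# periodogram, and envelope-based call segmentation. This is a bespoke
# re-implementation of measurements normally taken interactively in a
# spectrogram GUI; it is not a clone of any particular tool's settings.

#' Write a mono 16-bit PCM WAV file
#'
#' @param wave numeric vector in [-1, 1] (clipped otherwise).
#' @param path output path.
#' @param fs sampling rate, Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, fs = 44100) {
  pcm <- as.integer(round(pmax(-1, pmin(1, wave)) * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(c(1, 1)), con, size = 2, endian = "little")  # PCM, mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little")   # byte rate
  writeBin(as.integer(c(2, 16)), con, size = 2, endian = "little") # align,bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' Only uncompressed 16-bit PCM is supported; multi-channel files return the
#' first channel.
#'
#' @param path WAV path.
#' @return list `wave` (numeric in [-1, 1]) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  fs <- NULL; n_ch <- 1L; bits <- 16L; wave <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported", call. = FALSE)
      n_ch <- fmt[2]
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      ba_bits <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      bits <- ba_bits[2]
      if (bits != 16L) stop("only 16-bit WAV supported", call. = FALSE)
      if (sz > 16) invisible(readBin(con, raw(), n = sz - 16))
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = sz / 2, size = 2, signed = TRUE,
                     endian = "little")
      if (n_ch > 1L) pcm <- pcm[seq(1, length(pcm), by = n_ch)]
      wave <- pcm / 32767
    } else {
      invisible(readBin(con, raw(), n = sz + sz %% 2))
    }
    if (!is.null(fs) && !is.null(wave)) break
  }
  if (is.null(wave)) stop("no data chunk found", call. = FALSE)
  list(wave = wave, fs = fs)
}

#' Welch power spectral density
#'
#' Mean of modified periodograms over Hann-windowed segments with 50%
#' overlap. Used for the dominant frequency of a call (argmax of the PSD).
#'
#' @param x signal.
#' @param fs sampling rate, Hz.
#' @param nfft segment length (samples); shorter signals use one
#'   zero-padded segment.
#' @return list `freq_hz`, `power`.
#' @export
welch_psd <- function(x, fs, nfft = 2048) {
  n <- length(x)
  if (n < nfft) {
    x <- c(x, numeric(nfft - n))
    n <- nfft
  }
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / (nfft + 1))
  starts <- seq(1L, n - nfft + 1L, by = nfft %/% 2L)
  acc <- numeric(nfft %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1L)] * win
    p <- abs(stats::fft(seg))^2
    acc <- acc + p[seq_len(nfft %/% 2L + 1L)]
  }
  list(freq_hz = (0:(nfft %/% 2L)) * fs / nfft,
       power = acc / length(starts))
}

#' Audio detection parameters for call segmentation
#'
#' @param envelope_lp_hz cutoff of the envelope smoother (moving average of
#'   length `fs / envelope_lp_hz`); must be below the pulse rate to merge
#'   pulses of one call into one envelope hump, and well below it to split
#'   calls. Default 8 Hz.
#' @param onset_thresh,offset_thresh hysteresis thresholds, as multiples of
#'   the noise floor (median envelope).
#' @param min_gap_s minimum silent gap between calls; shorter gaps are merged.
#' @param min_call_s minimum call duration; shorter detections dropped.
#' @param pulse_lp_hz cutoff of the finer envelope used for pulse counting;
#'   must exceed the pulse rate. Default 400 Hz.
#' @param nfft FFT segment length for the dominant-frequency PSD.
#' @return object of class `audio_params`.
#' @export
audio_params <- function(envelope_lp_hz = 8, onset_thresh = 4,
                         offset_thresh = 2.5, min_gap_s = 0.15,
                         min_call_s = 0.05, pulse_lp_hz = 400, nfft = 2048) {
  structure(list(envelope_lp_hz = envelope_lp_hz,
                 onset_thresh = onset_thresh, offset_thresh = offset_thresh,
                 min_gap_s = min_gap_s, min_call_s = min_call_s,
                 pulse_lp_hz = pulse_lp_hz, nfft = nfft),
            class = "audio_params")
}

# centered moving average (shrinking windows at the edges)
moving_avg <- function(x, w) {
  w <- max(1L, as.integer(w))
  n <- length(x)
  h <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Segment calls and measure them from raw audio
#'
#' Calls are segmented by thresholding a smoothed amplitude envelope with
#' hysteresis (on above `onset_thresh` x noise floor, off below
#' `offset_thresh` x), merging detections separated by less than `min_gap_s`.
#' Within each call, pulses are counted as local maxima of a finer envelope
#' above half the call's peak, and the dominant frequency is the argmax of
#' the Welch PSD over the call samples.
#'
#' @param wave numeric waveform in [-1, 1] (or a path to a WAV file).
#' @param fs sampling rate, Hz; ignored when `wave` is a path.
#' @param params an [audio_params()].
#' @param recording_id id copied into the result.
#' @return call event data frame
#'   (`recording_id, call_idx, onset_s, offset_s, pulse_count, domfreq_hz`);
#'   zero rows for silence.
#' @export
extract_from_audio <- function(wave, fs = 44100, params = audio_params(),
                               recording_id = "audio") {
  if (is.character(wave)) {
    w <- read_wav(wave)
    fs <- w$fs
    wave <- w$wave
  }
  env <- moving_avg(abs(wave), fs / params$envelope_lp_hz)
  floor_amp <- stats::median(env)
  hi <- params$onset_thresh * floor_amp
  lo <- params$offset_thresh * floor_amp
  if (max(env) <= hi || floor_amp == 0 && max(env) == 0) {
    return(empty_events(recording_id))
  }
  # hysteresis state machine over the envelope
  state <- FALSE
  on_idx <- integer(0); off_idx <- integer(0)
  above_hi <- env > hi; below_lo <- env < lo
  i <- 1L; n <- length(env)
  while (i <= n) {
    if (!state && above_hi[i]) {
      state <- TRUE; on_idx <- c(on_idx, i)
    } else if (state && below_lo[i]) {
      state <- FALSE; off_idx <- c(off_idx, i)
    }
    i <- i + 1L
  }
  if (state) off_idx <- c(off_idx, n)
  if (!length(on_idx)) return(empty_events(recording_id))
  # merge gaps shorter than min_gap_s
  min_gap <- params$min_gap_s * fs
  keep_on <- on_idx[1]; ons <- integer(0); offs <- integer(0)
  for (k in seq_along(on_idx)) {
    if (k > 1L) {
      if (on_idx[k] - off_idx[k - 1L] < min_gap) next
      ons <- c(ons, keep_on); offs <- c(offs, off_idx[k - 1L])
      keep_on <- on_idx[k]
    }
  }
  ons <- c(ons, keep_on); offs <- c(offs, off_idx[length(off_idx)])
  dur_ok <- (offs - ons) / fs >= params$min_call_s
  ons <- ons[dur_ok]; offs <- offs[dur_ok]
  if (!length(ons)) return(empty_events(recording_id))
  # pad each segment by the coarse smoother's half-width (without crossing
  # a neighbor), then refine onset/offset on the fine envelope
  pad <- as.integer(fs / params$envelope_lp_hz)
  n_w <- length(wave)
  rows <- lapply(seq_along(ons), function(k) {
    a <- max(if (k > 1L) offs[k - 1L] + 1L else 1L, ons[k] - pad)
    b <- min(if (k < length(ons)) ons[k + 1L] - 1L else n_w, offs[k] + pad)
    seg <- wave[a:b]
    fine <- moving_avg(abs(seg), fs / params$pulse_lp_hz)
    span <- which(fine > 0.3 * max(fine))
    i0 <- span[1]; i1 <- span[length(span)]
    # hysteresis pulse counting (on > 0.5 max, off < 0.35 max) so noise
    # chatter around a single threshold cannot split a pulse in two
    fseg <- fine[i0:i1]
    hi_p <- 0.5 * max(fine); lo_p <- 0.35 * max(fine)
    state_p <- FALSE
    pulses <- 0L
    for (v in fseg) {
      if (!state_p && v > hi_p) { state_p <- TRUE; pulses <- pulses + 1L }
      else if (state_p && v < lo_p) state_p <- FALSE
    }
    psd <- welch_psd(seg[i0:i1], fs, params$nfft)
    data.frame(
      recording_id = recording_id, call_idx = k,
      onset_s = (a + i0 - 2L) / fs, offset_s = (a + i1 - 2L) / fs,
      pulse_count = max(1L, pulses),
      domfreq_hz = psd$freq_hz[which.max(psd$power)]
    )
  })
  do.call(rbind, rows)
}

empty_events <- function(recording_id) {
  data.frame(recording_id = character(0), call_idx = integer(0),
             onset_s = numeric(0), offset_s = numeric(0),
             pulse_count = integer(0), domfreq_hz = numeric(0))
}
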