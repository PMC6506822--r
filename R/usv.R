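#' Spectrogram settings for 22-kHz call detection
#'
#' The canonical analysis settings: 512-point FFT with 87.5% overlap and
#' a flat-top window on 214285-Hz audio, giving a frequency resolution of
#' about 419 Hz and a time resolution (hop) of about 0.29 ms.
#'
#' @param fft_len FFT length in samples (power of two).
#' @param overlap_fraction window overlap in `[0, 1)`.
#' @param sample_rate audio sampling rate, Hz.
#' @param window window type; only `"flattop"` is implemented.
#' @return list of class `usv_spec_config`.
#' @export
usv_spectrogram_config <- function(fft_len = 512L, overlap_fraction = 0.875,
                                   sample_rate = 214285,
                                   window = "flattop") {
  assert_that(overlap_fraction >= 0 && overlap_fraction < 1,
              "overlap_fraction must be in [0, 1)")
  assert_that(bitwAnd(fft_len, fft_len - 1L) == 0L && fft_len > 0L,
              "fft_len must be a power of two")
  structure(list(fft_len = as.integer(fft_len),
                 overlap_fraction = overlap_fraction,
                 sample_rate = sample_rate, window = window,
                 hop = as.integer(round(fft_len * (1 - overlap_fraction)))),
            class = "usv_spec_config")
}

#' Spectrogram resolution identities
#'
#' Frequency spacing (`sample_rate / fft_len`) and hop duration
#' (`fft_len * (1 - overlap) / sample_rate`), both raw and as
#' conventionally printed (frequency rounded to integer Hz, hop in ms
#' truncated to two decimals).
#'
#' @param config a [usv_spectrogram_config()].
#' @return list with `freq_res_hz`, `hop_s`, `freq_res_hz_printed`,
#'   `hop_ms_printed`.
#' @export
#' @examples
#' spectrogram_resolution(usv_spectrogram_config())
spectrogram_resolution <- function(config = usv_spectrogram_config()) {
  df <- config$sample_rate / config$fft_len
  hop_s <- config$hop / config$sample_rate
  list(freq_res_hz = df, hop_s = hop_s,
       freq_res_hz_printed = round(df),
       hop_ms_printed = floor(hop_s * 1e3 * 100) / 100)
}

#' Magnitude spectrogram of ultrasonic audio
#'
#' Short-time FFT with the configured window, computed in chunks so that
#' long high-rate recordings never materialize the full complex frame
#' matrix.  Magnitudes are linear; the session-wide maximum is stored so
#' downstream stages can express levels in dB relative to it.
#'
#' @param audio numeric audio at `config$sample_rate`.
#' @param config a [usv_spectrogram_config()].
#' @param band optional `c(lo_hz, hi_hz)`: keep only frequency rows in
#'   this band (the overall maximum is still taken over all rows).
#' @return list of class `usv_spectrogram`: `mag` (freq x time, linear),
#'   `freq_hz`, `times_s` (frame centres), `max_mag`, `hop_s`, `config`.
#' @export
compute_spectrogram <- function(audio, config = usv_spectrogram_config(),
                                band = NULL) {
  nfft <- config$fft_len
  assert_that(length(audio) >= nfft, "audio shorter than one FFT frame")
  hop <- config$hop
  rate <- config$sample_rate
  win <- signal::flattopwin(nfft)
  starts <- seq(1L, length(audio) - nfft + 1L, by = hop)
  freq <- (0:(nfft / 2)) * rate / nfft
  rows <- seq_along(freq)
  if (!is.null(band)) {
    rows <- which(freq >= band[1] & freq <= band[2])
    assert_that(length(rows) > 0, "band outside spectrogram range")
  }

  n_frames <- length(starts)
  mag <- matrix(0, length(rows), n_frames)
  max_mag <- 0
  chunk <- 8192L
  off <- 0:(nfft - 1L)
  for (c0 in seq(1L, n_frames, by = chunk)) {
    c1 <- min(c0 + chunk - 1L, n_frames)
    s <- starts[c0:c1]
    idx <- outer(off, s, `+`)
    W <- matrix(audio[idx], nfft) * win
    Fm <- Mod(stats::mvfft(W))[seq_len(nfft / 2 + 1L), , drop = FALSE]
    max_mag <- max(max_mag, max(Fm))
    mag[, c0:c1] <- Fm[rows, , drop = FALSE]
  }
  structure(list(mag = mag, freq_hz = freq[rows],
                 times_s = (starts - 1L + nfft / 2) / rate,
                 max_mag = max_mag, hop_s = hop / rate, config = config),
            class = "usv_spectrogram")
}

#' Whistle tracking: detect 22-kHz calls in a spectrogram
#'
#' A frame is voiced when its in-band peak exceeds `threshold_db`
#' relative to the session-wide spectrogram maximum.  Voiced runs
#' separated by gaps shorter than the hold time are merged, and merged
#' runs shorter than the minimum duration are discarded.  Each surviving
#' run becomes one call, with features from [call_features()].
#'
#' @param spec a [compute_spectrogram()] result covering the band.
#' @param threshold_db detection threshold, dB relative to session max.
#' @param min_duration_s minimal call duration.
#' @param hold_time_s gaps shorter than this merge adjacent runs.
#' @param band analysis band in Hz (18-32 kHz for 22-kHz calls).
#' @return data.frame of class `usv_calls`: `onset_s`, `offset_s`,
#'   `duration_s`, `peak_freq_hz`, `peak_amp_db`.
#' @export
track_whistles <- function(spec, threshold_db = -20, min_duration_s = 0.01,
                           hold_time_s = 0.02, band = c(18000, 32000)) {
  rows <- which(spec$freq_hz >= band[1] & spec$freq_hz <= band[2])
  assert_that(length(rows) > 0, "band outside spectrogram range")
  sub <- spec$mag[rows, , drop = FALSE]
  peak <- apply(sub, 2L, max)
  db <- 20 * log10(pmax(peak, .Machine$double.xmin) / spec$max_mag)
  voiced <- db > threshold_db

  runs <- rle(voiced)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  vstart <- starts[runs$values]; vend <- ends[runs$values]
  if (length(vstart) == 0L) return(empty_calls())

  # merge runs across sub-hold gaps
  hop <- spec$hop_s
  ms <- vstart[1L]; me <- vend[1L]
  mstart <- integer(0); mend <- integer(0)
  for (j in seq_along(vstart)[-1L]) {
    gap_s <- (vstart[j] - me - 1L) * hop
    if (gap_s < hold_time_s) {
      me <- vend[j]
    } else {
      mstart <- c(mstart, ms); mend <- c(mend, me)
      ms <- vstart[j]; me <- vend[j]
    }
  }
  mstart <- c(mstart, ms); mend <- c(mend, me)

  dur <- (mend - mstart + 1L) * hop
  keep <- dur >= min_duration_s
  mstart <- mstart[keep]; mend <- mend[keep]
  if (length(mstart) == 0L) return(empty_calls())

  feats <- lapply(seq_along(mstart), function(j)
    call_features(mstart[j]:mend[j], spec, rows))
  out <- do.call(rbind, feats)
  class(out) <- c("usv_calls", "data.frame")
  out
}

empty_calls <- function() {
  structure(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                       duration_s = numeric(0), peak_freq_hz = numeric(0),
                       peak_amp_db = numeric(0)),
            class = c("usv_calls", "data.frame"))
}

#' Features of one detected call
#'
#' Peak amplitude is the maximum in-band level (dB re session max) over
#' the call's frames; peak frequency is the frequency of that maximum;
#' duration spans the call's frames (one hop per frame).
#'
#' @param frame_idx integer indices of the call's spectrogram frames.
#' @param spec the [compute_spectrogram()] result.
#' @param rows in-band row indices (defaults to all rows of `spec`).
#' @return one-row data.frame (`onset_s`, `offset_s`, `duration_s`,
#'   `peak_freq_hz`, `peak_amp_db`).
#' @export
call_features <- function(frame_idx, spec, rows = seq_along(spec$freq_hz)) {
  assert_that(length(frame_idx) >= 1L, "call must have at least one frame")
  sub <- spec$mag[rows, frame_idx, drop = FALSE]
  pk <- arrayInd(which.max(sub), dim(sub))
  hop <- spec$hop_s
  onset <- spec$times_s[frame_idx[1L]]
  data.frame(onset_s = onset,
             offset_s = onset + length(frame_idx) * hop,
             duration_s = length(frame_idx) * hop,
             peak_freq_hz = spec$freq_hz[rows][pk[1L]],
             peak_amp_db = 20 * log10(max(sub) / spec$max_mag))
}

#' Group calls into USV blocks
#'
#' Successive calls separated by less than `max_gap_s` (offset to next
#' onset) belong to one block; a gap of `max_gap_s` or more starts a new
#' block.  Downstream, a block's bounding interval — including its
#' sub-second internal gaps — counts as USV time, and inter-block
#' periods are silent.
#'
#' @param calls a call table (any data.frame with `onset_s`, `offset_s`),
#'   time-ordered; unordered input is sorted with a warning.
#' @param max_gap_s block-breaking gap (1 s).
#' @return data.frame of class `usv_blocks`: `onset_s`, `offset_s`,
#'   `n_calls`, `first_call`, `last_call` (row indices into the sorted
#'   call table).
#' @export
group_blocks <- function(calls, max_gap_s = 1.0) {
  if (nrow(calls) == 0L)
    return(structure(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                                n_calls = integer(0), first_call = integer(0),
                                last_call = integer(0)),
                     class = c("usv_blocks", "data.frame")))
  if (is.unsorted(calls$onset_s)) {
    warning("call table not time-ordered; sorting by onset")
    calls <- calls[order(calls$onset_s), , drop = FALSE]
  }
  gaps <- calls$onset_s[-1L] - calls$offset_s[-nrow(calls)]
  new_block <- c(TRUE, gaps >= max_gap_s)
  grp <- cumsum(new_block)
  idx <- seq_len(nrow(calls))
  out <- data.frame(
    onset_s = as.numeric(tapply(calls$onset_s, grp, min)),
    offset_s = as.numeric(tapply(calls$offset_s, grp, max)),
    n_calls = as.integer(tapply(idx, grp, length)),
    first_call = as.integer(tapply(idx, grp, min)),
    last_call = as.integer(tapply(idx, grp, max)))
  class(out) <- c("usv_blocks", "data.frame")
  out
}
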