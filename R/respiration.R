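#' Zero-phase moving-average smoothing
#'
#' Centred moving average of the stated width, used for noise reduction
#' before zero-crossing detection.  The window is applied circularly
#' (wrapping at the trace ends), so the output has the same length and
#' the mean is preserved exactly.
#'
#' @param trace numeric signal.
#' @param rate sampling rate, Hz.
#' @param window_s window width, seconds (at least two sample periods).
#' @return smoothed numeric of the same length.
#' @export
#' @examples
#' smooth_signal(rep(1, 10), 100, 0.05)
smooth_signal <- function(trace, rate, window_s) {
  w <- max(3L, round(window_s * rate))
  if (w %% 2L == 0L) w <- w + 1L
  assert_that(window_s >= 2 / rate, "window_s must span >= 2 sample periods")
  assert_that(w <= length(trace), "smoothing window longer than trace")
  as.numeric(stats::filter(trace, rep(1 / w, w), sides = 2,
                           circular = TRUE))
}

# slowly drifting baseline: 2-s centred running mean.  A running median is
# structurally biased here: with inspiration occupying ~40% of the cycle the
# median of a zero-mean breathing waveform sits well above zero, shifting
# every crossing; the mean does not.
running_baseline <- function(x, rate, window_s = 2) {
  w <- min(round(window_s * rate), length(x))
  if (w %% 2L == 0L) w <- w - 1L
  if (w < 3L) return(rep(mean(x), length(x)))
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2, circular = TRUE))
}

#' Detect respiratory cycles by smoothed zero-crossing
#'
#' The trace is smoothed (centred moving average), a slowly drifting
#' baseline (2-s running median) is subtracted, and baseline crossings
#' with a small hysteresis (5% of the interquartile range) mark phase
#' starting points.  Under the `"neg"` sign convention, inspiration
#' onsets are downward crossings and expiration onsets upward crossings
#' (swapped for `"pos"`).  Crossing times are refined by linear
#' interpolation between the samples bracketing the crossing.  Cycles
#' shorter than `min_cycle_s` are merged into the preceding cycle, and
#' incomplete first/last cycles are discarded.
#'
#' @param trace numeric respiration signal.
#' @param rate sampling rate, Hz.
#' @param smoothing_window_s moving-average width, seconds.
#' @param min_cycle_s minimal plausible cycle duration (10 Hz ceiling by
#'   default, above the rat sniffing range in this paradigm).
#' @param sign_convention `"neg"` if inspiration is the negative limb.
#' @return data.frame of class `resp_cycles`: `insp_onset_s`,
#'   `exp_onset_s`, `next_insp_onset_s`, `duration_s`, `inst_freq_hz`.
#'   Empty (with a warning) if the trace never crosses baseline.
#' @export
detect_cycles <- function(trace, rate, smoothing_window_s = 0.025,
                          min_cycle_s = 0.1,
                          sign_convention = c("neg", "pos")) {
  sign_convention <- match.arg(sign_convention)
  assert_that(length(trace) / rate >= 2 * min_cycle_s,
              "trace shorter than two minimal cycles")
  y <- smooth_signal(trace, rate, smoothing_window_s)
  y <- y - running_baseline(y, rate)
  if (sign_convention == "neg") y <- -y   # inspiration becomes positive limb

  h <- 0.05 * stats::IQR(y)
  if (max(abs(y)) <= h || h == 0) {
    warning("no baseline crossings detected; returning empty cycle list")
    return(empty_cycles())
  }

  # Schmitt trigger: state +1 after exceeding +h, -1 after going below -h
  above <- y > h
  below <- y < -h
  event <- integer(length(y))
  event[above] <- 1L
  event[below] <- -1L
  nz <- which(event != 0L)
  st <- event[nz]
  flips <- nz[c(TRUE, st[-1L] != st[-length(st)])]
  states <- event[flips]

  # refine each flip to the nearest preceding sign change of y
  cross_t <- numeric(length(flips))
  keep <- logical(length(flips))
  sgn <- sign(y)
  for (j in seq_along(flips)) {
    i <- flips[j]
    want <- states[j]            # sign after the crossing
    k <- i
    while (k > 1L && sgn[k - 1L] == want) k <- k - 1L  # walk back inside limb
    if (k > 1L) {
      y0 <- y[k - 1L]; y1 <- y[k]
      frac <- if (y1 != y0) (0 - y0) / (y1 - y0) else 0
      cross_t[j] <- (k - 2L + frac) / rate
      keep[j] <- TRUE
    }
  }
  cross_t <- cross_t[keep]; states <- states[keep]

  # inspiration onset = transition into the inspiration (positive) limb
  insp_t <- cross_t[states == 1L]
  exp_t <- cross_t[states == -1L]
  if (length(insp_t) < 2L) {
    warning("fewer than two inspiration onsets; returning empty cycle list")
    return(empty_cycles())
  }

  cyc <- build_cycles(insp_t, exp_t)
  cyc <- merge_short_cycles(cyc, min_cycle_s)
  class(cyc) <- c("resp_cycles", "data.frame")
  cyc
}

empty_cycles <- function() {
  structure(data.frame(insp_onset_s = numeric(0), exp_onset_s = numeric(0),
                       next_insp_onset_s = numeric(0),
                       duration_s = numeric(0), inst_freq_hz = numeric(0)),
            class = c("resp_cycles", "data.frame"))
}

build_cycles <- function(insp_t, exp_t) {
  out <- vector("list", length(insp_t) - 1L)
  m <- 0L
  for (i in seq_len(length(insp_t) - 1L)) {
    e <- exp_t[exp_t > insp_t[i] & exp_t < insp_t[i + 1L]]
    if (length(e) == 0L) next          # malformed cycle, skip
    m <- m + 1L
    out[[m]] <- c(insp_t[i], e[1L], insp_t[i + 1L])
  }
  if (m == 0L) return(empty_cycles())
  mat <- do.call(rbind, out[seq_len(m)])
  data.frame(insp_onset_s = mat[, 1L], exp_onset_s = mat[, 2L],
             next_insp_onset_s = mat[, 3L],
             duration_s = mat[, 3L] - mat[, 1L],
             inst_freq_hz = 1 / (mat[, 3L] - mat[, 1L]))
}

# a cycle shorter than min_cycle_s is absorbed into its predecessor (the
# predecessor's end moves forward; its expiration onset is kept)
merge_short_cycles <- function(cyc, min_cycle_s) {
  if (nrow(cyc) == 0L) return(cyc)
  i <- 2L
  while (i <= nrow(cyc)) {
    if (cyc$duration_s[i] < min_cycle_s) {
      cyc$next_insp_onset_s[i - 1L] <- cyc$next_insp_onset_s[i]
      cyc <- cyc[-i, , drop = FALSE]
    } else i <- i + 1L
  }
  if (nrow(cyc) > 0L && cyc$duration_s[1L] < min_cycle_s)
    cyc <- cyc[-1L, , drop = FALSE]
  cyc$duration_s <- cyc$next_insp_onset_s - cyc$insp_onset_s
  cyc$inst_freq_hz <- 1 / cyc$duration_s
  rownames(cyc) <- NULL
  cyc
}

#' Instantaneous respiratory frequency series
#'
#' Piecewise-constant series: within cycle k the value is
#' `1 / duration` of that cycle; `NA` outside detected cycles.  The
#' default 4-ms step matches the clock of the frequency-coupling
#' analysis.
#'
#' @param cycles a cycle table from [detect_cycles()] (or simulator truth).
#' @param step_s sampling step of the output series, seconds.
#' @param t_range optional `c(t0, t1)` span; defaults to the cycle span.
#' @return list of class `inst_freq_series` with `times` and `freq_hz`.
#' @export
instantaneous_frequency <- function(cycles, step_s = 0.004, t_range = NULL) {
  if (nrow(cycles) == 0L)
    return(structure(list(times = numeric(0), freq_hz = numeric(0),
                          step_s = step_s), class = "inst_freq_series"))
  if (is.null(t_range))
    t_range <- c(cycles$insp_onset_s[1L],
                 cycles$next_insp_onset_s[nrow(cycles)])
  times <- seq(t_range[1L], t_range[2L], by = step_s)
  freq <- cycle_phase_at(times, cycles)$freq
  structure(list(times = times, freq_hz = freq, step_s = step_s),
            class = "inst_freq_series")
}

#' Respiratory-frequency probability distribution
#'
#' Histogram of instantaneous-frequency samples restricted to a set of
#' segments, normalized to total mass 1, with the peak (modal) frequency
#' reported.  Bin edges are anchored at 0 Hz with the stated width.
#'
#' @param freq_series an [instantaneous_frequency()] series.
#' @param segments data.frame with `onset_s`/`offset_s` (e.g. category
#'   segments); samples outside all segments are ignored.
#' @param bin_hz histogram bin width (0.33 Hz default).
#' @return list of class `resp_pdf`: `breaks`, `mids`, `mass`
#'   (sums to 1), `peak_hz` (centre of the modal bin), `n_samples`.
#' @export
respiration_pdf <- function(freq_series, segments, bin_hz = 0.33) {
  check_intervals(segments, "segments")
  assert_that(nrow(segments) > 0, "segments must be non-empty")
  sel <- points_in_intervals(freq_series$times, segments$onset_s,
                             segments$offset_s)
  f <- freq_series$freq_hz[sel]
  f <- f[!is.na(f)]
  if (length(f) == 0L)
    stop_typed("fearresp_no_data",
               "frequency series undefined on all supplied segments")
  breaks <- seq(0, (floor(max(f) / bin_hz) + 1) * bin_hz, by = bin_hz)
  h <- graphics::hist(f, breaks = breaks, plot = FALSE, right = FALSE)
  mass <- h$counts / sum(h$counts)
  structure(list(breaks = breaks, mids = h$mids, mass = mass,
                 peak_hz = h$mids[which.max(mass)], n_samples = length(f)),
            class = "resp_pdf")
}

#' @export
print.resp_pdf <- function(x, ...) {
  cat(sprintf("<resp_pdf> %d samples, peak %.2f Hz (bin %.2f Hz)\n",
              x$n_samples, x$peak_hz, diff(x$breaks[1:2])))
  invisible(x)
}
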