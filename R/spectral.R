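#' Default wavelet frequency grid
#'
#' 0.1-Hz spacing below 15 Hz (where delta/theta structure is resolved)
#' and 0.5-Hz spacing from 15 to 80 Hz.
#'
#' @param f_min,f_max grid limits, Hz.
#' @return numeric vector of frequencies, strictly increasing.
#' @export
default_freq_grid <- function(f_min = 0.5, f_max = 80) {
  lo <- seq(f_min, min(15, f_max), by = 0.1)
  if (f_max <= 15) return(lo)
  c(lo, seq(15.5, f_max, by = 0.5))
}

#' Continuous Morlet wavelet scalogram
#'
#' Convolution of the trace with complex Morlet atoms of `center_cycles`
#' cycles at each grid frequency, implemented in the frequency domain:
#' the analytic Gaussian filter has peak gain 2 at its centre frequency,
#' so the modulus of the output equals the envelope amplitude of a pure
#' sinusoid (a unit-amplitude tone yields amplitude 1 at its own
#' frequency).  Each frequency carries a cone-of-influence half-width
#' (`2 * sigma_t`); samples closer than that to either trace edge are
#' excluded from downstream averages.
#'
#' @param trace numeric LFP trace.
#' @param rate sampling rate, Hz.
#' @param freqs frequency grid; default [default_freq_grid()] clipped to
#'   `f_min`/`f_max`.
#' @param f_min,f_max grid limits when `freqs` is NULL (`f_max` must be
#'   below Nyquist).
#' @param center_cycles wavelet width in cycles (>= 5 for admissibility).
#' @param step_s output time step; the amplitude matrix is decimated to
#'   this step (default: native sample step).
#' @return list of class `scalogram`: `amp` (time x frequency matrix),
#'   `freq_hz`, `times_s`, `coi_s` (per-frequency edge half-width),
#'   `span_s` (trace duration), `rate`.
#' @export
morlet_scalogram <- function(trace, rate, freqs = NULL, f_min = 0.5,
                             f_max = 80, center_cycles = 6, step_s = NULL) {
  if (is.null(freqs)) freqs <- default_freq_grid(f_min, f_max)
  assert_that(all(diff(freqs) > 0), "frequency grid must be increasing")
  assert_that(max(freqs) < rate / 2, "f_max must be below Nyquist")
  assert_that(center_cycles >= 5, "center_cycles must be >= 5")

  n <- length(trace)
  npad <- stats::nextn(2L * n, 2)
  X <- stats::fft(c(trace, numeric(npad - n)))
  k <- 0:(npad - 1L)
  fgrid <- k / npad * rate
  pos <- fgrid <= rate / 2          # analytic filter: positive freqs only

  dec <- if (is.null(step_s)) 1L else max(1L, round(step_s * rate))
  keep <- seq(1L, n, by = dec)
  amp <- matrix(0, length(keep), length(freqs))
  for (j in seq_along(freqs)) {
    f0 <- freqs[j]
    sf <- f0 / center_cycles
    H <- numeric(npad)
    H[pos] <- 2 * exp(-0.5 * ((fgrid[pos] - f0) / sf)^2)
    w <- stats::fft(X * H, inverse = TRUE) / npad
    amp[, j] <- Mod(w[keep])
  }
  structure(list(amp = amp, freq_hz = freqs,
                 times_s = (keep - 1L) / rate,
                 coi_s = 2 * center_cycles / (2 * pi * freqs),
                 span_s = (n - 1L) / rate, rate = rate),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %d times x %d freqs (%.2f-%.2f Hz), span %.1f s\n",
              nrow(x$amp), length(x$freq_hz), min(x$freq_hz), max(x$freq_hz),
              x$span_s))
  invisible(x)
}

# per-frequency logical matrix of samples outside the cone of influence
outside_coi <- function(scal) {
  t <- scal$times_s
  ok <- outer(t, scal$coi_s, function(tt, c) tt >= c & tt <= scal$span_s - c)
  ok
}

#' Per-category mean spectra from a scalogram
#'
#' Duration-weighted time-average of the scalogram over each category's
#' segments: all samples falling inside any of a category's segments are
#' pooled, so splitting a segment leaves the result unchanged.  Samples
#' inside the cone of influence at the trace edges are excluded.  Both
#' the mean amplitude (as plotted in PSD figures) and the mean power
#' (squared modulus, used for band means) are returned.
#'
#' @param scal a [morlet_scalogram()].
#' @param segments a `category_segments` table (or any data.frame with
#'   `label`, `onset_s`, `offset_s`).
#' @return list of class `category_psd`: `freq_hz`, `amplitude` and
#'   `power` (frequency x category matrices; a category with zero
#'   retained time yields `NA` columns), `n_samples` per category.
#' @export
category_psd <- function(scal, segments) {
  assert_that(nrow(segments) > 0, "no segments supplied")
  cats <- unique(segments$label)
  ok <- outside_coi(scal)
  ampm <- matrix(NA_real_, length(scal$freq_hz), length(cats),
                 dimnames = list(NULL, cats))
  powm <- ampm
  nsamp <- stats::setNames(integer(length(cats)), cats)
  for (cat in cats) {
    seg <- segments[segments$label == cat, , drop = FALSE]
    sel <- points_in_intervals(scal$times_s, seg$onset_s, seg$offset_s)
    nsamp[cat] <- sum(sel)
    if (!any(sel)) next
    use <- ok & sel                 # recycle sel over columns
    a <- scal$amp
    a[!use] <- NA
    ampm[, cat] <- colMeans(a, na.rm = TRUE)
    powm[, cat] <- colMeans(a^2, na.rm = TRUE)
  }
  structure(list(freq_hz = scal$freq_hz, amplitude = ampm, power = powm,
                 n_samples = nsamp),
            class = "category_psd")
}

#' Mean band power per category
#'
#' Mean over each band's frequency bins of the category-averaged power.
#' Bands are half-open `[lo, hi)` so shared boundaries are counted once.
#'
#' @param psd a [category_psd()] result.
#' @param bands named list of `c(lo, hi)` pairs; default [lfp_bands()].
#' @return data.frame of class `band_power_table` with columns
#'   `category`, `band`, `mean_power`.
#' @export
band_power <- function(psd, bands = lfp_bands()) {
  rows <- list()
  for (b in names(bands)) {
    sel <- psd$freq_hz >= bands[[b]][1] & psd$freq_hz < bands[[b]][2]
    assert_that(any(sel), "band %s contains no grid frequencies", b)
    for (cat in colnames(psd$power)) {
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat, band = b,
        mean_power = mean(psd$power[sel, cat]))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("band_power_table", "data.frame")
  out
}
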