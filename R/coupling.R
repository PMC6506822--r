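#' Dominant low-frequency LFP rhythm over time
#'
#' At each time step, the frequency of the maximum wavelet amplitude
#' within the 0-15 Hz analysis band; ties break toward the lower
#' frequency.  Steps where the whole column is zero are flagged `NA`.
#'
#' @param scal a [morlet_scalogram()] whose grid covers the band.
#' @param band analysis band, Hz.
#' @param step_s output step; the scalogram is subsampled to a 4-ms
#'   clock shared with [instantaneous_frequency()].
#' @return list of class `dominant_freq_series`: `times`, `freq_hz`.
#' @export
dominant_lfp_frequency <- function(scal, band = c(0, 15), step_s = 0.004) {
  cols <- which(scal$freq_hz >= band[1] & scal$freq_hz <= band[2])
  assert_that(length(cols) > 0, "scalogram grid does not cover the band")
  native <- if (length(scal$times_s) > 1L) diff(scal$times_s[1:2]) else step_s
  dec <- max(1L, round(step_s / native))
  rows <- seq(1L, nrow(scal$amp), by = dec)
  sub <- scal$amp[rows, cols, drop = FALSE]
  idx <- max.col(sub, ties.method = "first")
  freq <- scal$freq_hz[cols][idx]
  freq[rowSums(sub) == 0] <- NA_real_
  structure(list(times = scal$times_s[rows], freq_hz = freq,
                 step_s = native * dec),
            class = "dominant_freq_series")
}

#' Joint histogram of respiratory and dominant LFP frequency
#'
#' Pairs the instantaneous respiratory frequency with the dominant LFP
#' frequency on a shared clock, restricted to the supplied segments,
#' and bins the pairs on a 2D grid (respiration on x, LFP on y) with
#' equal bin width on both axes.  The histogram is normalized to total
#' mass 1.  Steps where either series is undefined are dropped pairwise.
#'
#' @param resp an [instantaneous_frequency()] series.
#' @param lfp a [dominant_lfp_frequency()] series on the same clock.
#' @param segments data.frame with `onset_s`/`offset_s`; only samples
#'   inside these intervals are paired.
#' @param bin_hz bin width on both axes (0.33 Hz).
#' @param f_max upper frequency edge of the histogram (15 Hz).
#' @return list of class `coupling_histogram`: `resp_edges`,
#'   `lfp_edges`, `mass` (resp-bin x lfp-bin, sums to 1), `n_pairs`.
#' @export
coupling_histogram <- function(resp, lfp, segments, bin_hz = 0.33,
                               f_max = 15) {
  check_intervals(segments, "segments")
  # align the two series on their common time grid
  tol <- min(resp$step_s, lfp$step_s) / 4
  mi <- match(round(resp$times / tol), round(lfp$times / tol))
  ok <- !is.na(mi)
  rt <- resp$times[ok]
  rf <- resp$freq_hz[ok]
  lf <- lfp$freq_hz[mi[ok]]
  sel <- points_in_intervals(rt, segments$onset_s, segments$offset_s) &
    !is.na(rf) & !is.na(lf)
  rf <- rf[sel]; lf <- lf[sel]
  if (length(rf) == 0L)
    stop_typed("fearresp_no_data", "no paired samples inside segments")

  edges <- seq(0, (ceiling(f_max / bin_hz)) * bin_hz, by = bin_hz)
  nb <- length(edges) - 1L
  ri <- pmin(pmax(findInterval(rf, edges), 1L), nb)
  li <- pmin(pmax(findInterval(lf, edges), 1L), nb)
  mass <- matrix(0, nb, nb)
  tab <- table(factor(ri, levels = seq_len(nb)),
               factor(li, levels = seq_len(nb)))
  mass <- unclass(tab) / length(rf)
  dimnames(mass) <- NULL
  structure(list(resp_edges = edges, lfp_edges = edges, mass = mass,
                 n_pairs = length(rf)),
            class = "coupling_histogram")
}

#' Diagonal coupling index
#'
#' Scalar summary of how much joint mass concentrates along the identity
#' line: the mass of cells whose respiratory and LFP bin-centre
#' frequencies differ by at most `tol_hz`, minus the expectation of that
#' quantity under the product of the marginals (independence), clipped
#' to `[0, 1]`.  Near 0 for independent rhythms, approaching 1 when the
#' LFP rhythm tracks the breathing rate over a range of rates.
#'
#' @param hist a [coupling_histogram()].
#' @param tol_hz half-width of the diagonal band, Hz.
#' @return scalar in `[0, 1]`.
#' @export
diagonal_coupling_index <- function(hist, tol_hz = 0.5) {
  centers <- (hist$resp_edges[-1L] + hist$resp_edges[-length(hist$resp_edges)]) / 2
  d <- abs(outer(centers, centers, `-`)) <= tol_hz + 1e-9
  observed <- sum(hist$mass[d])
  indep <- outer(rowSums(hist$mass), colSums(hist$mass))
  expected <- sum(indep[d])
  min(max(observed - expected, 0), 1)
}

#' @export
print.coupling_histogram <- function(x, ...) {
  cat(sprintf("<coupling_histogram> %d x %d bins, %d pairs, index %.3f\n",
              nrow(x$mass), ncol(x$mass), x$n_pairs,
              diagonal_coupling_index(x)))
  invisible(x)
}
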