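#' Cycle-frequency scalogram (respiratory-phase-normalized power map)
#'
#' Maps LFP power onto a normalized respiratory-cycle template: for each
#' usable cycle the scalogram's inspiration samples are linearly
#' interpolated onto phases `[0, insp_fraction)` and the expiration
#' samples onto `[insp_fraction, 1)`, on a 40-bin grid (bin centres at
#' `0.0125, 0.0375, ...`).  Power (squared amplitude) is then averaged
#' across cycles, bin by bin.  Cycles are used only when they lie
#' entirely inside one of the supplied segments and both phases contain
#' at least two scalogram samples.
#'
#' @param scal a [morlet_scalogram()] of the LFP.
#' @param cycles a cycle table ([detect_cycles()] or truth).
#' @param segments data.frame with `onset_s`/`offset_s`; cycles
#'   straddling a segment edge are dropped entirely.
#' @param insp_fraction template position of the inspiration/expiration
#'   transition (0.4: the average inspiration share of a cycle).
#' @param bin phase-bin width (0.025, i.e. 40 bins).
#' @return list of class `cycle_scalogram`: `phase` (bin centres),
#'   `freq_hz`, `power` (phase x frequency), `n_cycles`.
#' @export
cycle_frequency_scalogram <- function(scal, cycles, segments,
                                      insp_fraction = 0.4, bin = 0.025) {
  assert_that(bin > 0 && abs(1 / bin - round(1 / bin)) < 1e-9,
              "bin must divide 1 exactly")
  nb <- as.integer(round(1 / bin))
  centers <- (seq_len(nb) - 0.5) * bin
  t <- scal$times_s
  pow <- scal$amp^2

  inside <- points_in_intervals(cycles$insp_onset_s, segments$onset_s,
                                segments$offset_s) &
    points_in_intervals(pmax(cycles$next_insp_onset_s - 1e-9,
                             cycles$insp_onset_s),
                        segments$onset_s, segments$offset_s)
  # also require onset and end in the *same* segment
  seg_of <- function(x) findInterval(x, segments$onset_s)
  inside <- inside & seg_of(cycles$insp_onset_s) ==
    seg_of(pmax(cycles$next_insp_onset_s - 1e-9, cycles$insp_onset_s))
  use <- cycles[inside, , drop = FALSE]

  acc <- matrix(0, nb, length(scal$freq_hz))
  n_used <- 0L
  for (i in seq_len(nrow(use))) {
    i0 <- use$insp_onset_s[i]; e0 <- use$exp_onset_s[i]
    i1 <- use$next_insp_onset_s[i]
    si <- which(t >= i0 & t < e0)
    se <- which(t >= e0 & t < i1)
    if (length(si) < 2L || length(se) < 2L) next
    p <- c(insp_fraction * (t[si] - i0) / (e0 - i0),
           insp_fraction + (1 - insp_fraction) * (t[se] - e0) / (i1 - e0))
    rows <- c(si, se)
    # linear interpolation of each frequency column onto the bin centres,
    # constant extrapolation at the phase extremes
    idx <- findInterval(centers, p)
    idx <- pmin(pmax(idx, 1L), length(p) - 1L)
    w <- (centers - p[idx]) / (p[idx + 1L] - p[idx])
    w <- pmin(pmax(w, 0), 1)
    acc <- acc + (1 - w) * pow[rows[idx], , drop = FALSE] +
      w * pow[rows[idx + 1L], , drop = FALSE]
    n_used <- n_used + 1L
  }
  if (n_used == 0L)
    stop_typed("fearresp_no_data", "no usable cycles inside segments")
  structure(list(phase = centers, freq_hz = scal$freq_hz,
                 power = acc / n_used, n_cycles = n_used,
                 insp_fraction = insp_fraction),
            class = "cycle_scalogram")
}

#' Maximum band power across the normalized respiratory cycle
#'
#' At each of the 40 phase bins, the maximum of the cycle-averaged power
#' over the band's frequency rows — the curve used to read off at which
#' respiratory phase beta or gamma power peaks.
#'
#' @param cyc a [cycle_frequency_scalogram()].
#' @param band `c(lo, hi)` in Hz (half-open), or a band name from
#'   [lfp_bands()].
#' @return list of class `band_phase_curve`: `band`, `phase`, `value`
#'   (length 40), `peak_phase` (bin centre of the maximum).
#' @export
band_max_power_curve <- function(cyc, band) {
  if (is.character(band)) {
    nm <- band
    band <- lfp_bands()[[band]]
    assert_that(!is.null(band), "unknown band name %s", nm)
  } else nm <- sprintf("%g-%g Hz", band[1], band[2])
  sel <- cyc$freq_hz >= band[1] & cyc$freq_hz < band[2]
  assert_that(any(sel), "band contains no scalogram frequencies")
  value <- apply(cyc$power[, sel, drop = FALSE], 1L, max)
  structure(list(band = nm, phase = cyc$phase, value = value,
                 peak_phase = cyc$phase[which.max(value)]),
            class = "band_phase_curve")
}

#' @export
print.cycle_scalogram <- function(x, ...) {
  cat(sprintf("<cycle_scalogram> %d phase bins x %d freqs, %d cycles\n",
              length(x$phase), length(x$freq_hz), x$n_cycles))
  invisible(x)
}

#' @export
print.band_phase_curve <- function(x, ...) {
  cat(sprintf("<band_phase_curve> %s, peak at phase %.3f\n",
              x$band, x$peak_phase))
  invisible(x)
}
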