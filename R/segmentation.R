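#' Intersect USV blocks with behaviour bouts into the four categories
#'
#' The USV mask is the union of block bounding intervals (sub-second gaps
#' inside a block count as USV time); its complement within the analysis
#' window is silent.  Every maximal interval with a constant
#' (vocal state, behaviour) pair becomes a candidate segment labelled
#' `silent_freezing`, `usv_freezing`, `silent_escape` or `usv_escape`;
#' candidates shorter than `min_len_s` are dropped ("longer than 1 s" is
#' read boundary-inclusive, so exactly 1.0-s segments are retained).
#' Dropped time is excluded from downstream averages, not reassigned.
#'
#' @param blocks USV blocks ([group_blocks()]); may be empty.
#' @param bouts behaviour bouts ([score_freezing()]); must tile `window`.
#' @param window `c(t0, t1)` analysis window, seconds.
#' @param min_len_s minimal retained segment length.
#' @return data.frame of class `category_segments`: `label`, `onset_s`,
#'   `offset_s`, plus attribute `dropped_s` (total candidate time removed
#'   by the length filter).
#' @export
intersect_categories <- function(blocks, bouts, window, min_len_s = 1.0) {
  check_intervals(bouts, "bouts")
  assert_that(nrow(bouts) > 0, "bouts must tile the window")
  tol <- 1e-6
  covers <- abs(bouts$onset_s[1L] - window[1]) < tol &&
    abs(bouts$offset_s[nrow(bouts)] - window[2]) < tol &&
    all(abs(bouts$onset_s[-1L] - bouts$offset_s[-nrow(bouts)]) < tol)
  assert_that(covers, "behaviour bouts must tile the analysis window")

  edges <- sort(unique(c(window,
                         pmax(pmin(c(blocks$onset_s, blocks$offset_s,
                                     bouts$onset_s, bouts$offset_s),
                                   window[2]), window[1]))))
  lo <- edges[-length(edges)]
  hi <- edges[-1L]
  keep <- hi - lo > tol
  lo <- lo[keep]; hi <- hi[keep]
  mid <- (lo + hi) / 2

  usv <- points_in_intervals(mid, blocks$onset_s, blocks$offset_s)
  b_idx <- findInterval(mid, bouts$onset_s)
  behav <- bouts$label[pmax(b_idx, 1L)]
  label <- paste0(ifelse(usv, "usv_", "silent_"), behav)

  merged <- merge_adjacent(lo, hi, label)
  long <- merged$offset_s - merged$onset_s >= min_len_s - 1e-9
  dropped <- sum((merged$offset_s - merged$onset_s)[!long])
  out <- merged[long, c("label", "onset_s", "offset_s")]
  rownames(out) <- NULL
  attr(out, "dropped_s") <- dropped
  class(out) <- c("category_segments", "data.frame")
  out
}

#' Screen LFP trials for saturation and signal-loss artifacts
#'
#' Artifact samples are those at or beyond full scale (saturation) or
#' inside a constant run at least `flat_run_s` long (transient signal
#' loss).  A trial is kept when its artifact time within the 60-s window
#' is at most `max_artifact_s`; a recording site is kept when no more
#' than `max_excluded` of its trials are excluded.
#'
#' @param trace LFP trace covering all windows.
#' @param rate sampling rate, Hz.
#' @param windows data.frame of trial windows (`onset_s`, `offset_s`),
#'   typically 10 x 60-s post-shock intervals.
#' @param full_scale saturation amplitude; default 1.05 x the 99.9th
#'   percentile of `abs(trace)` (an automated proxy for the amplifier's
#'   rail, which visual screening would identify directly).
#' @param flat_run_s minimal duration of a constant run to count as loss.
#' @param max_artifact_s per-trial artifact budget (5 s).
#' @param max_excluded site-level budget of excluded trials (5 of 10).
#' @return list of class `trial_screen`: `trials` (data.frame with
#'   `onset_s`, `offset_s`, `artifact_s`, `kept`), `n_excluded`,
#'   `site_kept`.
#' @export
screen_artifacts <- function(trace, rate, windows, full_scale = NULL,
                             flat_run_s = 0.5, max_artifact_s = 5,
                             max_excluded = 5L) {
  check_intervals(windows, "windows")
  if (is.null(full_scale))
    full_scale <- 1.05 * stats::quantile(abs(trace), 0.999, names = FALSE)
  n <- length(trace)
  bad <- abs(trace) >= full_scale

  r <- rle(c(diff(trace) == 0, FALSE))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  flat <- r$values & r$lengths + 1L >= flat_run_s * rate
  for (j in which(flat)) bad[starts[j]:min(ends[j] + 1L, n)] <- TRUE

  t <- (seq_len(n) - 1L) / rate
  art <- vapply(seq_len(nrow(windows)), function(i) {
    sel <- t >= windows$onset_s[i] & t < windows$offset_s[i]
    sum(bad[sel]) / rate
  }, numeric(1))
  trials <- data.frame(onset_s = windows$onset_s, offset_s = windows$offset_s,
                       artifact_s = art, kept = art <= max_artifact_s)
  n_excluded <- sum(!trials$kept)
  structure(list(trials = trials, n_excluded = n_excluded,
                 site_kept = n_excluded <= max_excluded,
                 full_scale = full_scale),
            class = "trial_screen")
}

#' @export
print.trial_screen <- function(x, ...) {
  cat(sprintf("<trial_screen> %d/%d trials kept; site %s\n",
              sum(x$trials$kept), nrow(x$trials),
              if (x$site_kept) "kept" else "excluded"))
  invisible(x)
}
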