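#' Motion trace from frame differencing
#'
#' For every pair of consecutive frames the absolute difference image is
#' binarized at a gray-level threshold; pixels above threshold are
#' "white", the rest "black", and the white-pixel count per 40-ms bin is
#' the motion trace.  When `gray_threshold` is `NULL` it is calibrated as
#' three times a robust estimate (`mad`) of the difference-image pixel
#' spread, which tracks the sensor-noise floor because moving-object
#' pixels are a small minority.
#'
#' @param frames array `h x w x n` of grayscale frames in `[0, 1]`, or a
#'   `simulate_video()` result.
#' @param rate frame rate, Hz (taken from the video object if supplied).
#'   Rates other than 25 Hz are rebinned to 40-ms bins.
#' @param gray_threshold binarization threshold, or `NULL` to calibrate.
#' @return data.frame of class `motion_trace`: `onset_s`, `offset_s`
#'   (40-ms bins) and `count` (white pixels).
#' @export
frame_motion <- function(frames, rate = 25, gray_threshold = NULL) {
  if (is.list(frames) && !is.null(frames$frames)) {
    rate <- frames$rate
    frames <- frames$frames
  }
  d <- dim(frames)
  assert_that(length(d) == 3L && d[3L] >= 2L,
              "need an h x w x n array with at least two frames")
  n <- d[3L]
  diffs <- frames[, , -1L, drop = FALSE] - frames[, , -n, drop = FALSE]
  # calibrate on the signed differences: their robust spread tracks the
  # sensor-noise floor (moving-object pixels are a small minority)
  if (is.null(gray_threshold)) gray_threshold <- 3 * stats::mad(diffs)
  counts <- apply(abs(diffs) > gray_threshold, 3L, sum)

  onset <- (seq_len(n - 1L) - 1L) / rate
  if (abs(rate - 25) > 1e-9) {       # rebin to the canonical 40-ms grid
    bin <- floor(onset / 0.04)
    counts <- as.numeric(tapply(counts, bin, sum))
    onset <- sort(unique(bin)) * 0.04
  }
  structure(data.frame(onset_s = onset, offset_s = onset + 0.04,
                       count = counts),
            class = c("motion_trace", "data.frame"))
}

#' Score freezing from a motion trace
#'
#' Freezing is the absence of any white pixel: maximal runs of zero-count
#' bins become freezing candidates; candidates shorter than
#' `min_episode_s` are absorbed into the surrounding non-freezing state,
#' and all remaining time is labelled escape — in the post-shock window
#' the animal is either freezing or escaping.  The output bouts tile the
#' analyzed window.
#'
#' @param motion a [frame_motion()] trace (or any data.frame with
#'   `onset_s`, `offset_s`, `count`).
#' @param min_episode_s minimal stable-freezing duration (1 s).
#' @return data.frame of class `behavior_bouts`: `label`
#'   (`"freezing"`/`"escape"`), `onset_s`, `offset_s`.
#' @export
score_freezing <- function(motion, min_episode_s = 1.0) {
  assert_that(nrow(motion) > 0, "motion trace is empty")
  frozen <- motion$count == 0
  r <- rle(frozen)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  onset <- motion$onset_s[starts]
  offset <- motion$offset_s[ends]
  label <- ifelse(r$values & (offset - onset >= min_episode_s - 1e-9),
                  "freezing", "escape")
  out <- merge_adjacent(onset, offset, label)
  out <- out[, c("label", "onset_s", "offset_s")]
  class(out) <- c("behavior_bouts", "data.frame")
  out
}
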