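# Internal helpers shared across modules.  All event times are seconds from
# session start; intervals are half-open [onset, offset).

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_typed <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(class = c(class, "fearresp_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_typed("fearresp_invalid_input", fmt, ...)
  invisible(TRUE)
}

# total overlap (seconds) of [a0,a1) with a set of intervals given as a
# two-column matrix/data.frame of onsets/offsets
interval_overlap_s <- function(a0, a1, onsets, offsets) {
  if (length(onsets) == 0L) return(0)
  sum(pmax(0, pmin(a1, offsets) - pmax(a0, onsets)))
}

# TRUE for points t that fall inside any half-open [onset, offset)
points_in_intervals <- function(t, onsets, offsets) {
  if (length(onsets) == 0L) return(rep(FALSE, length(t)))
  idx <- findInterval(t, onsets)
  idx > 0L & t < offsets[pmax(idx, 1L)]
}

# intervals as data.frame(onset_s, offset_s[, label]); validate ordering
check_intervals <- function(x, what = "interval table") {
  assert_that(all(c("onset_s", "offset_s") %in% names(x)),
              "%s must have onset_s and offset_s columns", what)
  assert_that(all(x$offset_s > x$onset_s), "%s has empty/negative intervals",
              what)
  if (nrow(x) > 1L) {
    assert_that(all(diff(x$onset_s) >= 0), "%s must be time-ordered", what)
    assert_that(all(x$onset_s[-1L] >= x$offset_s[-nrow(x)] - 1e-9),
                "%s has overlapping intervals", what)
  }
  invisible(x)
}

empty_events <- function(extra = character()) {
  cols <- c("onset_s", "offset_s", extra)
  out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  out
}
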