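# Independent brute-force oracles used to cross-check the implementation.

# O(n^2)-style block grouping: merge time-adjacent blocks while any gap is
# below the threshold; independent of the greedy left-to-right scan.
oracle_group_blocks <- function(calls, max_gap_s = 1.0) {
  if (nrow(calls) == 0L) return(data.frame(onset_s = numeric(0),
                                           offset_s = numeric(0)))
  calls <- calls[order(calls$onset_s), , drop = FALSE]
  blocks <- data.frame(onset_s = calls$onset_s, offset_s = calls$offset_s)
  repeat {
    if (nrow(blocks) < 2L) break
    gaps <- blocks$onset_s[-1L] - blocks$offset_s[-nrow(blocks)]
    j <- which(gaps < max_gap_s)
    if (length(j) == 0L) break
    j <- j[1L]
    blocks$offset_s[j] <- max(blocks$offset_s[j], blocks$offset_s[j + 1L])
    blocks <- blocks[-(j + 1L), , drop = FALSE]
  }
  rownames(blocks) <- NULL
  blocks
}

# dense millisecond labelling oracle for category segmentation
oracle_intersect <- function(blocks, bouts, window, min_len_s = 1.0,
                             dt = 0.001) {
  t <- seq(window[1] + dt / 2, window[2] - dt / 2, by = dt)
  usv <- rep(FALSE, length(t))
  for (i in seq_len(nrow(blocks)))
    usv[t >= blocks$onset_s[i] & t < blocks$offset_s[i]] <- TRUE
  behav <- rep(NA_character_, length(t))
  for (i in seq_len(nrow(bouts)))
    behav[t >= bouts$onset_s[i] & t < bouts$offset_s[i]] <- bouts$label[i]
  lab <- paste0(ifelse(usv, "usv_", "silent_"), behav)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(label = r$values,
                    onset_s = window[1] + (starts - 1L) * dt,
                    offset_s = window[1] + ends * dt)
  out[out$offset_s - out$onset_s >= min_len_s - dt / 2, , drop = FALSE]
}

# explicit run-length scan for freezing scoring
oracle_score_freezing <- function(motion, min_episode_s = 1.0) {
  n <- nrow(motion)
  lab <- character(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && (motion$count[j + 1L] == 0) == (motion$count[i] == 0))
      j <- j + 1L
    dur <- motion$offset_s[j] - motion$onset_s[i]
    lab[i:j] <- if (motion$count[i] == 0 && dur >= min_episode_s - 1e-9)
      "freezing" else "escape"
    i <- j + 1L
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(label = r$values, onset_s = motion$onset_s[starts],
             offset_s = motion$offset_s[ends])
}

# random call tables for property tests
random_calls <- function(n, t_max = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  onset <- sort(runif(n, 0, t_max))
  dur <- runif(n, 0.02, 0.8)
  offset <- pmin(onset + dur, c(onset[-1L] - 1e-3, t_max + 1))
  data.frame(onset_s = onset, offset_s = pmax(offset, onset + 1e-4))
}

four_state_schedule <- function(d = c(20, 20, 10, 10)) {
  data.frame(state = c("silent_freezing", "usv_freezing",
                       "silent_escape", "usv_escape"),
             duration_s = d)
}
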