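# Session-directory format: single-column CSV traces (rates in the
# manifest), CSV event tables, plain-text key-value manifest/config.
# All times are seconds from session start on one synchronized clock;
# intervals are half-open [onset, offset).

write_kv <- function(x, path) {
  writeLines(paste0(names(x), ": ", vapply(x, as.character, "")), path)
}

read_kv <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexpr(": ", lines), invert = TRUE)
  stats::setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, "", 1L))
}

clip_intervals <- function(df, window) {
  if (nrow(df) == 0L) return(df)
  out <- df
  out$onset_s <- pmax(df$onset_s, window[1])
  out$offset_s <- pmin(df$offset_s, window[2])
  out <- out[out$offset_s - out$onset_s > 1e-9, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a simulated session to a session directory
#'
#' Persists the respiration and LFP traces as single-column CSV, the
#' motion trace (white-pixel counts) derived from the video, the call
#' table (raw ultrasonic audio is regenerable from the config and is not
#' stored), the ground-truth event tables, the trial windows, and a
#' plain-text manifest carrying the sampling rates.
#'
#' @param session a [simulate_session()] result.
#' @param dir output directory (created if needed).
#' @param windows trial windows data.frame (`onset_s`, `offset_s`);
#'   default one window spanning the session.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, windows = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- session$config
  if (is.null(windows))
    windows <- data.frame(onset_s = 0, offset_s = cfg$duration_s)
  check_intervals(windows, "trial windows")

  p <- function(f) file.path(dir, f)
  utils::write.csv(data.frame(value = session$resp$waveform), p("resp.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(value = session$lfp$lfp), p("lfp.csv"),
                   row.names = FALSE)
  motion <- if (!is.null(session$video)) frame_motion(session$video) else NULL
  if (!is.null(motion))
    utils::write.csv(motion, p("motion.csv"), row.names = FALSE)
  utils::write.csv(session$usv$calls, p("calls.csv"), row.names = FALSE)
  utils::write.csv(windows, p("trials.csv"), row.names = FALSE)
  for (nm in c("cycles", "calls", "bouts", "segments"))
    utils::write.csv(session$truth[[nm]], p(sprintf("truth_%s.csv", nm)),
                     row.names = FALSE)

  write_kv(list(session_id = sprintf("synthetic-seed%d", cfg$seed),
                duration_s = cfg$duration_s,
                resp_rate = cfg$resp_rate, lfp_rate = cfg$lfp_rate,
                video_frame_rate = cfg$video_frame_rate,
                resp_file = "resp.csv", lfp_file = "lfp.csv",
                motion_file = if (is.null(motion)) "" else "motion.csv",
                calls_file = "calls.csv", trials_file = "trials.csv",
                seed = cfg$seed),
           p("manifest.txt"))
  write_kv(list(duration_s = cfg$duration_s, seed = cfg$seed,
                states = paste(cfg$state_schedule$state, collapse = ","),
                state_durations = paste(cfg$state_schedule$duration_s,
                                        collapse = ",")),
           p("config.txt"))
  invisible(dir)
}

#' Read a session directory
#'
#' Parses and validates the manifest, checks that every referenced file
#' exists, and loads the traces and event tables.  Violations raise
#' typed errors naming the offending field.
#'
#' @param dir session directory written by [write_session()].
#' @return list of class `session_data`: `manifest`, `resp` (waveform +
#'   rate), `lfp`, `motion` (or NULL), `calls`, `windows`, and any
#'   `truth_*` tables present.
#' @export
read_session <- function(dir) {
  mpath <- file.path(dir, "manifest.txt")
  if (!file.exists(mpath))
    stop_typed("fearresp_missing_file", "manifest file not found in %s", dir)
  man <- read_kv(mpath)
  for (field in c("resp_file", "lfp_file", "calls_file", "trials_file")) {
    f <- man[[field]]
    if (is.null(f) || !nzchar(f) || !file.exists(file.path(dir, f)))
      stop_typed("fearresp_missing_file",
                 "manifest field %s references a missing file", field)
  }
  rates <- as.numeric(c(man$resp_rate, man$lfp_rate))
  if (any(is.na(rates)) || any(rates <= 0))
    stop_typed("fearresp_bad_manifest", "sampling rates must be positive")

  windows <- utils::read.csv(file.path(dir, man$trials_file))
  ok <- nrow(windows) > 0 && all(windows$offset_s > windows$onset_s) &&
    (nrow(windows) < 2 ||
       all(windows$onset_s[-1L] >= windows$offset_s[-nrow(windows)] - 1e-9))
  if (!isTRUE(ok))
    stop_typed("fearresp_bad_manifest",
               "trial windows must be non-empty and disjoint")

  out <- list(
    manifest = man,
    resp = list(waveform = utils::read.csv(file.path(dir, man$resp_file))$value,
                rate = as.numeric(man$resp_rate)),
    lfp = list(lfp = utils::read.csv(file.path(dir, man$lfp_file))$value,
               rate = as.numeric(man$lfp_rate)),
    motion = if (nzchar(man$motion_file %||% ""))
      utils::read.csv(file.path(dir, man$motion_file)) else NULL,
    calls = utils::read.csv(file.path(dir, man$calls_file)),
    windows = windows)
  for (nm in c("cycles", "calls", "bouts", "segments")) {
    f <- file.path(dir, sprintf("truth_%s.csv", nm))
    if (file.exists(f)) out[[paste0("truth_", nm)]] <- utils::read.csv(f)
  }
  class(out) <- "session_data"
  out
}

#' Run the full analysis pipeline on a session
#'
#' Executes the stages in dependency order: respiratory-cycle detection,
#' freezing scoring, call grouping into blocks, artifact screening,
#' per-window category segmentation, Morlet scalogram, per-category
#' spectra and band power, respiration-LFP frequency coupling, and
#' cycle-frequency scalograms with beta/gamma phase curves.  Given the
#' same inputs the pipeline is deterministic (no stage uses the RNG).
#'
#' @param session a `fear_session` (from [simulate_session()]), a
#'   `session_data` (from [read_session()]), or a session directory path.
#' @param out_dir optional directory; when given, all result tables are
#'   written as CSV together with a plain-text run log.
#' @param windows trial windows; defaults to the session's own windows
#'   (or one window spanning a simulated session).
#' @param f_max upper scalogram frequency, Hz.
#' @param screen_args named list of overrides passed to
#'   [screen_artifacts()] (e.g. `full_scale`, `max_excluded`).
#' @return list of class `fear_results` with elements `cycles`, `bouts`,
#'   `calls`, `blocks`, `segments`, `screen`, `psd`, `band_power`,
#'   `coupling` (per-category histogram + index), `cycle_scalograms`
#'   (per category, with beta/gamma curves), `windows`.
#' @export
run_pipeline <- function(session, out_dir = NULL, windows = NULL,
                         f_max = 80, screen_args = list()) {
  if (is.character(session)) session <- read_session(session)
  if (inherits(session, "fear_session")) {
    resp <- session$resp$waveform; resp_rate <- session$resp$rate
    lfp <- session$lfp$lfp; lfp_rate <- session$lfp$rate
    motion <- if (!is.null(session$video)) frame_motion(session$video)
    calls <- session$usv$calls
    dur <- session$config$duration_s
  } else {
    resp <- session$resp$waveform; resp_rate <- session$resp$rate
    lfp <- session$lfp$lfp; lfp_rate <- session$lfp$rate
    motion <- session$motion
    calls <- session$calls
    dur <- length(lfp) / lfp_rate
    windows <- windows %||% session$windows
  }
  if (is.null(windows)) windows <- data.frame(onset_s = 0, offset_s = dur)

  cycles <- detect_cycles(resp, resp_rate)
  bouts <- if (!is.null(motion)) {
    score_freezing(motion)
  } else if (inherits(session, "fear_session")) {
    session$truth$bouts          # no video simulated: use schedule truth
  } else if (!is.null(session$truth_bouts)) {
    session$truth_bouts
  } else {
    data.frame(label = "freezing", onset_s = 0, offset_s = dur)
  }
  blocks <- group_blocks(calls)
  screen <- do.call(screen_artifacts,
                    c(list(lfp, lfp_rate, windows), screen_args))

  segments <- do.call(rbind, lapply(seq_len(nrow(windows)), function(i) {
    win <- c(windows$onset_s[i], windows$offset_s[i])
    b <- clip_intervals(bouts, win)
    if (nrow(b) > 0) {            # re-anchor clipped bouts to the window
      b$onset_s[1L] <- win[1]; b$offset_s[nrow(b)] <- win[2]
    }
    seg <- intersect_categories(clip_intervals(blocks, win), b, win)
    seg$trial <- i
    seg
  }))

  results <- list(cycles = cycles, bouts = bouts, calls = calls,
                  blocks = blocks, segments = segments, screen = screen,
                  windows = windows)

  if (screen$site_kept) {
    scal <- morlet_scalogram(lfp, lfp_rate, f_max = f_max)
    psd <- category_psd(scal, segments)
    results$psd <- psd
    results$band_power <- band_power(psd)

    resp_if <- instantaneous_frequency(cycles, t_range = c(0, dur))
    scal_lo <- morlet_scalogram(lfp, lfp_rate, f_max = 15, step_s = 0.004)
    dom <- dominant_lfp_frequency(scal_lo)
    results$coupling <- lapply(split(segments, segments$label), function(seg) {
      h <- tryCatch(coupling_histogram(resp_if, dom, seg),
                    fearresp_no_data = function(e) NULL)
      if (is.null(h)) return(NULL)
      list(histogram = h, index = diagonal_coupling_index(h))
    })

    results$cycle_scalograms <- lapply(split(segments, segments$label),
                                       function(seg) {
      cs <- tryCatch(cycle_frequency_scalogram(scal, cycles, seg),
                     fearresp_no_data = function(e) NULL)
      if (is.null(cs)) return(NULL)
      list(map = cs, beta = band_max_power_curve(cs, "beta"),
           gamma = band_max_power_curve(cs, "gamma"))
    })
  }
  class(results) <- "fear_results"

  if (!is.null(out_dir)) write_results(results, out_dir)
  results
}

write_results <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  utils::write.csv(results$cycles, p("cycles.csv"), row.names = FALSE)
  utils::write.csv(results$bouts, p("bouts.csv"), row.names = FALSE)
  utils::write.csv(results$calls, p("calls.csv"), row.names = FALSE)
  utils::write.csv(results$blocks, p("blocks.csv"), row.names = FALSE)
  utils::write.csv(results$segments, p("segments.csv"), row.names = FALSE)
  utils::write.csv(results$screen$trials, p("screen.csv"), row.names = FALSE)
  log <- c(sprintf("site_kept: %s", results$screen$site_kept),
           sprintf("n_cycles: %d", nrow(results$cycles)),
           sprintf("n_calls: %d", nrow(results$calls)),
           sprintf("n_blocks: %d", nrow(results$blocks)),
           sprintf("n_segments: %d", nrow(results$segments)))
  if (!is.null(results$band_power)) {
    utils::write.csv(results$band_power, p("band_power.csv"),
                     row.names = FALSE)
    psd_df <- data.frame(freq_hz = results$psd$freq_hz,
                         results$psd$amplitude, check.names = FALSE)
    utils::write.csv(psd_df, p("category_psd.csv"), row.names = FALSE)
    idx <- vapply(results$coupling, function(x)
      if (is.null(x)) NA_real_ else x$index, numeric(1))
    utils::write.csv(data.frame(category = names(idx), coupling_index = idx),
                     p("coupling_index.csv"), row.names = FALSE)
    for (cat in names(results$cycle_scalograms)) {
      cs <- results$cycle_scalograms[[cat]]
      if (is.null(cs)) next
      m <- data.frame(phase = cs$map$phase, cs$map$power, check.names = FALSE)
      names(m)[-1L] <- sprintf("f_%g", cs$map$freq_hz)
      utils::write.csv(m, p(sprintf("cycle_scalogram_%s.csv", cat)),
                       row.names = FALSE)
    }
    log <- c(log, sprintf("coupling_index_%s: %.4f", names(idx), idx))
  }
  writeLines(log, p("run_log.txt"))
  invisible(out_dir)
}
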