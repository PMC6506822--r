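#' Configuration for a synthetic fear-conditioning session
#'
#' Builds the parameter set consumed by [simulate_session()] and the
#' per-modality simulators.  Defaults encode the empirical regime the
#' simulator emulates: state-dependent respiratory rates (6.3 Hz during
#' silent escape, 2.8 Hz during silent freezing, slowing to 1.4 and 1 Hz
#' respectively when 22-kHz calls are emitted), a delta oscillation whose
#' frequency tracks the breathing rate during silent freezing only, theta
#' fixed near 6.5 Hz, beta/gamma amplitude modulated by respiratory-cycle
#' phase with state-dependent preferred phase, calls emitted during
#' expiration, and a bright-blob video that is stationary during freezing.
#'
#' @param duration_s session length in seconds.
#' @param seed integer RNG seed; a fixed seed makes every simulated
#'   modality bit-identical across runs (R's default Mersenne-Twister).
#' @param state_schedule data.frame with columns `state` (one of
#'   [fear_categories()]) and `duration_s`; durations must sum to
#'   `duration_s`.
#' @param resp_freq_by_state named numeric, breaths/s per state.
#' @param resp_jitter fractional SD of cycle durations (0 = metronomic).
#' @param resp_rate_walk_sd step SD of the AR(1) random walk on log
#'   breathing rate (coefficient 0.9), giving the slow waxing and waning
#'   of respiratory rate around the state nominal that real animals show
#'   (stationary SD about 9% of the rate); 0 disables the drift.
#' @param resp_noise_sd additive Gaussian noise SD on the pressure trace.
#' @param insp_fraction fraction of each cycle occupied by inspiration
#'   (template value 0.4).
#' @param resp_sign `"neg"` if inspiration is the negative-going limb of
#'   the pressure trace (plethysmograph convention), `"pos"` otherwise.
#' @param lfp_rate,resp_rate,audio_rate,video_frame_rate sampling rates, Hz.
#' @param delta_locked_states states in which the delta component's
#'   frequency equals the instantaneous respiratory frequency.
#' @param delta_free_freq delta frequency (Hz) in unlocked states.
#' @param theta_freq fixed theta frequency, Hz.
#' @param beta_carrier,gamma_carrier carrier frequencies (Hz) of the
#'   phase-modulated fast components.
#' @param band_amplitudes 4x4 numeric matrix, rows = bands
#'   (delta/theta/beta/gamma), columns = states: per-state amplitude of
#'   each injected component.
#' @param gamma_mod,beta_mod data.frame with columns `state`, `phase`
#'   (preferred normalized respiratory phase in `[0,1)`) and `depth`
#'   (modulation depth in `[0,1]`).
#' @param noise_exponent,noise_amp 1/f^a background: exponent and SD.
#' @param usv_call_model list with `carrier_hz`, `mean_dur_s`, `sd_dur_s`,
#'   `p_call` (probability a USV-state cycle carries a call; gaps between
#'   calls of successive cycles stay below 1 s, exercising block grouping)
#'   and `amp_range`.
#' @param audio_noise_sd microphone background noise SD.
#' @param frame_px square frame side, pixels.
#' @param blob_px blob side, pixels.
#' @param blob_speed_px_per_frame blob translation per frame during escape.
#' @param video_noise uniform sensor-noise half-width (bounded, so that
#'   freezing frames stay below any threshold above twice this value).
#'
#' @return An object of class `session_config` (a named list).
#' @export
#' @examples
#' cfg <- session_config(20, seed = 1, state_schedule = data.frame(
#'   state = c("silent_freezing", "usv_freezing"), duration_s = c(10, 10)))
session_config <- function(duration_s,
                           seed = 1L,
                           state_schedule = NULL,
                           resp_freq_by_state = c(silent_freezing = 2.8,
                                                  usv_freezing   = 1.0,
                                                  silent_escape  = 6.3,
                                                  usv_escape     = 1.4),
                           resp_jitter = 0.05,
                           resp_rate_walk_sd = 0.04,
                           resp_noise_sd = 0.02,
                           insp_fraction = 0.4,
                           resp_sign = c("neg", "pos"),
                           lfp_rate = 1000,
                           resp_rate = 1000,
                           audio_rate = 214285,
                           video_frame_rate = 25,
                           delta_locked_states = "silent_freezing",
                           delta_free_freq = 3.5,
                           theta_freq = 6.5,
                           beta_carrier = 25,
                           gamma_carrier = 55,
                           band_amplitudes = NULL,
                           gamma_mod = NULL,
                           beta_mod = NULL,
                           noise_exponent = 1,
                           noise_amp = 0.3,
                           usv_call_model = list(carrier_hz = 22000,
                                                 mean_dur_s = 0.4,
                                                 sd_dur_s = 0.08,
                                                 p_call = 0.9,
                                                 amp_range = c(0.7, 1)),
                           audio_noise_sd = 0.002,
                           frame_px = 64L,
                           blob_px = 8L,
                           blob_speed_px_per_frame = 3,
                           video_noise = 0.01) {
  resp_sign <- match.arg(resp_sign)
  if (is.null(state_schedule)) {
    state_schedule <- data.frame(state = "silent_freezing",
                                 duration_s = duration_s)
  }
  assert_that(duration_s > 0, "duration_s must be positive")
  assert_that(all(state_schedule$state %in% fear_categories()),
              "unknown state label in state_schedule")
  assert_that(abs(sum(state_schedule$duration_s) - duration_s) < 1e-6,
              "state_schedule durations must sum to duration_s")
  assert_that(all(c(lfp_rate, resp_rate, audio_rate, video_frame_rate) > 0),
              "all sampling rates must be positive")

  states <- fear_categories()
  if (is.null(band_amplitudes)) {
    # injected between-category contrasts: delta higher in freezing and under
    # USV; theta higher in escape, reduced under USV; beta and gamma raised
    # under USV, gamma higher in escape
    band_amplitudes <- rbind(
      delta = c(silent_freezing = 1.6, usv_freezing = 2.2,
                silent_escape = 0.7, usv_escape = 1.0),
      theta = c(0.9, 0.6, 1.6, 1.2),
      beta  = c(0.5, 0.9, 0.55, 0.8),
      gamma = c(0.6, 0.9, 0.85, 1.2))
    colnames(band_amplitudes) <- states
  }
  if (is.null(gamma_mod)) {
    # silent freezing: gamma maximal during inspiration; USV freezing: peak
    # in late expiration; escape: peak at the inspiration/expiration
    # transition, shifted into inspiration under USV
    gamma_mod <- data.frame(state = states,
                            phase = c(0.20, 0.85, 0.40, 0.20),
                            depth = c(0.80, 0.80, 0.60, 0.60))
  }
  if (is.null(beta_mod)) {
    beta_mod <- data.frame(state = states,
                           phase = c(0.15, 0.55, 0.40, 0.20),
                           depth = c(0.60, 0.60, 0.40, 0.40))
  }
  assert_that(all(gamma_mod$depth >= 0 & gamma_mod$depth <= 1) &&
                all(beta_mod$depth >= 0 & beta_mod$depth <= 1),
              "modulation depths must lie in [0, 1]")

  cfg <- list(duration_s = duration_s, seed = as.integer(seed),
              state_schedule = state_schedule,
              resp_freq_by_state = resp_freq_by_state,
              resp_jitter = resp_jitter,
              resp_rate_walk_sd = resp_rate_walk_sd,
              resp_noise_sd = resp_noise_sd,
              insp_fraction = insp_fraction, resp_sign = resp_sign,
              lfp_rate = lfp_rate, resp_rate = resp_rate,
              audio_rate = audio_rate, video_frame_rate = video_frame_rate,
              delta_locked_states = delta_locked_states,
              delta_free_freq = delta_free_freq, theta_freq = theta_freq,
              beta_carrier = beta_carrier, gamma_carrier = gamma_carrier,
              band_amplitudes = band_amplitudes,
              gamma_mod = gamma_mod, beta_mod = beta_mod,
              noise_exponent = noise_exponent, noise_amp = noise_amp,
              usv_call_model = usv_call_model,
              audio_noise_sd = audio_noise_sd,
              frame_px = as.integer(frame_px), blob_px = as.integer(blob_px),
              blob_speed_px_per_frame = blob_speed_px_per_frame,
              video_noise = video_noise)
  class(cfg) <- "session_config"
  cfg
}

# schedule as cumulative onsets/offsets
schedule_intervals <- function(config) {
  d <- config$state_schedule$duration_s
  data.frame(state = config$state_schedule$state,
             onset_s = cumsum(c(0, d[-length(d)])),
             offset_s = cumsum(d))
}

state_at <- function(t, config) {
  sch <- schedule_intervals(config)
  idx <- pmin(pmax(findInterval(t, sch$onset_s), 1L), nrow(sch))
  sch$state[idx]
}

#' Simulate the respiration trace of a session
#'
#' Generates a plethysmograph-like pressure trace as a concatenation of
#' non-sinusoidal cycles: each cycle is a negative half-cosine-shaped
#' inspiration limb occupying `insp_fraction` of the cycle followed by a
#' positive expiration limb (signs swapped for `resp_sign = "pos"`).
#' Cycle durations are drawn around the state's nominal rate with
#' fractional jitter.  The waveform is zero (hence continuous) at every
#' limb boundary.
#'
#' @param config a [session_config()].
#' @return list with `waveform` (numeric), `rate` (Hz) and `cycles`, a
#'   data.frame of ground-truth cycles (`insp_onset_s`, `exp_onset_s`,
#'   `next_insp_onset_s`, `duration_s`, `inst_freq_hz`, `state`).
#' @export
simulate_respiration <- function(config) {
  assert_that(inherits(config, "session_config"), "config required")
  assert_that(nrow(config$state_schedule) > 0 && config$duration_s > 0,
              "empty session: schedule has zero duration")
  set.seed(config$seed)
  sch <- schedule_intervals(config)
  dur <- config$duration_s
  insp_frac <- config$insp_fraction

  onsets <- numeric(0); durations <- numeric(0); states <- character(0)
  t <- 0
  lograte <- 0                      # AR(1) drift of log breathing rate
  for (k in seq_len(nrow(sch))) {
    f <- config$resp_freq_by_state[[sch$state[k]]]
    while (t < sch$offset_s[k] - 1e-9) {
      lograte <- 0.9 * lograte + config$resp_rate_walk_sd * stats::rnorm(1)
      fi <- f * exp(lograte)
      d <- (1 / fi) * (1 + config$resp_jitter * stats::rnorm(1))
      d <- min(max(d, 0.4 / f, 0.11), 2.5 / f)
      onsets <- c(onsets, t); durations <- c(durations, d)
      states <- c(states, sch$state[k])
      t <- t + d
    }
  }
  exp_onsets <- onsets + insp_frac * durations
  next_onsets <- onsets + durations
  complete <- next_onsets <= dur + 1e-6
  cycles <- data.frame(insp_onset_s = onsets[complete],
                       exp_onset_s = exp_onsets[complete],
                       next_insp_onset_s = next_onsets[complete],
                       duration_s = durations[complete],
                       inst_freq_hz = 1 / durations[complete],
                       state = states[complete])

  rate <- config$resp_rate
  n <- round(dur * rate)
  tt <- (seq_len(n) - 1L) / rate
  x <- numeric(n)
  sgn <- if (config$resp_sign == "neg") -1 else 1
  for (i in seq_along(onsets)) {
    i0 <- onsets[i]; e0 <- exp_onsets[i]; i1 <- next_onsets[i]
    sel <- tt >= i0 & tt < min(e0, dur)
    x[sel] <- sgn * sin(pi * (tt[sel] - i0) / (e0 - i0))
    sel <- tt >= e0 & tt < min(i1, dur)
    x[sel] <- -sgn * 0.7 * sin(pi * (tt[sel] - e0) / (i1 - e0))
  }
  x <- x + config$resp_noise_sd * stats::rnorm(n)
  list(waveform = x, rate = rate, cycles = cycles)
}

# 1/f^a noise via spectral shaping, unit then rescaled SD
one_over_f_noise <- function(n, exponent, sd_out) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  k <- c(0, seq_len(n - 1L))
  f <- pmin(k, n - k)            # symmetric frequency index
  scale <- ifelse(f == 0, 0, f^(-exponent / 2))
  x <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  if (stats::sd(x) > 0) x <- x * sd_out / stats::sd(x)
  x
}

# per-sample normalized respiratory phase (insp -> [0, frac), exp -> [frac,1))
# and instantaneous respiratory frequency; NA outside detected/true cycles
cycle_phase_at <- function(t, cycles, insp_fraction = 0.4) {
  phase <- rep(NA_real_, length(t))
  freq <- rep(NA_real_, length(t))
  if (nrow(cycles) == 0L) return(list(phase = phase, freq = freq))
  idx <- findInterval(t, cycles$insp_onset_s)
  ok <- idx > 0L & t < cycles$next_insp_onset_s[pmax(idx, 1L)]
  i <- idx[ok]
  ti <- t[ok]
  insp <- cycles$insp_onset_s[i]; expo <- cycles$exp_onset_s[i]
  nxt <- cycles$next_insp_onset_s[i]
  p <- ifelse(ti < expo,
              insp_fraction * (ti - insp) / (expo - insp),
              insp_fraction + (1 - insp_fraction) * (ti - expo) / (nxt - expo))
  phase[ok] <- p
  freq[ok] <- cycles$inst_freq_hz[i]
  list(phase = phase, freq = freq)
}

#' Simulate an LFP trace with respiration-locked structure
#'
#' The trace is a sum of (i) a delta component whose instantaneous
#' frequency equals the respiratory frequency in `delta_locked_states`
#' and is fixed at `delta_free_freq` elsewhere, (ii) theta at
#' `theta_freq`, (iii) beta and gamma carriers whose instantaneous
#' amplitude follows `1 - depth + depth * (1 + cos(2*pi*(phase -
#' preferred)))/2` on the normalized respiratory phase, and (iv) 1/f^a
#' background noise.  Per-state band amplitudes from
#' `config$band_amplitudes` scale each component.
#'
#' @param config a [session_config()].
#' @param resp_truth ground-truth cycle table from
#'   [simulate_respiration()] (the `cycles` element).
#' @return list with `lfp` (numeric trace), `rate`, and `injected`
#'   (the modulation tables and amplitude matrix actually used).
#' @export
simulate_lfp <- function(config, resp_truth) {
  assert_that(inherits(config, "session_config"), "config required")
  assert_that(nrow(resp_truth) > 0, "respiration truth must cover session")
  assert_that(all(config$state_schedule$state %in% fear_categories()),
              "unknown state label")
  set.seed(config$seed + 1L)
  rate <- config$lfp_rate
  n <- round(config$duration_s * rate)
  t <- (seq_len(n) - 1L) / rate
  st <- state_at(t, config)
  ph <- cycle_phase_at(t, resp_truth, config$insp_fraction)
  f_resp <- ph$freq
  f_resp[is.na(f_resp)] <- config$resp_freq_by_state[st[is.na(f_resp)]]

  amp <- config$band_amplitudes
  a_delta <- amp["delta", st]; a_theta <- amp["theta", st]
  a_beta <- amp["beta", st]; a_gamma <- amp["gamma", st]

  locked <- st %in% config$delta_locked_states
  f_delta <- ifelse(locked, f_resp, config$delta_free_freq)
  delta <- a_delta * sin(2 * pi * cumsum(f_delta) / rate)
  theta <- a_theta * sin(2 * pi * config$theta_freq * t)

  env_from <- function(mod_tab) {
    pref <- stats::setNames(mod_tab$phase, mod_tab$state)[st]
    depth <- stats::setNames(mod_tab$depth, mod_tab$state)[st]
    p <- ph$phase
    env <- 1 - depth + depth * (1 + cos(2 * pi * (p - pref))) / 2
    env[is.na(p)] <- 1
    # unit-RMS normalization so band power tracks the configured amplitude
    # squared regardless of modulation depth (E[env^2] = 1 - d + 0.375 d^2)
    env / sqrt(1 - depth + 0.375 * depth^2)
  }
  beta <- a_beta * env_from(config$beta_mod) *
    sin(2 * pi * config$beta_carrier * t)
  gamma <- a_gamma * env_from(config$gamma_mod) *
    sin(2 * pi * config$gamma_carrier * t)

  noise <- one_over_f_noise(n, config$noise_exponent, config$noise_amp)
  list(lfp = delta + theta + beta + gamma + noise, rate = rate,
       injected = list(band_amplitudes = amp, gamma_mod = config$gamma_mod,
                       beta_mod = config$beta_mod))
}

#' Simulate ultrasonic audio with 22-kHz calls during expiration
#'
#' Places constant-carrier tone bursts inside the expiration phase of
#' cycles belonging to USV states.  Each USV-state cycle carries a call
#' with probability `p_call`; onsets sit shortly after expiration onset
#' and durations are truncated to fit the expiration limb, so every true
#' call interval is contained in a true expiration interval by
#' construction.
#'
#' @param config a [session_config()].
#' @param resp_truth ground-truth cycle table.
#' @param make_audio if `FALSE`, only the call table is returned
#'   (`audio = NULL`); useful when only event-level truth is needed.
#' @return list with `audio` (numeric at `config$audio_rate`, or NULL),
#'   `rate`, and `calls` (data.frame `onset_s`, `offset_s`, `duration_s`,
#'   `amp`, `state`).
#' @export
simulate_usv_audio <- function(config, resp_truth, make_audio = TRUE) {
  assert_that(inherits(config, "session_config"), "config required")
  m <- config$usv_call_model
  assert_that(config$audio_rate > 2 * m$carrier_hz,
              "audio_rate must exceed twice the call carrier (aliasing)")
  set.seed(config$seed + 2L)
  usv_cycles <- resp_truth[grepl("^usv_", resp_truth$state), , drop = FALSE]

  calls <- empty_events(c("duration_s", "amp", "state"))
  calls$state <- character(0)
  if (nrow(usv_cycles) > 0L) {
    keep <- stats::runif(nrow(usv_cycles)) < m$p_call
    cc <- usv_cycles[keep, , drop = FALSE]
    if (nrow(cc) > 0L) {
      exp_dur <- cc$next_insp_onset_s - cc$exp_onset_s
      onset <- cc$exp_onset_s + 0.08 * exp_dur
      dur <- stats::rnorm(nrow(cc), m$mean_dur_s, m$sd_dur_s)
      dur <- pmin(pmax(dur, 0.05), 0.85 * exp_dur)
      calls <- data.frame(onset_s = onset, offset_s = onset + dur,
                          duration_s = dur,
                          amp = stats::runif(nrow(cc), m$amp_range[1],
                                             m$amp_range[2]),
                          state = cc$state)
    }
  }

  audio <- NULL
  if (make_audio) {
    rate <- config$audio_rate
    n <- round(config$duration_s * rate)
    audio <- config$audio_noise_sd * stats::rnorm(n)
    ramp_n <- round(0.002 * rate)
    for (i in seq_len(nrow(calls))) {
      i0 <- round(calls$onset_s[i] * rate) + 1L
      i1 <- min(round(calls$offset_s[i] * rate), n)
      if (i1 <= i0) next
      idx <- i0:i1
      tt <- (idx - 1L) / rate
      env <- rep(1, length(idx))
      r <- min(ramp_n, floor(length(idx) / 2))
      if (r > 1) {
        ramp <- (1 - cos(pi * seq_len(r) / r)) / 2
        env[seq_len(r)] <- ramp
        env[length(idx) - r + seq_len(r)] <- rev(ramp)
      }
      audio[idx] <- audio[idx] + calls$amp[i] * env *
        sin(2 * pi * m$carrier_hz * tt + stats::runif(1, 0, 2 * pi))
    }
  }
  list(audio = audio, rate = config$audio_rate, calls = calls)
}

#' Simulate behaviour video as a moving bright blob
#'
#' A bright square blob on a dark background: stationary during freezing
#' states (only bounded uniform sensor noise), translating by
#' `blob_speed_px_per_frame` during escape states, wrapping around frame
#' edges.  Sensor noise is uniform with half-width `config$video_noise`,
#' hence strictly bounded: frame differences during freezing never exceed
#' twice that value.
#'
#' @param config a [session_config()].
#' @return list with `frames` (array `frame_px` x `frame_px` x n, values
#'   in `[0,1]`), `rate` (frames/s) and `times` (frame onset seconds).
#' @export
simulate_video <- function(config) {
  assert_that(inherits(config, "session_config"), "config required")
  assert_that(config$video_frame_rate >= 25,
              "frame rate must be at least 25 Hz (40-ms analysis bin)")
  set.seed(config$seed + 3L)
  fps <- config$video_frame_rate
  nf <- round(config$duration_s * fps)
  px <- config$frame_px; bp <- config$blob_px
  times <- (seq_len(nf) - 1L) / fps
  escape <- grepl("escape$", state_at(times, config))

  pos <- matrix(0, nf, 2)
  pos[1, ] <- c(px / 2, px / 2)
  ang <- stats::runif(1, 0, 2 * pi)
  for (i in seq_len(nf - 1L)) {
    ang <- ang + 0.3 * stats::rnorm(1)
    step <- if (escape[i + 1L]) config$blob_speed_px_per_frame else 0
    pos[i + 1L, ] <- (pos[i, ] + step * c(cos(ang), sin(ang))) %% px
  }

  frames <- array(0.05, dim = c(px, px, nf))
  half <- floor(bp / 2)
  for (i in seq_len(nf)) {
    rows <- ((round(pos[i, 1]) - half):(round(pos[i, 1]) + half - 1L)) %% px + 1L
    cols <- ((round(pos[i, 2]) - half):(round(pos[i, 2]) + half - 1L)) %% px + 1L
    frames[rows, cols, i] <- 0.8
  }
  noise <- array(stats::runif(px * px * nf, -config$video_noise,
                              config$video_noise), dim = dim(frames))
  frames <- pmin(pmax(frames + noise, 0), 1)
  list(frames = frames, rate = fps, times = times)
}

#' Simulate a complete multimodal session with ground truth
#'
#' Runs the four per-modality simulators under one seed and derives the
#' event-level ground truth: true respiratory cycles, true call table and
#' call blocks, true behaviour bouts (schedule states collapsed to
#' freezing/escape), and true category segments (blocks intersected with
#' bouts, segments shorter than 1 s dropped).
#'
#' @param config a [session_config()].
#' @param make_audio,make_video generate the raw audio / frame stack
#'   (memory-heavy); the call table and motion truth are produced either
#'   way.
#' @return An object of class `fear_session`: list with `config`, `resp`,
#'   `lfp`, `usv`, `video` (or NULL) and `truth` (cycles, calls, blocks,
#'   bouts, segments, injected modulation parameters).
#' @export
simulate_session <- function(config, make_audio = FALSE, make_video = TRUE) {
  resp <- simulate_respiration(config)
  lfp <- simulate_lfp(config, resp$cycles)
  usv <- simulate_usv_audio(config, resp$cycles, make_audio = make_audio)
  video <- if (make_video) simulate_video(config) else NULL

  sch <- schedule_intervals(config)
  sch$behavior <- ifelse(grepl("freezing$", sch$state), "freezing", "escape")
  bouts <- merge_adjacent(sch$onset_s, sch$offset_s, sch$behavior)
  names(bouts)[3] <- "label"

  blocks <- group_blocks(usv$calls)
  segments <- intersect_categories(blocks, bouts,
                                   window = c(0, config$duration_s))
  truth <- list(cycles = resp$cycles, calls = usv$calls, blocks = blocks,
                bouts = bouts, segments = segments,
                injected = lfp$injected)
  structure(list(config = config, resp = resp, lfp = lfp, usv = usv,
                 video = video, truth = truth),
            class = "fear_session")
}

# merge consecutive intervals sharing a label (intervals must tile)
merge_adjacent <- function(onsets, offsets, labels) {
  if (length(onsets) == 0L)
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      label = character(0)))
  grp <- cumsum(c(1L, as.integer(labels[-1L] != labels[-length(labels)])))
  data.frame(onset_s = tapply(onsets, grp, min),
             offset_s = tapply(offsets, grp, max),
             label = tapply(labels, grp, `[`, 1L),
             row.names = NULL)
}

#' @export
print.fear_session <- function(x, ...) {
  cat(sprintf("<fear_session> %.1f s, seed %d\n", x$config$duration_s,
              x$config$seed))
  cat(sprintf("  states: %s\n",
              paste(x$config$state_schedule$state, collapse = ", ")))
  cat(sprintf("  truth: %d cycles, %d calls, %d blocks, %d bouts, %d segments\n",
              nrow(x$truth$cycles), nrow(x$truth$calls), nrow(x$truth$blocks),
              nrow(x$truth$bouts), nrow(x$truth$segments)))
  invisible(x)
}
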