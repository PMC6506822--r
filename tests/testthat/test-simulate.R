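test_that("jitter-free single-state session yields metronomic cycles", {
  cfg <- session_config(10, seed = 7,
                        state_schedule = data.frame(state = "silent_escape",
                                                    duration_s = 10),
                        resp_jitter = 0, resp_rate_walk_sd = 0)
  r <- simulate_respiration(cfg)
  expect_equal(nrow(r$cycles), 63L)          # floor(10 * 6.3) complete cycles
  expect_equal(r$cycles$duration_s, rep(1 / 6.3, 63), tolerance = 1e-9)
  expect_equal(r$cycles$inst_freq_hz * r$cycles$duration_s, rep(1, 63))
})

test_that("a fixed seed reproduces every modality bit-identically", {
  cfg <- session_config(8, seed = 7, state_schedule = four_state_schedule(
    c(2, 2, 2, 2)))
  s1 <- simulate_session(cfg, make_video = TRUE)
  s2 <- simulate_session(cfg, make_video = TRUE)
  expect_identical(s1$resp$waveform, s2$resp$waveform)
  expect_identical(s1$lfp$lfp, s2$lfp$lfp)
  expect_identical(s1$usv$calls, s2$usv$calls)
  expect_identical(s1$video$frames, s2$video$frames)
})

test_that("generated cycle frequencies cluster at the configured state rate", {
  cfg <- session_config(60, seed = 2,
                        state_schedule = data.frame(state = "silent_freezing",
                                                    duration_s = 60),
                        resp_rate_walk_sd = 0)   # 5% jitter only
  r <- simulate_respiration(cfg)
  h <- hist(r$cycles$inst_freq_hz, breaks = seq(0, 12, by = 0.33),
            plot = FALSE)
  mode_hz <- h$mids[which.max(h$counts)]
  expect_lt(abs(mode_hz - 2.8), 0.33)
})

test_that("ground-truth intervals lie inside the session", {
  cfg <- session_config(30, seed = 4, state_schedule = four_state_schedule(
    c(10, 10, 5, 5)))
  s <- simulate_session(cfg, make_video = FALSE)
  for (tab in list(s$truth$cycles, s$truth$calls, s$truth$bouts,
                   s$truth$segments)) {
    if (nrow(tab) == 0) next
    t0 <- if ("insp_onset_s" %in% names(tab)) tab$insp_onset_s else tab$onset_s
    t1 <- if ("next_insp_onset_s" %in% names(tab)) tab$next_insp_onset_s else
      tab$offset_s
    expect_true(all(t0 >= 0) && all(t1 <= 30 + 1e-6))
  }
})

test_that("unmodulated gamma has a flat analytic envelope", {
  gm <- data.frame(state = fear_categories(), phase = 0.2, depth = 0)
  cfg <- session_config(20, seed = 3,
                        state_schedule = data.frame(state = "silent_freezing",
                                                    duration_s = 20),
                        gamma_mod = gm, beta_mod = gm, noise_amp = 0)
  s <- simulate_session(cfg, make_video = FALSE)
  scal <- morlet_scalogram(s$lfp$lfp, 1000, freqs = seq(40, 80, by = 2))
  env <- apply(scal$amp[scal$times_s > 2 & scal$times_s < 18, ], 1L, max)
  expect_lt(sd(env) / mean(env), 0.1)
})

test_that("delta-locked LFP spectrum peaks at the breathing rate", {
  cfg <- session_config(60, seed = 5,
                        state_schedule = data.frame(state = "silent_freezing",
                                                    duration_s = 60),
                        resp_jitter = 0, resp_rate_walk_sd = 0, noise_amp = 0)
  s <- simulate_session(cfg, make_video = FALSE)
  sp <- Mod(fft(s$lfp$lfp))^2
  f <- (seq_along(sp) - 1) / 60
  sel <- f > 0.2 & f < 5
  expect_lt(abs(f[sel][which.max(sp[sel])] - 2.8), 0.2)
})

test_that("gamma envelope peaks inside inspiration when so configured", {
  gm <- data.frame(state = fear_categories(), phase = 0.2, depth = 0.8)
  cfg <- session_config(40, seed = 6,
                        state_schedule = data.frame(state = "silent_freezing",
                                                    duration_s = 40),
                        gamma_mod = gm, noise_amp = 0)
  s <- simulate_session(cfg, make_video = FALSE)
  scal <- morlet_scalogram(s$lfp$lfp, 1000, freqs = seq(45, 65, by = 2.5))
  env <- apply(scal$amp, 1L, max)
  cyc <- s$truth$cycles
  cyc <- cyc[cyc$insp_onset_s > 2 & cyc$next_insp_onset_s < 38, ]
  hit <- vapply(seq_len(nrow(cyc)), function(i) {
    sel <- scal$times_s >= cyc$insp_onset_s[i] &
      scal$times_s < cyc$next_insp_onset_s[i]
    tmax <- scal$times_s[sel][which.max(env[sel])]
    tmax < cyc$exp_onset_s[i]                 # peak inside inspiration
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("every simulated call sits inside a true expiration interval", {
  cfg <- session_config(60, seed = 8,
                        state_schedule = data.frame(state = "usv_freezing",
                                                    duration_s = 60))
  r <- simulate_respiration(cfg)
  u <- simulate_usv_audio(cfg, r$cycles, make_audio = FALSE)
  expect_gt(nrow(u$calls), 10)
  cyc <- r$cycles
  inside <- vapply(seq_len(nrow(u$calls)), function(i) {
    any(u$calls$onset_s[i] >= cyc$exp_onset_s &
          u$calls$offset_s[i] <= cyc$next_insp_onset_s)
  }, logical(1))
  expect_true(all(inside))
})

test_that("a schedule without USV states yields an empty call table", {
  cfg <- session_config(10, seed = 1,
                        state_schedule = data.frame(state = "silent_escape",
                                                    duration_s = 10))
  r <- simulate_respiration(cfg)
  u <- simulate_usv_audio(cfg, r$cycles, make_audio = TRUE)
  expect_equal(nrow(u$calls), 0L)
  expect_lt(max(abs(u$audio)), 10 * cfg$audio_noise_sd)
})

test_that("aliasing and empty-session configurations are rejected", {
  expect_error(session_config(0), "positive")
  cfg <- session_config(10, audio_rate = 30000)
  r <- simulate_respiration(cfg)
  expect_error(simulate_usv_audio(cfg, r$cycles), "aliasing")
  expect_error(session_config(10, state_schedule = data.frame(
    state = "grooming", duration_s = 10)), "unknown state")
})

test_that("injected band energy scales quadratically with amplitude", {
  base <- session_config(30, seed = 9,
                         state_schedule = data.frame(state = "silent_escape",
                                                     duration_s = 30),
                         noise_amp = 0)
  amp2 <- base$band_amplitudes
  amp2["theta", ] <- 2 * amp2["theta", ]
  cfg2 <- session_config(30, seed = 9,
                         state_schedule = data.frame(state = "silent_escape",
                                                     duration_s = 30),
                         band_amplitudes = amp2, noise_amp = 0)
  r <- simulate_respiration(base)
  band_energy <- function(cfg) {
    x <- simulate_lfp(cfg, r$cycles)$lfp
    sp <- Mod(fft(x))^2
    f <- (seq_along(sp) - 1) / 30
    sum(sp[f >= 5 & f < 15])
  }
  expect_equal(band_energy(cfg2) / band_energy(base), 4, tolerance = 0.05)
})

test_that("video blob is still during freezing and moving during escape", {
  cfg <- session_config(6, seed = 10, state_schedule = data.frame(
    state = c("silent_freezing", "silent_escape"), duration_s = c(3, 3)))
  v <- simulate_video(cfg)
  d <- abs(v$frames[, , -1] - v$frames[, , -dim(v$frames)[3]])
  mx <- apply(d, 3L, max)
  # a difference bin belongs to freezing only if both frames precede the
  # state change
  frz <- v$times[-1] < 3 - 1e-9
  expect_true(all(mx[frz] <= 2 * cfg$video_noise + 1e-12))
  expect_true(all(mx[v$times[-1] > 3.1] > 0.2))
})
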