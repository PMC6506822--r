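regular_cycles <- function(n, dur = 0.5, t0 = 0, insp_frac = 0.4) {
  on <- t0 + (seq_len(n) - 1) * dur
  data.frame(insp_onset_s = on, exp_onset_s = on + insp_frac * dur,
             next_insp_onset_s = on + dur, duration_s = dur,
             inst_freq_hz = 1 / dur)
}

test_that("a stationary tone gives a flat phase-power profile", {
  t <- seq(0, 20, by = 1e-3)[-1]
  scal <- morlet_scalogram(sin(2 * pi * 25 * t), 1000,
                           freqs = seq(20, 30, by = 1))
  cyc <- regular_cycles(36, dur = 0.5, t0 = 1)
  cs <- cycle_frequency_scalogram(scal, cyc,
                                  data.frame(onset_s = 0, offset_s = 20))
  curve <- band_max_power_curve(cs, "beta")
  expect_lt(max(curve$value) / min(curve$value), 1.1)
})

test_that("phase bins follow the 0.4/0.6 template with 0.025 bins", {
  t <- seq(0, 10, by = 1e-3)[-1]
  scal <- morlet_scalogram(sin(2 * pi * 25 * t), 1000, freqs = c(24, 25, 26))
  cs <- cycle_frequency_scalogram(scal, regular_cycles(16, t0 = 1),
                                  data.frame(onset_s = 0, offset_s = 10))
  expect_equal(length(cs$phase), 40L)
  expect_equal(cs$phase[1], 0.0125)
  expect_equal(sum(cs$phase < 0.4), 16L)        # inspiration bins
  expect_equal(cs$insp_fraction, 0.4)
})

test_that("injected gamma phase is recovered within two phase bins", {
  gm <- data.frame(state = fear_categories(), phase = 0.2, depth = 0.8)
  cfg <- session_config(60, seed = 60,
                        state_schedule = data.frame(state = "silent_freezing",
                                                    duration_s = 60),
                        gamma_mod = gm)
  s <- simulate_session(cfg, make_video = FALSE)
  cyc <- detect_cycles(s$resp$waveform, 1000)
  scal <- morlet_scalogram(s$lfp$lfp, 1000, freqs = seq(40, 79.5, by = 1.5))
  cs <- cycle_frequency_scalogram(scal, cyc,
                                  data.frame(onset_s = 0, offset_s = 60))
  curve <- band_max_power_curve(cs, "gamma")
  expect_lte(abs(curve$peak_phase - 0.2), 0.05)
})

test_that("distinct injected phases put silent and USV freezing peaks in the
           configured cycle phases", {
  cfg <- session_config(120, seed = 61, state_schedule = data.frame(
    state = c("silent_freezing", "usv_freezing"), duration_s = c(60, 60)))
  s <- simulate_session(cfg, make_video = FALSE)
  cyc <- detect_cycles(s$resp$waveform, 1000)
  scal <- morlet_scalogram(s$lfp$lfp, 1000, freqs = seq(40, 79.5, by = 1.5))
  seg <- s$truth$segments
  sf <- band_max_power_curve(cycle_frequency_scalogram(
    scal, cyc, seg[seg$label == "silent_freezing", ]), "gamma")
  uf <- band_max_power_curve(cycle_frequency_scalogram(
    scal, cyc, seg[seg$label == "usv_freezing", ]), "gamma")
  expect_lt(sf$peak_phase, 0.4)                 # inspiration
  expect_gte(uf$peak_phase, 0.7)                # late expiration
})

test_that("phase-mean power equals time-mean power over the same cycles", {
  t <- seq(0, 30, by = 1e-3)[-1]
  set.seed(62)
  x <- sin(2 * pi * 25 * t) * (1 + 0.5 * sin(2 * pi * 2 * t)) + rnorm(30000,
                                                                      0, 0.1)
  scal <- morlet_scalogram(x, 1000, freqs = seq(20, 30, by = 1))
  cyc <- regular_cycles(56, dur = 0.5, t0 = 1)
  cs <- cycle_frequency_scalogram(scal, cyc,
                                  data.frame(onset_s = 0, offset_s = 30))
  pow <- scal$amp^2
  sel <- scal$times_s >= 1 & scal$times_s < 29
  expect_equal(mean(colMeans(cs$power)), mean(colMeans(pow[sel, ])),
               tolerance = 0.05)
})

test_that("stretching a 0.4/0.6 cycle is the identity up to interpolation", {
  t <- seq(0, 10, by = 1e-3)[-1]
  # beta amplitude tied deterministically to the phase of a 0.5-s cycle
  phase <- (t %% 0.5) / 0.5
  x <- sin(2 * pi * 24 * t) * (1 + cos(2 * pi * (phase - 0.3)))
  scal <- morlet_scalogram(x, 1000, freqs = seq(22, 26, by = 1))
  cs <- cycle_frequency_scalogram(scal, regular_cycles(16, t0 = 1),
                                  data.frame(onset_s = 0, offset_s = 10))
  curve <- band_max_power_curve(cs, c(22, 27))
  # direct template: power at phase p is ((1 + cos(2 pi (p - 0.3))))^2 scaled
  templ <- (1 + cos(2 * pi * (cs$phase - 0.3)))^2
  r <- suppressWarnings(cor(curve$value, templ))
  expect_gt(r, 0.99)
  expect_lte(abs(curve$peak_phase - 0.3), 0.025)
})

test_that("cycle averaging is count-weighted: duplicating cycles is a no-op", {
  t <- seq(0, 10, by = 1e-3)[-1]
  scal <- morlet_scalogram(sin(2 * pi * 25 * t) * (1 + 0.3 * sin(2 * pi * t)),
                           1000, freqs = c(24, 25, 26))
  cyc <- regular_cycles(16, t0 = 1)
  seg <- data.frame(onset_s = 0, offset_s = 10)
  cs1 <- cycle_frequency_scalogram(scal, cyc, seg)
  cs2 <- cycle_frequency_scalogram(scal, rbind(cyc, cyc)[order(rep(seq_len(16),
                                                                   2)), ], seg)
  expect_equal(cs1$power, cs2$power, tolerance = 1e-12)
})

test_that("cycles straddling segment edges are excluded", {
  t <- seq(0, 10, by = 1e-3)[-1]
  scal <- morlet_scalogram(sin(2 * pi * 25 * t), 1000, freqs = c(24, 25, 26))
  cyc <- regular_cycles(16, t0 = 1)
  cs <- cycle_frequency_scalogram(scal, cyc,
                                  data.frame(onset_s = 1.1, offset_s = 8.9))
  expect_equal(cs$n_cycles, 14L)                # first and last cycles dropped
  expect_error(cycle_frequency_scalogram(
    scal, cyc, data.frame(onset_s = 9.7, offset_s = 10)), "no usable cycles")
})

test_that("band curves report exactly the boosted phase bins", {
  cs <- structure(list(phase = (seq_len(40) - 0.5) / 40,
                       freq_hz = c(45, 55, 65),
                       power = matrix(1, 40, 3), n_cycles = 5L,
                       insp_fraction = 0.4), class = "cycle_scalogram")
  flat <- band_max_power_curve(cs, "gamma")
  expect_true(all(flat$value == 1))
  cs$power[31:40, 2] <- 3
  boosted <- band_max_power_curve(cs, "gamma")
  expect_equal(which(boosted$value == 3), 31:40)
  expect_error(band_max_power_curve(cs, c(100, 120)), "no scalogram")
})
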