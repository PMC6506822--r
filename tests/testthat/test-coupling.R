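test_that("dominant frequency of a pure tone is the tone frequency", {
  t <- seq(0, 10, by = 1e-3)[-1]
  scal <- morlet_scalogram(sin(2 * pi * 7 * t), 1000, f_max = 15,
                           step_s = 0.004)
  dom <- dominant_lfp_frequency(scal)
  mid <- dom$times > 2 & dom$times < 8
  expect_true(all(abs(dom$freq_hz[mid] - 7) <= 0.1 + 1e-9))
  expect_equal(dom$step_s, 0.004)
})

test_that("dominant frequency tracks a slow chirp monotonically", {
  t <- seq(0, 20, by = 1e-3)[-1]
  # linear chirp 2 -> 10 Hz: instantaneous frequency 2 + 0.4 t
  x <- sin(2 * pi * (2 * t + 0.2 * t^2))
  scal <- morlet_scalogram(x, 1000, f_max = 15, step_s = 0.004)
  dom <- dominant_lfp_frequency(scal)
  mid <- dom$times > 2 & dom$times < 18
  f <- dom$freq_hz[mid]
  expect_true(all(diff(f) >= -0.35))            # non-decreasing up to one bin
  inst <- 2 + 0.4 * dom$times[mid]
  expect_lt(median(abs(f - inst)), 0.3)         # chirp oracle
})

test_that("the stronger of two rhythms dominates throughout", {
  t <- seq(0, 10, by = 1e-3)[-1]
  x <- sin(2 * pi * 3 * t) + 0.4 * sin(2 * pi * 12 * t)
  dom <- dominant_lfp_frequency(morlet_scalogram(x, 1000, f_max = 15,
                                                 step_s = 0.004))
  mid <- dom$times > 2 & dom$times < 8
  expect_true(all(abs(dom$freq_hz[mid] - 3) < 0.5))
})

test_that("an all-zero trace yields flagged (NA) dominant frequencies", {
  scal <- morlet_scalogram(rep(0, 4000), 1000, f_max = 15, step_s = 0.004)
  dom <- dominant_lfp_frequency(scal)
  expect_true(all(is.na(dom$freq_hz)))
})

series_from <- function(times, values, step = 0.004) {
  structure(list(times = times, freq_hz = values, step_s = step),
            class = "inst_freq_series")
}

test_that("identical series put all histogram mass on the diagonal", {
  times <- seq(0, 40, by = 0.004)
  f <- 1 + 3 * (1 + sin(2 * pi * times / 10)) / 2   # sweeps 1-4 Hz
  h <- coupling_histogram(series_from(times, f), series_from(times, f),
                          data.frame(onset_s = 0, offset_s = 40))
  expect_equal(sum(h$mass), 1, tolerance = 1e-9)
  centers <- (h$resp_edges[-1] + h$resp_edges[-length(h$resp_edges)]) / 2
  diag_mass <- sum(h$mass[abs(outer(centers, centers, `-`)) < 0.33])
  expect_equal(diag_mass, 1, tolerance = 1e-9)

  # index on a uniformly sweeping coupled pair: observed diagonal mass is 1,
  # the independence expectation is ~3 bins / 21 bins, so the excess is large
  fu <- 1 + 7 * (times %% 10) / 10
  hu <- coupling_histogram(series_from(times, fu), series_from(times, fu),
                           data.frame(onset_s = 0, offset_s = 40))
  expect_gt(diagonal_coupling_index(hu), 0.8)
})

test_that("a fixed-frequency LFP confines mass to one row across columns", {
  times <- seq(0, 40, by = 0.004)
  resp <- series_from(times, 1 + 3 * (times %% 10) / 10)
  lfp <- series_from(times, rep(6.5, length(times)))
  h <- coupling_histogram(resp, lfp, data.frame(onset_s = 0, offset_s = 40))
  li <- findInterval(6.5, h$lfp_edges)
  expect_equal(sum(h$mass[, li]), 1, tolerance = 1e-9)
  expect_gt(sum(colSums(h$mass) > 0.01), 0)     # one LFP row only
  expect_equal(sum(rowSums(h$mass) > 0.01) > 5, TRUE)  # many resp columns
})

test_that("independent series give near-zero diagonal excess", {
  set.seed(50)
  times <- seq(0, 200, by = 0.004)
  resp <- series_from(times, runif(length(times), 1, 8))
  lfp <- series_from(times, runif(length(times), 1, 8))
  h <- coupling_histogram(resp, lfp, data.frame(onset_s = 0, offset_s = 200))
  expect_lt(diagonal_coupling_index(h), 0.1)
  # diagonal-band mass matches the closed-form independence expectation
  centers <- (h$resp_edges[-1] + h$resp_edges[-length(h$resp_edges)]) / 2
  d <- abs(outer(centers, centers, `-`)) <= 0.5 + 1e-9
  expected <- sum(outer(rowSums(h$mass), colSums(h$mass))[d])
  observed <- sum(h$mass[d])
  se <- sqrt(expected * (1 - expected) / h$n_pairs)
  expect_lt(abs(observed - expected), 30 * se)  # samples autocorrelation-free
})

test_that("mass in a single off-diagonal cell gives index zero", {
  h <- structure(list(resp_edges = seq(0, 15, by = 0.33),
                      lfp_edges = seq(0, 15, by = 0.33),
                      mass = matrix(0, 45, 45), n_pairs = 100),
                 class = "coupling_histogram")
  h$mass[3, 30] <- 1
  expect_equal(diagonal_coupling_index(h), 0)
})

test_that("histogram is conserved under segment splitting", {
  times <- seq(0, 30, by = 0.004)
  set.seed(51)
  resp <- series_from(times, runif(length(times), 1, 6))
  lfp <- series_from(times, runif(length(times), 1, 6))
  h1 <- coupling_histogram(resp, lfp, data.frame(onset_s = 0, offset_s = 30))
  h2 <- coupling_histogram(resp, lfp,
                           data.frame(onset_s = c(0, 11.3),
                                      offset_s = c(11.3, 30)))
  expect_equal(h1$mass, h2$mass)
  expect_equal(h1$n_pairs, h2$n_pairs)
})

test_that("pairing fails cleanly when no samples fall in the segments", {
  times <- seq(0, 10, by = 0.004)
  s <- series_from(times, rep(3, length(times)))
  expect_error(coupling_histogram(s, s, data.frame(onset_s = 20,
                                                   offset_s = 21)),
               "no paired samples")
})

test_that("delta-locked freezing couples while USV freezing does not", {
  cfg <- session_config(80, seed = 52, state_schedule = data.frame(
    state = c("silent_freezing", "usv_freezing"), duration_s = c(40, 40)))
  s <- simulate_session(cfg, make_video = FALSE)
  cyc <- detect_cycles(s$resp$waveform, 1000)
  rif <- instantaneous_frequency(cyc, t_range = c(0, 80))
  dom <- dominant_lfp_frequency(morlet_scalogram(s$lfp$lfp, 1000, f_max = 15,
                                                 step_s = 0.004))
  seg <- s$truth$segments
  i_sf <- diagonal_coupling_index(coupling_histogram(
    rif, dom, seg[seg$label == "silent_freezing", ]))
  i_uf <- diagonal_coupling_index(coupling_histogram(
    rif, dom, seg[seg$label == "usv_freezing", ]))
  expect_gt(i_sf, i_uf)
  expect_gt(i_sf, 0.05)
  expect_lt(i_uf, 0.05)
})
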