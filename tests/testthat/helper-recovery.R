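# Restrict realized category segments to times where the realized category
# coincides with the scheduled generator state: a scheduled USV state may
# contain a silent stretch longer than 1 s (calls are probabilistic), which
# the segmentation correctly labels silent although the generator injected
# USV-state amplitudes there.  Recovery of injected parameters is evaluated
# where the injection is defined.
state_consistent_segments <- function(segments, schedule, min_len_s = 1) {
  pieces <- list()
  for (i in seq_len(nrow(segments))) {
    for (k in seq_len(nrow(schedule))) {
      lo <- max(segments$onset_s[i], schedule$onset_s[k])
      hi <- min(segments$offset_s[i], schedule$offset_s[k])
      if (hi - lo >= min_len_s && segments$label[i] == schedule$state[k])
        pieces[[length(pieces) + 1L]] <-
          data.frame(label = segments$label[i], onset_s = lo, offset_s = hi)
    }
  }
  if (length(pieces) == 0L)
    return(data.frame(label = character(0), onset_s = numeric(0),
                      offset_s = numeric(0)))
  out <- do.call(rbind, pieces)
  out[order(out$onset_s), , drop = FALSE]
}

# One parameter-recovery replicate under the study conditions: a four-state
# session (40 s silent freezing, 40 s USV freezing, 20 s silent escape,
# 20 s USV escape) analysed end to end with detected cycles and the
# ground-truth event segmentation.
recovery_replicate <- function(seed) {
  dur <- 120
  cfg <- session_config(dur, seed = seed, state_schedule = data.frame(
    state = c("silent_freezing", "usv_freezing",
              "silent_escape", "usv_escape"),
    duration_s = c(40, 40, 20, 20)))
  s <- simulate_session(cfg, make_audio = FALSE, make_video = FALSE)
  sch <- data.frame(state = cfg$state_schedule$state,
                    offset_s = cumsum(cfg$state_schedule$duration_s))
  sch$onset_s <- sch$offset_s - cfg$state_schedule$duration_s
  seg <- state_consistent_segments(s$truth$segments, sch)

  cyc <- detect_cycles(s$resp$waveform, s$resp$rate)
  rif <- instantaneous_frequency(cyc, t_range = c(0, dur))

  freqs <- c(seq(0.5, 15, by = 0.15), seq(15.5, 79.5, by = 1))
  scal <- morlet_scalogram(s$lfp$lfp, s$lfp$rate, freqs = freqs,
                           step_s = 0.004)

  # (a) respiratory-frequency PDF per category (0.33-Hz bins)
  pdfs <- lapply(fear_categories(), function(cat) {
    sg <- seg[seg$label == cat, , drop = FALSE]
    if (nrow(sg) == 0) return(NULL)
    respiration_pdf(rif, sg)
  })
  names(pdfs) <- fear_categories()

  # (b) respiration/delta frequency coupling per freezing category
  lo <- scal
  lo$amp <- scal$amp[, scal$freq_hz <= 15, drop = FALSE]
  lo$freq_hz <- scal$freq_hz[scal$freq_hz <= 15]
  lo$coi_s <- scal$coi_s[scal$freq_hz <= 15]
  dom <- dominant_lfp_frequency(lo)
  idx <- vapply(c("silent_freezing", "usv_freezing"), function(cat) {
    diagonal_coupling_index(coupling_histogram(
      rif, dom, seg[seg$label == cat, , drop = FALSE]))
  }, numeric(1))

  # (c) gamma preferred phase per category from the cycle scalogram
  phases <- vapply(fear_categories(), function(cat) {
    sg <- seg[seg$label == cat, , drop = FALSE]
    cs <- tryCatch(cycle_frequency_scalogram(scal, cyc, sg),
                   fearresp_no_data = function(e) NULL)
    if (is.null(cs)) return(NA_real_)
    band_max_power_curve(cs, "gamma")$peak_phase
  }, numeric(1))

  # (d) per-category band power along the standard analysis path
  bp <- band_power(category_psd(scal, seg))

  list(config = cfg, pdfs = pdfs, idx = idx, phases = phases,
       band_power = bp, injected = s$truth$injected)
}

# circular distance between normalized phases in [0, 1)
phase_dist <- function(a, b) {
  d <- abs(a - b) %% 1
  pmin(d, 1 - d)
}

# do the signs of all pairwise between-category band-power contrasts match
# the injected amplitude ordering?  Returns fraction of contrasts recovered.
contrast_sign_recovery <- function(mean_bp, injected_amp) {
  cats <- colnames(injected_amp)
  total <- 0L; hit <- 0L
  for (b in rownames(injected_amp)) {
    for (i in seq_along(cats)) {
      for (j in seq_len(i - 1L)) {
        inj <- injected_amp[b, cats[i]]^2 - injected_amp[b, cats[j]]^2
        obs <- mean_bp[[b]][cats[i]] - mean_bp[[b]][cats[j]]
        total <- total + 1L
        hit <- hit + (sign(inj) == sign(obs))
      }
    }
  }
  hit / total
}

# mean band power per band/category over a list of band_power tables
pool_band_power <- function(bps) {
  all <- do.call(rbind, bps)
  out <- lapply(split(all, all$band), function(d)
    tapply(d$mean_power, d$category, mean))
  out
}
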