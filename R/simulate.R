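#' Default evoked-response templates per stimulation region and ROI
#'
#' One Gaussian-windowed ~20 Hz component per (region, ROI): the scalp
#' response to a DBS pulse looks like a short series of diminishing waves
#' whose dominant positive peak sits at a region-dependent latency.
#' Latency defaults encode the reported group medians: medial
#' fronto-central 77/69/67 ms, right fronto-central 73.5/62/64 ms and
#' occipital 80/71/92 ms for ZI/DLR/VMR. Amplitudes are conventions (the
#' source data are reported in arbitrary/z-scored units): the topography is
#' concentrated medially and ipsilaterally fronto-centrally, the left
#' (contralateral) frontal area carries essentially nothing, and occipital
#' areas are weak.
#'
#' @return Data frame with columns `region`, `roi`, `latency_ms`,
#'   `amplitude_uv`, `width_ms`, `freq_hz`.
#' @export
default_templates <- function() {
  regions <- c("ZI", "DLR", "VMR")
  lat <- list(
    medial_fronto_central     = c(77, 69, 67),
    right_fronto_central      = c(73.5, 62, 64),
    left_fronto_central       = c(77, 69, 67),
    medial_frontal            = c(77, 69, 67),
    right_frontal             = c(73.5, 62, 64),
    left_frontal              = c(77, 69, 67),
    medial_occipital_parietal = c(80, 71, 92),
    right_occipital_parietal  = c(80, 71, 92),
    left_occipital_parietal   = c(80, 71, 92)
  )
  amp <- c(medial_fronto_central = 4, right_fronto_central = 3,
           left_fronto_central = 0.8, medial_frontal = 1,
           right_frontal = 0.8, left_frontal = 0.05,
           medial_occipital_parietal = 0.08, right_occipital_parietal = 0.08,
           left_occipital_parietal = 0.08)
  do.call(rbind, lapply(names(lat), function(roi) {
    data.frame(region = regions, roi = roi, latency_ms = lat[[roi]],
               amplitude_uv = amp[[roi]], width_ms = 20, freq_hz = 20,
               stringsAsFactors = FALSE)
  }))
}

#' Generative parameters of the synthetic cohort
#'
#' Defaults reproduce the study protocol: 5 Hz stimulation for 8 min
#' (2,400 pulses; 3 Hz for 13.3 min is the alternative protocol), 1,000 Hz
#' sampling, 64 channels, a cohort of 61 sessions labelled ZI (20),
#' DLR (23), VMR (18). Background noise is 1/f plus an alpha bump plus
#' broadband sensor noise; each pulse deposits a biphasic stimulus artifact
#' two orders of magnitude above the evoked response. Between-session
#' (patient) variability enters as one latency shift and one amplitude gain
#' per session; the latency spread is region dependent, which is what makes
#' some region contrasts harder than others.
#'
#' @param stim_freq stimulation rate (Hz).
#' @param duration stimulation duration (s); `stim_freq * duration` pulses.
#' @param fs sampling rate (Hz).
#' @param n_channels 64 or 128.
#' @param templates evoked component table, see [default_templates()].
#' @param artifact list: `amplitude_uv`, `duration_ms` (per phase, biphasic).
#' @param noise list: `pink_sd`, `pink_exponent`, `white_sd`, `alpha_sd`,
#'   `alpha_freq`, `alpha_bw`, `max_freq` (all SDs in microvolts RMS per
#'   channel; spectra band-limited at `max_freq`).
#' @param cohort_counts named sessions-per-region vector.
#' @param latency_jitter_sd named per-region SD (ms) of the session-level
#'   latency shift.
#' @param amplitude_gain_range session-level multiplicative gain range.
#' @param lead_in_s,lead_out_s quiet padding around the pulse train so every
#'   pulse supports a full epoch.
#' @param seed master seed; per-session seeds derive from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(stim_freq = 5, duration = 480, fs = 1000,
                              n_channels = 64,
                              templates = default_templates(),
                              artifact = list(amplitude_uv = 200,
                                              duration_ms = 1),
                              noise = list(pink_sd = 8, pink_exponent = 1,
                                           white_sd = 3, alpha_sd = 3,
                                           alpha_freq = 10, alpha_bw = 2,
                                           max_freq = 55),
                              cohort_counts = c(ZI = 20, DLR = 23, VMR = 18),
                              latency_jitter_sd = c(ZI = 2, DLR = 6, VMR = 2),
                              amplitude_gain_range = c(0.8, 1.2),
                              lead_in_s = 0.5, lead_out_s = 0.5,
                              seed = 1) {
  cfg <- list(stim_freq = stim_freq, duration = duration, fs = fs,
              n_channels = n_channels, templates = templates,
              artifact = artifact, noise = noise,
              cohort_counts = cohort_counts,
              latency_jitter_sd = latency_jitter_sd,
              amplitude_gain_range = amplitude_gain_range,
              lead_in_s = lead_in_s, lead_out_s = lead_out_s, seed = seed)
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  npulse <- cfg$stim_freq * cfg$duration
  if (abs(npulse - round(npulse)) > 1e-9) {
    stopf("stim_freq x duration must give an integer pulse count")
  }
  if (!cfg$n_channels %in% c(64L, 128L)) stopf("n_channels must be 64 or 128")
  lat <- cfg$templates$latency_ms
  if (any(lat <= 0 | lat >= 150)) stopf("template latencies must lie in (0, 150) ms")
  if (any(cfg$cohort_counts < 0)) stopf("cohort counts must be >= 0")
  bad <- setdiff(unique(cfg$templates$region), c("ZI", "DLR", "VMR"))
  if (length(bad)) stopf("unknown template region(s): %s", paste(bad, collapse = ", "))
  invisible(cfg)
}

evoked_components <- function(config, region, roi) {
  comps <- config$templates[config$templates$region == region &
                              config$templates$roi == roi, , drop = FALSE]
  if (!nrow(comps)) {
    stopf("no template for region '%s' / ROI '%s'", region, roi)
  }
  comps
}

# Sum of Gaussian-windowed cosine components evaluated at times t (ms,
# relative to pulse onset). Each component peaks exactly at its latency.
eval_components <- function(t_ms, comps, shift_ms = 0, gain = 1) {
  out <- numeric(length(t_ms))
  for (i in seq_len(nrow(comps))) {
    lat <- comps$latency_ms[i] + shift_ms
    w <- comps$width_ms[i]
    out <- out + gain * comps$amplitude_uv[i] *
      exp(-(t_ms - lat)^2 / (2 * w^2)) *
      cos(2 * pi * comps$freq_hz[i] * (t_ms - lat) / 1000)
  }
  out
}

#' Evoked-response template for one region and ROI
#'
#' Evaluates the configured component sum on the epoch grid; the waveform
#' is zero before stimulus onset (a single-pulse template, without the tail
#' of the preceding pulse).
#'
#' @param region `"ZI"`, `"DLR"` or `"VMR"`.
#' @param roi one of [roi_names()].
#' @param config a [simulation_config()].
#' @param window_ms half-open epoch span in ms.
#' @param shift_ms,gain session-level latency shift (ms) and amplitude gain.
#' @return Numeric waveform, one sample per epoch sample; `attr(,"times_ms")`
#'   carries the time axis.
#' @export
make_evoked_template <- function(region, roi, config = simulation_config(),
                                 window_ms = c(-50, 150),
                                 shift_ms = 0, gain = 1) {
  if (!region %in% c("ZI", "DLR", "VMR")) stopf("unknown region '%s'", region)
  if (!roi %in% roi_names()) stopf("unknown ROI '%s'", roi)
  comps <- evoked_components(config, region, roi)
  n0 <- ms_to_samples(window_ms[1], config$fs)
  n1 <- ms_to_samples(window_ms[2], config$fs)
  t_ms <- samples_to_ms(n0:(n1 - 1L), config$fs)
  out <- eval_components(t_ms, comps, shift_ms, gain)
  out[t_ms < 0] <- 0
  attr(out, "times_ms") <- t_ms
  out
}

# ROI -> channel spatial spread: weight 1 at the ROI centroid channel,
# falling linearly to 0.5 at the ROI's outermost member; non-members 0.
roi_channel_weights <- function(montage) {
  pos <- montage$positions
  W <- matrix(0, length(roi_names()), nrow(pos),
              dimnames = list(roi_names(), pos$name))
  for (r in roi_names()) {
    members <- montage$roi_map[[r]]
    idx <- match(members, pos$name)
    centroid <- colMeans(pos[idx, c("x", "y", "z"), drop = FALSE])
    d <- sqrt(colSums((t(as.matrix(pos[idx, c("x", "y", "z")])) - centroid)^2))
    dmax <- max(d)
    w <- if (dmax < 1e-12) rep(1, length(idx)) else 1 - 0.5 * d / dmax
    W[r, idx] <- w
  }
  W
}

# Background noise: 1/f ("pink") + alpha bump + flat broadband component.
# Synthesised in the time domain as filtered white noise — a pole-zero
# pinking cascade, a second-order resonator at the alpha frequency, and a
# flat stream — at an internal rate of 2 x max_freq, then linearly
# upsampled to fs. Time-domain AR synthesis makes the process aperiodic
# with a genuinely continuous spectrum, so averages over the periodic
# pulse train shrink as 1/sqrt(N) (an FFT-synthesised signal would carry a
# line spectrum that resonates with the stimulus comb). Component SDs are
# normalised at the internal rate via each filter's impulse response.

# Pole-zero pinking cascade: quarter-decade zero offsets give ~ -10
# dB/decade over [0.4, max_freq] Hz.
pink_sections <- function(fs_low) {
  f_poles <- 0.4 * 10^(0.5 * (0:4))
  f_poles <- f_poles[f_poles < fs_low / 2]
  lapply(f_poles, function(fp) {
    list(b = c(1, -exp(-2 * pi * fp * 10^0.25 / fs_low)),
         a = c(1, -exp(-2 * pi * fp / fs_low)))
  })
}

filter_gain <- function(sections, n = 8192) {
  h <- apply_sections(c(1, rep(0, n - 1)), sections)
  sqrt(sum(h^2))
}

apply_sections <- function(x, sections) {
  iir_cascade(x, lapply(sections, `[[`, "b"), lapply(sections, `[[`, "a"))
}

synth_background <- function(n_channels, n_samples, fs, noise) {
  out <- matrix(0, n_samples, n_channels)     # samples x channels
  sds <- c(noise$pink_sd, noise$alpha_sd, noise$white_sd)
  if (all(sds == 0)) return(out)
  fs_low <- 2 * noise$max_freq
  burn <- 512L
  n_low <- as.integer(ceiling((n_samples - 1) * fs_low / fs)) + 2L
  pink <- pink_sections(fs_low)
  g_pink <- filter_gain(pink)
  th <- 2 * pi * noise$alpha_freq / fs_low
  r <- exp(-pi * noise$alpha_bw / fs_low)
  alpha <- list(list(b = c(1), a = c(1, -2 * r * cos(th), r^2)))
  g_alpha <- filter_gain(alpha)
  for (ch in seq_len(n_channels)) {
    low <- numeric(n_low + burn)
    if (noise$pink_sd > 0) {
      x <- apply_sections(stats::rnorm(n_low + burn), pink)
      low <- low + x * (noise$pink_sd / g_pink)
    }
    if (noise$alpha_sd > 0) {
      x <- apply_sections(stats::rnorm(n_low + burn), alpha)
      low <- low + x * (noise$alpha_sd / g_alpha)
    }
    if (noise$white_sd > 0) {
      low <- low + noise$white_sd * stats::rnorm(n_low + burn)
    }
    out[, ch] <- lin_upsample(low[(burn + 1L):(burn + n_low)],
                              fs_low / fs, n_samples)
  }
  out
}

#' Simulate one stimulation session
#'
#' Generates a continuous recording: evoked templates mixed onto channels
#' through the ROI spatial spread, time-locked to every pulse; a biphasic
#' stimulus artifact at each onset (per-channel gain ramp, so it survives
#' no re-referencing trick); and 1/f + alpha + broadband background noise.
#' One latency shift and one amplitude gain, drawn per session, model
#' between-patient variability; both are recorded in `meta` as ground
#' truth (`latency_shift_ms`, `amplitude_gain`).
#'
#' @param config a [simulation_config()].
#' @param region stimulated region label.
#' @param seed session seed (deterministic output for equal seeds).
#' @param montage optional pre-built montage (rebuilt from
#'   `config$n_channels` when missing).
#' @return An `eeg_recording` with a full event table (one row per pulse).
#' @export
simulate_session <- function(config, region, seed = config$seed,
                             montage = NULL) {
  validate_simulation_config(config)
  if (!region %in% c("ZI", "DLR", "VMR")) stopf("unknown region '%s'", region)
  montage <- montage %||% make_montage(config$n_channels)
  fs <- config$fs
  n_pulse <- as.integer(round(config$stim_freq * config$duration))
  lead_in <- as.integer(round(config$lead_in_s * fs))
  lead_out <- as.integer(round(config$lead_out_s * fs))
  period_exact <- fs / config$stim_freq
  onsets <- lead_in + as.integer(round((seq_len(n_pulse) - 1L) * period_exact))
  n_samples <- as.integer(onsets[n_pulse] + ceiling(period_exact) + lead_out)
  epoch_span <- ms_to_samples(150, fs)
  if (n_samples - onsets[n_pulse] < epoch_span) {
    warnf("recording too short for a full epoch after the last pulse; dropping it")
    onsets <- onsets[-n_pulse]
    n_pulse <- n_pulse - 1L
  }

  with_seed(seed, {
    shift_ms <- stats::rnorm(1, 0, config$latency_jitter_sd[[region]])
    gain <- stats::runif(1, config$amplitude_gain_range[1],
                         config$amplitude_gain_range[2])
    sig <- synth_background(config$n_channels, n_samples, fs, config$noise)
  })

  # evoked responses: ROI templates spread to member channels, tiled pulse
  # by pulse (vectorised when the inter-pulse interval is a whole number of
  # samples, as in the 5 Hz protocol)
  W <- roi_channel_weights(montage)         # 9 x channels
  period <- as.integer(floor(period_exact))
  uniform <- abs(period_exact - period) < 1e-9
  span <- if (uniform) period else as.integer(ceiling(period_exact))
  t_ms <- samples_to_ms(0:(span - 1L), fs)
  P <- vapply(roi_names(), function(r) {
    eval_components(t_ms, evoked_components(config, region, r), shift_ms, gain)
  }, numeric(span))                         # span x 9
  E <- P %*% W[colnames(P), , drop = FALSE] # span x channels
  if (uniform) {
    tile_add_inplace(sig, E, onsets[1], n_pulse)
  } else {
    for (o in onsets) {
      rows <- (o + 1L):min(o + span, n_samples)
      sig[rows, ] <- sig[rows, ] + E[seq_along(rows), , drop = FALSE]
    }
  }

  # biphasic stimulus artifact, amplitude graded across channels
  art <- config$artifact
  if (art$amplitude_uv != 0) {
    g <- art$amplitude_uv * seq(0.7, 1.3, length.out = config$n_channels)
    half <- max(1L, ms_to_samples(art$duration_ms, fs))
    gmat <- matrix(g, length(onsets) * half, config$n_channels, byrow = TRUE)
    pos <- as.vector(outer(0:(half - 1L), onsets + 1L, "+"))
    sig[pos, ] <- sig[pos, ] + gmat
    sig[pos + half, ] <- sig[pos + half, ] - gmat
  }

  events <- data.frame(onset_sample = onsets, label = "stim",
                       stringsAsFactors = FALSE)
  recording(sig, fs, montage$positions$name, events,
            meta = list(region_label = region,
                        montage_id = montage$montage_id,
                        seed = seed, latency_shift_ms = shift_ms,
                        amplitude_gain = gain))
}

#' Simulate the labelled cohort
#'
#' One session per (virtual patient, contact), regions interleaved so that
#' consecutive sessions belong to the same virtual patient's different
#' contacts. Per-session seeds derive deterministically from the master
#' seed. With the default counts this yields the 61-session cohort
#' (ZI 20 / DLR 23 / VMR 18).
#'
#' @param config a [simulation_config()].
#' @param action optional `function(recording, info)` applied to each
#'   session as it is generated; its return values are collected and the
#'   recording is discarded (keeps full cohorts within memory). When
#'   `NULL`, the recordings themselves are returned.
#' @param out_dir optional directory: writes `<session_id>.edf`,
#'   `<session_id>_events.tsv` and `manifest.csv` per session.
#' @return List with `manifest` (session_id, patient_id, region, seed,
#'   latency_shift_ms, amplitude_gain, gen_seconds) and `sessions` (list of
#'   recordings or of `action` results).
#' @export
simulate_cohort <- function(config = simulation_config(), action = NULL,
                            out_dir = NULL) {
  validate_simulation_config(config)
  counts <- config$cohort_counts
  # round-robin interleave of region labels
  pool <- lapply(names(counts), function(r) rep(r, counts[[r]]))
  labels <- character(0)
  while (any(lengths(pool) > 0)) {
    for (j in seq_along(pool)) {
      if (length(pool[[j]])) {
        labels <- c(labels, pool[[j]][1])
        pool[[j]] <- pool[[j]][-1]
      }
    }
  }
  n <- length(labels)
  manifest <- data.frame(
    session_id = sprintf("S%03d", seq_len(n)),
    patient_id = sprintf("P%02d", (seq_len(n) - 1L) %/% 4L + 1L),
    region = labels,
    seed = vapply(seq_len(n), function(i) derive_seed(config$seed, i), 1L),
    latency_shift_ms = NA_real_, amplitude_gain = NA_real_,
    gen_seconds = NA_real_, stringsAsFactors = FALSE)
  montage <- make_montage(config$n_channels)
  sessions <- vector("list", n)
  for (i in seq_len(n)) {
    t0 <- proc.time()[["elapsed"]]
    rec <- simulate_session(config, labels[i], manifest$seed[i], montage)
    manifest$gen_seconds[i] <- proc.time()[["elapsed"]] - t0
    rec$meta$patient_id <- manifest$patient_id[i]
    rec$meta$contact_id <- manifest$session_id[i]
    manifest$latency_shift_ms[i] <- rec$meta$latency_shift_ms
    manifest$amplitude_gain[i] <- rec$meta$amplitude_gain
    if (!is.null(out_dir)) {
      write_recording(rec, file.path(out_dir, paste0(manifest$session_id[i], ".edf")),
                      file.path(out_dir, paste0(manifest$session_id[i], "_events.tsv")))
    }
    sessions[[i]] <- if (is.null(action)) rec else action(rec, manifest[i, ])
    if (!is.null(action)) rm(rec)
  }
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(manifest = manifest, sessions = sessions)
}
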