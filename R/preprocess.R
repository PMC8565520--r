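#' Subtract the DC offset from every channel
#'
#' @param rec an `eeg_recording`.
#' @return The recording with per-channel mean removed.
#' @export
remove_dc <- function(rec) {
  rec$data <- center_columns(rec$data)
  rec
}

#' Detect stimulus artifacts on the channel-mean signal
#'
#' The DBS pulse is synchronous across the scalp, so detection runs on the
#' across-channel mean m(t): samples with |m - mean(m)| above
#' `threshold_sd` SDs of m are flagged, flagged runs are extended by
#' `margin_ms` on both sides, and overlapping runs are merged.
#'
#' @param rec an `eeg_recording` (DC already removed).
#' @param threshold_sd detection threshold in SDs (default 3).
#' @param margin_ms run extension in ms (default 2).
#' @return Data frame of half-open spans: `start_sample`, `end_sample`
#'   (0-based), `peak_abs_value`; sorted, non-overlapping.
#' @export
detect_stim_artifacts <- function(rec, threshold_sd = 3, margin_ms = 2) {
  if (nrow(rec$data) == 0L) stopf("empty recording")
  m <- rowMeans(rec$data)
  dev <- abs(m - mean(m))
  flag <- dev > threshold_sd * stats::sd(m)
  if (!any(flag)) {
    return(data.frame(start_sample = integer(0), end_sample = integer(0),
                      peak_abs_value = numeric(0)))
  }
  margin <- ms_to_samples(margin_ms, rec$fs)
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])     # 1-based inclusive
  s <- pmax(runs[, 1] - margin, 1L)
  e <- pmin(runs[, 2] + margin, length(m))
  # merge overlapping/adjacent extended runs
  ms_ <- integer(0); me_ <- integer(0)
  cs <- s[1]; ce <- e[1]
  if (length(s) > 1) {
    for (i in 2:length(s)) {
      if (s[i] <= ce + 1L) {
        ce <- max(ce, e[i])
      } else {
        ms_ <- c(ms_, cs); me_ <- c(me_, ce)
        cs <- s[i]; ce <- e[i]
      }
    }
  }
  ms_ <- c(ms_, cs); me_ <- c(me_, ce)
  peak <- vapply(seq_along(ms_), function(i) max(dev[ms_[i]:me_[i]]), 1.0)
  data.frame(start_sample = ms_ - 1L, end_sample = me_,  # half-open, 0-based
             peak_abs_value = peak)
}

#' Replace artifact spans by first-degree polynomial interpolation
#'
#' Within each span every channel is replaced by the straight line joining
#' the last clean sample before and the first clean sample after the span;
#' samples outside spans are untouched. Spans touching a recording boundary
#' are filled by holding the available anchor, with a warning.
#'
#' @param rec an `eeg_recording`.
#' @param spans artifact spans from [detect_stim_artifacts()].
#' @return The interpolated recording.
#' @export
interpolate_artifacts <- function(rec, spans) {
  if (!nrow(spans)) return(rec)
  n <- nrow(rec$data)
  if (any(spans$start_sample < 0 | spans$end_sample > n |
            spans$start_sample >= spans$end_sample)) {
    stopf("invalid artifact spans")
  }
  boundary <- FALSE
  for (i in seq_len(nrow(spans))) {
    a <- spans$start_sample[i]        # 0-based anchor before = sample a-1
    b <- spans$end_sample[i]          # first clean sample after = b (0-based)
    len <- b - a
    if (a == 0L && b == n) {
      boundary <- TRUE
      rec$data[, ] <- 0
    } else if (a == 0L) {
      boundary <- TRUE
      rec$data[1:len, ] <- rep(rec$data[b + 1L, ], each = len)
    } else if (b == n) {
      boundary <- TRUE
      rec$data[(a + 1L):n, ] <- rep(rec$data[a, ], each = n - a)
    } else {
      left <- rec$data[a, ]
      right <- rec$data[b + 1L, ]
      w <- seq_len(len) / (len + 1)
      rec$data[(a + 1L):b, ] <- (1 - w) %o% left + w %o% right
    }
  }
  if (boundary) warnf("span touching the recording boundary: hold-value fill")
  rec
}

#' Re-reference every sample to the average of all channels
#'
#' @param rec an `eeg_recording`.
#' @return The recording with zero across-channel mean at every sample.
#' @export
rereference_average <- function(rec) {
  rec$data <- subtract_row_means(rec$data)
  rec
}

# Windowed-sinc (Hamming) band-pass kernel; odd length chosen from the
# narrower (low-edge) transition width.
fir_bandpass_kernel <- function(fs, low, high, transition_hz = 0.5) {
  ntaps <- ceiling(3.3 * fs / transition_hz)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  signal::fir1(ntaps - 1, c(low, high) / (fs / 2), type = "pass")
}

# Zero-phase (forward-backward) FIR filtering via FFT: multiplying the
# spectrum by |H|^2 equals filtering with h forwards then backwards.
# Edges are reflection-padded over the kernel length; two channels are
# filtered per FFT by complex packing. `data` is samples x channels.
filtfilt_fft <- function(data, h, fs) {
  nsamp <- nrow(data); nch <- ncol(data)
  L <- length(h)
  if (nsamp <= L) stopf("recording shorter than the filter kernel")
  nfft <- stats::nextn(nsamp + 2L * L, c(2, 3, 5))
  H2 <- Mod(stats::fft(c(h, rep(0, nfft - L))))^2
  pre <- L:1; post <- nsamp:(nsamp - L + 1L)
  zeros <- rep(0, nfft - nsamp - 2L * L)
  keep <- (L + 1L):(L + nsamp)
  out <- matrix(0, nsamp, nch)
  for (p in seq_len(ceiling(nch / 2))) {
    c1 <- 2L * p - 1L
    x1 <- data[, c1]
    x2 <- if (c1 + 1L <= nch) data[, c1 + 1L] else numeric(nsamp)
    z <- complex(real = c(x1[pre], x1, x1[post], zeros),
                 imaginary = c(x2[pre], x2, x2[post], zeros))
    y <- (stats::fft(stats::fft(z) * H2, inverse = TRUE) / nfft)[keep]
    out[, c1] <- Re(y)
    if (c1 + 1L <= nch) out[, c1 + 1L] <- Im(y)
  }
  out
}

#' Two-way (zero-phase) FIR band-pass filter
#'
#' Windowed-sinc FIR applied forwards and backwards (zero phase, squared
#' magnitude response): pass-band gain within 5% at 10 Hz, stop-band
#' attenuation far beyond 20 dB at DC and 60 Hz with the default band.
#'
#' @param rec an `eeg_recording`.
#' @param low,high band edges in Hz (defaults 0.5 and 40).
#' @param transition_hz transition width controlling the kernel length.
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, low = 0.5, high = 40, transition_hz = 0.5) {
  if (high >= rec$fs / 2) stopf("high edge must be below Nyquist (%g Hz)", rec$fs / 2)
  if (low <= 0 || low >= high) stopf("invalid band: [%g, %g]", low, high)
  h <- fir_bandpass_kernel(rec$fs, low, high, transition_hz)
  rec$data <- filtfilt_fft(rec$data, h, rec$fs)
  rec
}

#' Run the full cleaning chain
#'
#' DC removal, artifact detection + linear interpolation, average
#' re-reference, zero-phase band-pass — in that order.
#'
#' @param rec an `eeg_recording`.
#' @param config a [pipeline_config()].
#' @param channels_out optional channel subset to keep after re-referencing
#'   (re-reference and artifact detection always use all channels); the
#'   band-pass then runs on the subset only. Useful when only a few ROI
#'   members are analysed downstream.
#' @return List: `recording` (cleaned) and `spans` (detected artifacts).
#' @export
preprocess_recording <- function(rec, config = pipeline_config(),
                                 channels_out = NULL) {
  rec <- remove_dc(rec)
  spans <- detect_stim_artifacts(rec, config$artifact_threshold_sd,
                                 config$artifact_margin_ms)
  rec <- interpolate_artifacts(rec, spans)
  rec <- rereference_average(rec)
  if (!is.null(channels_out)) {
    keep <- match(channels_out, rec$channel_names)
    if (anyNA(keep)) stopf("unknown channel(s) in channels_out")
    rec$data <- rec$data[, keep, drop = FALSE]
    rec$channel_names <- rec$channel_names[keep]
  }
  rec <- bandpass_filter(rec, config$filter_band[1], config$filter_band[2])
  list(recording = rec, spans = spans)
}
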