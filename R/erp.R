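#' Segment a recording into stimulus-locked epochs
#'
#' Epoch window is half-open in ms (`[-50, 150)` by default: exactly 200
#' samples at 1 kHz); t = 0 is the stimulus-onset sample. Events whose full
#' window does not fit inside the recording are dropped and counted.
#'
#' @param rec a cleaned `eeg_recording` with events.
#' @param window_ms half-open epoch span relative to onset (ms).
#' @param channels optional channel-name subset to epoch.
#' @return An `eeg_epochs` object: `data` (samples x trials x channels),
#'   `times_ms`, `fs`, `onsets`, `n_dropped`, `channel_names`, `meta`.
#' @export
extract_epochs <- function(rec, window_ms = c(-50, 150), channels = NULL) {
  if (!nrow(rec$events)) stopf("no events to epoch")
  fs <- rec$fs
  rel <- ms_to_samples(window_ms[1], fs):(ms_to_samples(window_ms[2], fs) - 1L)
  n <- nrow(rec$data)
  onsets <- rec$events$onset_sample
  ok <- onsets + rel[1] >= 0L & onsets + rel[length(rel)] < n
  n_dropped <- sum(!ok)
  onsets <- onsets[ok]
  if (!length(onsets)) stopf("no event supports a full epoch window")
  cols <- if (is.null(channels)) seq_len(ncol(rec$data)) else {
    match(channels, rec$channel_names)
  }
  if (anyNA(cols)) stopf("unknown channel(s) requested")
  idx <- as.vector(outer(rel, onsets, "+")) + 1L
  arr <- array(rec$data[idx, cols, drop = FALSE],
               c(length(rel), length(onsets), length(cols)))
  structure(
    list(data = arr, times_ms = samples_to_ms(rel, fs), fs = fs,
         onsets = onsets, n_dropped = n_dropped,
         channel_names = rec$channel_names[cols], meta = rec$meta),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples [%g, %g) ms (%d dropped)\n",
              d[2], d[3], d[1], min(x$times_ms), max(x$times_ms) + 1000 / x$fs,
              x$n_dropped))
  invisible(x)
}

#' Average epochs into an evoked response potential
#'
#' Per-sample arithmetic mean across trials, with the standard error
#' SD/sqrt(n) (sample SD, n - 1 denominator).
#'
#' @param epochs an `eeg_epochs`.
#' @return An `eeg_erp`: `data` and `se` (channels x samples), `n_trials`,
#'   `times_ms`, `fs`, `channel_names`, `meta`.
#' @export
average_epochs <- function(epochs) {
  d <- dim(epochs$data)
  n <- d[2]
  if (n < 1L) stopf("need at least one trial")
  nch <- d[3]
  m <- matrix(0, nch, d[1])          # ERP stays channels x samples (small)
  se <- matrix(0, nch, d[1])
  for (ch in seq_len(nch)) {
    M <- epochs$data[, , ch]
    if (n == 1L) {
      m[ch, ] <- M
    } else {
      mu <- rowMeans(M)
      m[ch, ] <- mu
      s2 <- (rowSums(M^2) - n * mu^2) / (n - 1)
      se[ch, ] <- sqrt(pmax(s2, 0) / n)
    }
  }
  structure(
    list(data = m, se = se, n_trials = n, times_ms = epochs$times_ms,
         fs = epochs$fs, channel_names = epochs$channel_names,
         meta = epochs$meta),
    class = "eeg_erp")
}

#' @export
print.eeg_erp <- function(x, ...) {
  cat(sprintf("<eeg_erp> %d channels x %d samples, average of %d trials\n",
              nrow(x$data), ncol(x$data), x$n_trials))
  invisible(x)
}

#' Z-score an ERP per channel over its time course
#'
#' @param erp an `eeg_erp`.
#' @return The ERP with every channel standardised to mean 0, SD 1 over the
#'   epoch; errors on zero-variance channels, naming them.
#' @export
zscore_erp <- function(erp) {
  s <- apply(erp$data, 1, stats::sd)
  flat <- which(s == 0)
  if (length(flat)) {
    stopf("zero-variance channel(s): %s",
          paste(erp$channel_names[flat], collapse = ", "))
  }
  mu <- rowMeans(erp$data)
  erp$data <- (erp$data - mu) / s
  erp$se <- erp$se / s
  erp
}

#' Reduce channels to the nine ROI virtual channels
#'
#' Each ROI trace is the unweighted mean of its member channels; output
#' order is fixed to [roi_names()]. Works on ERPs and on epochs (trial by
#' trial).
#'
#' @param x an `eeg_erp` or `eeg_epochs`.
#' @param roi_map named list mapping ROI name -> member channels (e.g.
#'   `make_montage(64)$roi_map`).
#' @param rois which ROIs to produce (default all nine).
#' @return Object of the same class over ROI virtual channels.
#' @export
roi_average <- function(x, roi_map, rois = roi_names()) {
  missing_rois <- setdiff(rois, names(roi_map))
  if (length(missing_rois)) {
    stopf("ROI(s) not in map: %s", paste(missing_rois, collapse = ", "))
  }
  if (any(lengths(roi_map[rois]) == 0L)) stopf("empty ROI in map")
  A <- matrix(0, length(rois), length(x$channel_names),
              dimnames = list(rois, x$channel_names))
  for (r in rois) {
    idx <- match(roi_map[[r]], x$channel_names)
    if (anyNA(idx)) stopf("ROI %s refers to channels absent from the data", r)
    A[r, idx] <- 1 / length(idx)
  }
  if (inherits(x, "eeg_erp")) {
    x$data <- A %*% x$data
    x$se <- sqrt(A^2 %*% x$se^2)       # SE of a mean of independent traces
  } else if (inherits(x, "eeg_epochs")) {
    d <- dim(x$data)                   # samples x trials x channels
    flat <- matrix(x$data, d[1] * d[2], d[3])
    x$data <- array(flat %*% t(A), c(d[1], d[2], length(rois)))
  } else {
    stopf("roi_average handles eeg_erp or eeg_epochs")
  }
  x$channel_names <- rois
  x
}

#' Across-session grand average
#'
#' Mean and standard error over sessions, per channel (or ROI) and sample.
#'
#' @param erps list of `eeg_erp` objects on identical windows and channels.
#' @return An `eeg_group_erp`: `data`, `se`, `n_sessions`, `times_ms`,
#'   `channel_names`.
#' @export
group_average <- function(erps) {
  if (!length(erps)) stopf("no ERPs supplied")
  ref <- erps[[1]]
  for (e in erps) {
    if (!identical(dim(e$data), dim(ref$data)) ||
        !identical(e$channel_names, ref$channel_names) ||
        !isTRUE(all.equal(e$times_ms, ref$times_ms))) {
      stopf("sessions have mismatched channels or windows")
    }
  }
  n <- length(erps)
  stack <- vapply(erps, function(e) e$data, ref$data)
  m <- rowMeans(stack, dims = 2)
  se <- if (n > 1L) {
    s2 <- (rowSums(stack^2, dims = 2) - n * m^2) / (n - 1)
    sqrt(pmax(s2, 0) / n)
  } else {
    matrix(0, nrow(m), ncol(m))
  }
  structure(
    list(data = m, se = se, n_sessions = n, times_ms = ref$times_ms,
         channel_names = ref$channel_names),
    class = "eeg_group_erp")
}

#' Export a grand-average as a long CSV for topographic plotting
#'
#' One row per (time, channel) with mean and SE; external tools can render
#' scalp maps from it together with the montage positions.
#'
#' @param group an `eeg_group_erp`.
#' @param path CSV path.
#' @export
write_group_erp_csv <- function(group, path) {
  df <- data.frame(
    time_ms = rep(group$times_ms, each = length(group$channel_names)),
    channel = rep(group$channel_names, times = length(group$times_ms)),
    mean = as.vector(group$data), se = as.vector(group$se))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Fused epoch-and-average: computes the same ERP as
# average_epochs(extract_epochs(rec, window_ms)) channel by channel,
# without materialising the full trial tensor (the tensor of a 2,400-trial
# 64-channel session is ~250 MB). Equivalence is covered by tests.
session_erp <- function(rec, window_ms = c(-50, 150)) {
  if (!nrow(rec$events)) stopf("no events to epoch")
  fs <- rec$fs
  rel <- ms_to_samples(window_ms[1], fs):(ms_to_samples(window_ms[2], fs) - 1L)
  nsamp <- nrow(rec$data)
  onsets <- rec$events$onset_sample
  ok <- onsets + rel[1] >= 0L & onsets + rel[length(rel)] < nsamp
  onsets <- onsets[ok]
  if (!length(onsets)) stopf("no event supports a full epoch window")
  n <- length(onsets)
  st <- epoch_mean_se(rec$data, as.integer(onsets), rel[1], length(rel))
  structure(
    list(data = st$mean, se = st$se, n_trials = n,
         times_ms = samples_to_ms(rel, fs), fs = fs,
         channel_names = rec$channel_names, meta = rec$meta),
    class = "eeg_erp")
}

# Scalar feature of an ERP trace used by the stability analysis.
trace_feature <- function(trace, times_ms, window, kind) {
  sel <- which(times_ms >= window[1] & times_ms < window[2])
  if (!length(sel)) stopf("empty feature window")
  seg <- trace[sel]
  if (all(seg == seg[1]) && kind %in% c("max_latency", "min_latency")) {
    stopf("flat window: latency feature undefined")
  }
  switch(kind,
         max_amp = max(seg),
         min_amp = min(seg),
         max_latency = times_ms[sel[which.max(seg)]],
         min_latency = times_ms[sel[which.min(seg)]],
         stopf("unsupported stability feature '%s'", kind))
}

#' Trial-count stability of an ERP feature
#'
#' Computes the feature on the first-N-trial average for each N of the
#' grid, then finds the smallest N from which every estimate (including
#' larger grid values and the full-trial estimate) stays within
#' `tolerance_ms` of the full-trial estimate.
#'
#' @param epochs an `eeg_epochs` (typically a single ROI virtual channel,
#'   see [roi_average()]).
#' @param location channel/ROI name to analyse.
#' @param window half-open window in ms (default the 50-100 ms middle
#'   window).
#' @param kind `"max_latency"` (default), `"min_latency"`, `"max_amp"` or
#'   `"min_amp"`.
#' @param n_grid increasing trial counts to evaluate.
#' @param tolerance tolerance on the feature (ms for latencies).
#' @return List: `n_grid`, `estimate` (per N), `full_estimate`, `n_stable`
#'   (NA when never stable within the grid), `stable` flag.
#' @export
stability_curve <- function(epochs, location, window = c(50, 100),
                            kind = "max_latency",
                            n_grid = seq(100, dim(epochs$data)[2], by = 100),
                            tolerance = 2) {
  n_tot <- dim(epochs$data)[2]
  if (is.unsorted(n_grid, strictly = TRUE) || max(n_grid) > n_tot) {
    stopf("n_grid must be strictly increasing and within the trial count")
  }
  ch <- match(location, epochs$channel_names)
  if (is.na(ch)) stopf("unknown location '%s'", location)
  tr <- epochs$data[, , ch]                 # samples x trials
  csum <- t(apply(tr, 1, cumsum))          # samples x trials running sums
  est <- vapply(n_grid, function(N) {
    trace_feature(csum[, N] / N, epochs$times_ms, window, kind)
  }, 1.0)
  full <- trace_feature(rowMeans(tr), epochs$times_ms, window, kind)
  ok <- abs(est - full) <= tolerance
  # smallest N such that this and all larger grid estimates stay within tol
  stable_from <- rev(cumprod(rev(ok))) == 1
  n_stable <- if (any(stable_from)) n_grid[which(stable_from)[1]] else NA_integer_
  list(n_grid = n_grid, estimate = est, full_estimate = full,
       n_stable = n_stable, stable = !is.na(n_stable), tolerance = tolerance,
       kind = kind, location = location, window = window)
}
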