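test_that("DC removal zeroes channel means and keeps variance", {
  rec <- toy_recording(n_samples = 2000, n_channels = 3)
  rec$data[, 2] <- rec$data[, 2] + 7
  out <- remove_dc(rec)
  expect_close(colMeans(out$data), rep(0, 3), 1e-10)
  expect_close(apply(out$data, 2, var), apply(rec$data, 2, var), 1e-10)
  # constant channel -> zeros; pure sinusoid + offset -> sinusoid
  cst <- recording(matrix(7, 100, 1), 1000, "E1")
  expect_true(all(remove_dc(cst)$data == 0))
  tt <- (0:999) / 1000
  s <- sin(2 * pi * 10 * tt)
  out2 <- remove_dc(recording(matrix(s + 3, 1000, 1), 1000, "E1"))
  expect_close(out2$data[, 1], s - mean(s), 1e-9)
  # idempotent
  expect_close(remove_dc(out)$data, out$data, 1e-12)
})

test_that("artifact detection flags spikes and nothing in bounded noise", {
  # uniform noise never exceeds 1.74 SD, so a 3 SD threshold stays silent
  set.seed(4)
  un <- remove_dc(recording(matrix(runif(5000, -1, 1), 5000, 1), 1000, "E1"))
  expect_identical(nrow(detect_stim_artifacts(un)), 0L)

  set.seed(5)
  x <- matrix(rnorm(5000 * 2), 5000, 2)
  x[1001, ] <- x[1001, ] + 40; x[2001, ] <- x[2001, ] + 40
  sp <- detect_stim_artifacts(remove_dc(recording(x, 1000)))
  expect_identical(nrow(sp), 2L)
  expect_true(sp$start_sample[1] <= 1000 && sp$end_sample[1] > 1000)
  expect_true(sp$start_sample[2] <= 2000 && sp$end_sample[2] > 2000)

  # degenerate threshold flags the whole recording as one span
  all_sp <- detect_stim_artifacts(un, threshold_sd = 0)
  expect_identical(nrow(all_sp), 1L)
  expect_identical(all_sp$start_sample, 0L)
  expect_identical(all_sp$end_sample, 5000L)

  empty <- recording(matrix(numeric(0), 0, 1), 1000, "E1")
  expect_error(detect_stim_artifacts(empty), "empty")
})

test_that("linear interpolation is exact on ramps and bounded by anchors", {
  ramp <- recording(matrix(seq_len(1000), 1000, 3) *
                      rep(c(1, -2, 0.5), each = 1000), 1000)
  sp <- data.frame(start_sample = c(100L, 400L), end_sample = c(120L, 430L),
                   peak_abs_value = 1)
  out <- interpolate_artifacts(ramp, sp)
  expect_close(out$data, ramp$data, 1e-9)

  set.seed(6)
  rec <- toy_recording(n_samples = 500, n_channels = 2)
  rec$data[201:210, ] <- 50      # spike inside the span
  sp2 <- data.frame(start_sample = 200L, end_sample = 210L,
                    peak_abs_value = 50)
  out2 <- interpolate_artifacts(rec, sp2)
  hi <- pmax(abs(rec$data[200, ]), abs(rec$data[211, ]))
  for (ch in 1:2) {
    expect_true(all(abs(out2$data[201:210, ch]) <= hi[ch] + 1e-12))
  }
  # untouched outside
  expect_identical(out2$data[-(201:210), ], rec$data[-(201:210), ])
  # empty span list is the identity
  expect_identical(interpolate_artifacts(rec, sp2[0, ]), rec)
  # boundary span falls back to hold-value with a warning
  spb <- data.frame(start_sample = 0L, end_sample = 10L, peak_abs_value = 1)
  expect_warning(outb <- interpolate_artifacts(rec, spb), "boundary")
  expect_close(outb$data[1:10, ], rep(rec$data[11, ], each = 10), 1e-12)
})

test_that("average re-reference zeroes the channel mean at every sample", {
  rec <- toy_recording(n_samples = 3000, n_channels = 64)
  out <- rereference_average(rec)
  expect_lt(max(abs(rowMeans(out$data))), 1e-9 * sd(rec$data))
  # idempotent
  expect_close(rereference_average(out)$data, out$data, 1e-12)
  # single channel -> all zeros; antisymmetric pair unchanged
  one <- toy_recording(n_samples = 100, n_channels = 1)
  expect_true(all(rereference_average(one)$data == 0))
  x <- rnorm(100)
  pair <- recording(cbind(x, -x), 1000, c("A", "B"))
  expect_close(rereference_average(pair)$data, pair$data, 1e-12)
})

test_that("the zero-phase band-pass meets its gain specification", {
  fs <- 1000; n <- 20000
  tt <- (0:(n - 1)) / fs
  mk <- function(x) recording(matrix(x, ncol = 1), fs, "E1")
  gain <- function(freq) {
    x <- sin(2 * pi * freq * tt)
    y <- bandpass_filter(mk(x))$data[, 1]
    mid <- 5000:15000
    sqrt(mean(y[mid]^2) / mean(x[mid]^2))
  }
  expect_lt(abs(gain(10) - 1), 0.05)
  expect_lt(gain(60), 0.1)
  dc <- bandpass_filter(mk(rep(1, n)))$data[5000:15000, 1]
  expect_lt(sqrt(mean(dc^2)), 0.1)
  # zero phase: a smooth pulse keeps its peak latency
  pulse <- exp(-(tt - 10)^2 / (2 * 0.05^2))
  y <- bandpass_filter(mk(pulse))$data[, 1]
  expect_lt(abs(which.max(y) - which.max(pulse)) / fs * 1000, 1)
  # invalid bands are refused
  expect_error(bandpass_filter(mk(rep(0, n)), low = 0.5, high = 600),
               "Nyquist")
})

test_that("cleaning keeps the evoked waveform and silences former spans", {
  cfg <- short_sim(duration = 20)
  pc <- pipeline_config()
  # noiseless session: cleaning must not distort the 5-149 ms ERP by > 5% RMS
  cfg0 <- cfg
  cfg0$noise[c("pink_sd", "white_sd", "alpha_sd")] <- list(0, 0, 0)
  cfg0$latency_jitter_sd[] <- 0
  cfg0$amplitude_gain_range <- c(1, 1)
  rec0 <- simulate_session(cfg0, "ZI", seed = 21)
  raw_nostim <- cfg0
  raw_nostim$artifact$amplitude_uv <- 0
  ref <- simulate_session(raw_nostim, "ZI", seed = 21)
  erp_clean <- stnerp:::session_erp(preprocess_recording(rec0, pc)$recording)
  erp_ref <- stnerp:::session_erp(rereference_average(ref))
  keep <- erp_ref$times_ms >= 5 & erp_ref$times_ms <= 149
  num <- sqrt(mean((erp_clean$data[, keep] - erp_ref$data[, keep])^2))
  expect_lt(num / sqrt(mean(erp_ref$data[, keep]^2)), 0.05)

  # order fidelity: once interpolated, the detector finds nothing anymore,
  # and no former-span sample exceeds the recomputed threshold (after the
  # average reference the channel mean is identically zero, so the check
  # is made at the interpolation stage where it is non-degenerate)
  rec <- simulate_session(cfg, "DLR", seed = 22)
  dc <- remove_dc(rec)
  spans <- detect_stim_artifacts(dc, pc$artifact_threshold_sd)
  expect_identical(nrow(spans), nrow(rec$events))
  interp <- interpolate_artifacts(dc, spans)
  m <- rowMeans(interp$data)
  thr <- 3 * sd(m)
  inside <- unlist(mapply(function(s, e) (s + 1L):e, spans$start_sample,
                          spans$end_sample, SIMPLIFY = FALSE))
  expect_true(all(abs(m[inside] - mean(m)) <= thr))
  # re-detection may fire on genuine evoked peaks (the detector cannot
  # tell physiology from artifact) but never inside the former spans
  redet <- detect_stim_artifacts(interp, pc$artifact_threshold_sd)
  if (nrow(redet)) {
    overlap <- outer(redet$start_sample, spans$end_sample, "<") &
      outer(redet$end_sample, spans$start_sample, ">")
    expect_false(any(overlap))
  }
  # and the full chain leaves the channel mean at exact zero by construction
  cl <- preprocess_recording(rec, pc)
  expect_lt(max(abs(rowMeans(cl$recording$data))), 1e-9)
})
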