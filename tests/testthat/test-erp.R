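test_that("epoching respects the half-open window and drops partial events", {
  rec <- toy_recording(n_samples = 2000, n_channels = 3,
                       events = data.frame(
                         onset_sample = c(10L, 500L, 1000L, 1900L),
                         label = "stim"))
  ep <- extract_epochs(rec)          # [-50, 150) needs 50 before, 150 after
  expect_identical(dim(ep$data), c(200L, 2L, 3L))
  expect_identical(ep$n_dropped, 2L) # onset 10 (head) and 1900 (tail)
  expect_identical(ep$onsets, c(500L, 1000L))
  expect_identical(ep$times_ms, as.numeric(-50:149))
  # epoch content matches direct slicing
  expect_identical(ep$data[, 1, 2], rec$data[451:650, 2])
  # conservation: usable + dropped = total events
  expect_identical(dim(ep$data)[2] + ep$n_dropped, nrow(rec$events))
  expect_error(extract_epochs(toy_recording()), "no events")
})

test_that("averaging reproduces identical trials and obeys symmetry and linearity", {
  rec <- toy_recording(n_samples = 3000, n_channels = 2,
                       events = data.frame(onset_sample = c(500L, 1500L),
                                           label = "s"))
  rec$data[1451:1650, ] <- rec$data[451:650, ]      # identical trials
  erp <- average_epochs(extract_epochs(rec))
  expect_close(erp$data[1, ], rec$data[451:650, 1], 1e-12)
  expect_close(erp$se, matrix(0, 2, 200), 1e-12)
  expect_identical(erp$n_trials, 2L)

  # two trials (x, -x) cancel
  rec$data[1451:1650, ] <- -rec$data[451:650, ]
  erp2 <- average_epochs(extract_epochs(rec))
  expect_close(erp2$data, matrix(0, 2, 200), 1e-12)

  # linearity: avg(a * X) = a * avg(X)
  reca <- rec; reca$data <- 3.5 * reca$data
  erpa <- average_epochs(extract_epochs(reca))
  expect_close(erpa$data, 3.5 * erp2$data, 1e-9)
})

test_that("trial averaging recovers a template at the sqrt(N) noise rate", {
  set.seed(31)
  n_tr <- 400; len <- 200; sigma <- 1
  tpl <- 5 * exp(-((seq_len(len) - 120)^2) / (2 * 64))
  onsets <- 50L + seq_len(n_tr) * 200L
  data <- matrix(rnorm((n_tr + 2) * 200, sd = sigma), ncol = 1)
  for (o in onsets) data[(o - 49):(o + 150), 1] <-
    data[(o - 49):(o + 150), 1] + tpl
  rec <- recording(data, 1000, "E1",
                   events = data.frame(onset_sample = onsets, label = "s"))
  erp <- average_epochs(extract_epochs(rec))
  resid <- erp$data[1, ] - tpl
  expect_lt(abs(sqrt(mean(resid^2)) / (sigma / sqrt(n_tr)) - 1), 0.15)
})

test_that("the fused session ERP equals the epoch-then-average route", {
  rec <- simulate_session(short_sim(duration = 6), "VMR", seed = 8)
  a <- average_epochs(extract_epochs(rec))
  b <- stnerp:::session_erp(rec)
  expect_close(a$data, b$data, 1e-10)
  expect_close(a$se, b$se, 1e-10)
  expect_identical(a$n_trials, b$n_trials)
})

test_that("z-scoring standardises channels and is affine invariant", {
  erp <- average_epochs(extract_epochs(
    toy_recording(n_samples = 3000, n_channels = 3,
                  events = data.frame(onset_sample = c(500L, 1500L, 2500L),
                                      label = "s"))))
  z <- zscore_erp(erp)
  expect_close(rowMeans(z$data), rep(0, 3), 1e-10)
  expect_close(apply(z$data, 1, sd), rep(1, 3), 1e-10)
  shifted <- erp
  shifted$data <- 4 * shifted$data + 2
  expect_close(zscore_erp(shifted)$data, z$data, 1e-9)
  flat <- erp; flat$data[2, ] <- 5
  expect_error(zscore_erp(flat), "E2")
})

test_that("ROI averaging equals the brute-force member mean", {
  m <- make_montage(64)
  set.seed(33)
  erp <- structure(
    list(data = matrix(rnorm(64 * 200), 64, 200),
         se = matrix(abs(rnorm(64 * 200)), 64, 200), n_trials = 5,
         times_ms = -50:149, fs = 1000, channel_names = paste0("E", 1:64),
         meta = list()),
    class = "eeg_erp")
  rois <- roi_average(erp, m$roi_map)
  expect_identical(rois$channel_names, roi_names())
  for (r in roi_names()) {
    idx <- match(m$roi_map[[r]], erp$channel_names)
    expect_close(rois$data[match(r, roi_names()), ],
                 colMeans(erp$data[idx, , drop = FALSE]), 1e-10)
  }
  # identical members reproduce themselves; antisymmetric members cancel
  erp$data[match(m$roi_map$left_frontal, erp$channel_names), ] <-
    rep(erp$data[1, ], each = length(m$roi_map$left_frontal))
  expect_close(roi_average(erp, m$roi_map)$data[1, ], erp$data[1, ], 1e-10)
  expect_error(roi_average(erp, list(left_frontal = character(0))), "empty|not in map")
})

test_that("group averages match brute-force mean and SE", {
  set.seed(34)
  erps <- lapply(1:5, function(i) {
    structure(
      list(data = matrix(rnorm(9 * 200), 9, 200), se = matrix(0, 9, 200),
           n_trials = 10, times_ms = -50:149, fs = 1000,
           channel_names = roi_names(), meta = list()),
      class = "eeg_erp")
  })
  g <- group_average(erps)
  stack <- simplify2array(lapply(erps, `[[`, "data"))
  expect_close(g$data, apply(stack, c(1, 2), mean), 1e-10)
  expect_close(g$se, apply(stack, c(1, 2), sd) / sqrt(5), 1e-10)
  one <- group_average(erps[1])
  expect_close(one$data, erps[[1]]$data, 1e-12)
  expect_true(all(one$se == 0))
  same <- group_average(rep(erps[2], 4))
  expect_close(same$se, matrix(0, 9, 200), 1e-10)
  short <- erps[[1]]; short$data <- short$data[, 1:100]
  expect_error(group_average(list(erps[[1]], short)), "mismatched")
  # CSV export is long-format time x channel
  path <- tempfile(fileext = ".csv")
  write_group_erp_csv(g, path)
  back <- read.csv(path)
  expect_identical(nrow(back), 9L * 200L)
})

test_that("stability analysis finds the stabilisation trial count", {
  # noiseless: stable from the smallest grid value
  cfg <- short_sim(duration = 20)
  cfg$noise[c("pink_sd", "white_sd", "alpha_sd")] <- list(0, 0, 0)
  cfg$artifact$amplitude_uv <- 0
  rec <- simulate_session(cfg, "ZI", seed = 41)
  ep <- roi_average(extract_epochs(rec), make_montage(64)$roi_map,
                    "medial_fronto_central")
  st <- stability_curve(ep, "medial_fronto_central", n_grid = c(10, 50, 100))
  expect_identical(st$n_stable, 10)
  expect_true(st$stable)
  expect_close(st$estimate, rep(st$full_estimate, 3), 1e-9)

  # zero tolerance on noisy data: stable only at the full trial count (the
  # last grid point equals the full average) or flagged unstable
  recn <- simulate_session(short_sim(duration = 20), "ZI", seed = 42)
  epn <- roi_average(extract_epochs(recn), make_montage(64)$roi_map,
                     "medial_fronto_central")
  stn <- stability_curve(epn, "medial_fronto_central", kind = "max_amp",
                         n_grid = c(25, 50, 100), tolerance = 0)
  expect_true(is.na(stn$n_stable) || stn$n_stable == 100)
  st0 <- stability_curve(epn, "medial_fronto_central", kind = "max_amp",
                         n_grid = c(25, 50, 75), tolerance = 0)
  expect_true(is.na(st0$n_stable))
  expect_error(stability_curve(epn, "nowhere"), "unknown location")
})
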