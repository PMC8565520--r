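test_that("evoked templates peak at the configured region latencies", {
  cfg <- simulation_config()
  cases <- list(
    list("ZI", "medial_fronto_central", 77),
    list("DLR", "medial_fronto_central", 69),
    list("VMR", "medial_fronto_central", 67),
    list("ZI", "right_fronto_central", 73.5),
    list("DLR", "right_fronto_central", 62),
    list("VMR", "right_fronto_central", 64),
    list("DLR", "medial_occipital_parietal", 71),
    list("VMR", "medial_occipital_parietal", 92))
  for (cs in cases) {
    tpl <- make_evoked_template(cs[[1]], cs[[2]], cfg)
    t_ms <- attr(tpl, "times_ms")
    win <- t_ms >= 50 & t_ms < 100
    # peak on the 1 ms sample grid within half a sample of the configured
    # latency (73.5 ms falls between two grid points)
    expect_lte(abs(t_ms[win][which.max(tpl[win])] - cs[[3]]), 0.5,
               label = paste(cs[[1]], cs[[2]]))
  }
})

test_that("the left frontal area carries a null topography", {
  cfg <- simulation_config()
  ref <- max(abs(make_evoked_template("ZI", "medial_fronto_central", cfg)))
  for (region in c("ZI", "DLR", "VMR")) {
    tpl <- make_evoked_template(region, "left_frontal", cfg)
    expect_lt(max(abs(tpl)), 0.05 * ref)
  }
})

test_that("zero amplitudes give a zero template; unknown names error", {
  cfg <- simulation_config()
  cfg$templates$amplitude_uv <- 0
  expect_true(all(make_evoked_template("ZI", "medial_frontal", cfg) == 0))
  expect_error(make_evoked_template("XX", "medial_frontal", cfg), "region")
  expect_error(make_evoked_template("ZI", "nowhere", cfg), "ROI")
})

test_that("pulse trains carry one event per stimulus for both protocols", {
  r5 <- simulate_session(short_sim(duration = 20), "ZI", seed = 1)
  expect_identical(nrow(r5$events), 100L)          # 5 Hz x 20 s
  r3 <- simulate_session(short_sim(stim_freq = 3, duration = 10), "DLR",
                         seed = 1)
  expect_identical(nrow(r3$events), 30L)           # 3 Hz x 10 s
  # every onset inside the recording with room for a full epoch
  expect_true(all(r5$events$onset_sample + 150 < nrow(r5$data)))
})

test_that("the noiseless, artifact-free session is exactly the tiled template", {
  cfg <- short_sim(duration = 10)
  cfg$noise[c("pink_sd", "white_sd", "alpha_sd")] <- list(0, 0, 0)
  cfg$artifact$amplitude_uv <- 0
  cfg$latency_jitter_sd[] <- 0
  cfg$amplitude_gain_range <- c(1, 1)
  rec <- simulate_session(cfg, "ZI", seed = 9)
  ep <- extract_epochs(rec)
  m <- make_montage(64)
  # medial fronto-central ROI trace equals the weighted template mix
  roi_ep <- roi_average(ep, m$roi_map, "medial_fronto_central")
  tpl <- make_evoked_template("ZI", "medial_fronto_central", cfg)
  t_ms <- attr(tpl, "times_ms")
  post <- t_ms >= 0
  # post-onset, every epoch is identical in the noiseless limit (the
  # pre-onset window of later epochs carries the previous pulse's tail)
  spread <- apply(roi_ep$data[post, , 1], 1, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-9)
  pre_spread <- apply(roi_ep$data[!post, -1, 1], 1,
                      function(x) diff(range(x)))
  expect_lt(max(pre_spread), 1e-9)
  # and the post-onset shape matches the template up to the ROI weighting
  trace <- roi_ep$data[, 1, 1]
  w <- sum(stnerp:::roi_channel_weights(m)["medial_fronto_central", ]) /
    length(m$roi_map$medial_fronto_central)
  # the ROI average mixes in neighbouring ROI spill; compare peak location
  win <- t_ms >= 50 & t_ms < 100
  expect_equal(t_ms[win][which.max(trace[win])], 77)
  expect_gt(max(trace[post]), 0.5 * w * max(tpl))
})

test_that("cohort generation yields labelled, deterministic sessions", {
  cfg <- short_sim(duration = 4)
  cfg$cohort_counts <- c(ZI = 2, DLR = 1, VMR = 1)
  got <- simulate_cohort(cfg, action = function(rec, info) {
    list(region = rec$meta$region_label, sum = sum(rec$data[1:100, 1]))
  })
  expect_identical(nrow(got$manifest), 4L)
  expect_identical(sort(table(got$manifest$region), decreasing = TRUE),
                   sort(table(c("ZI", "ZI", "DLR", "VMR")), decreasing = TRUE))
  again <- simulate_cohort(cfg, action = function(rec, info) {
    list(region = rec$meta$region_label, sum = sum(rec$data[1:100, 1]))
  })
  expect_identical(vapply(got$sessions, `[[`, 1.0, "sum"),
                   vapply(again$sessions, `[[`, 1.0, "sum"))

  one <- simulate_cohort(
    simulation_config(duration = 4,
                      cohort_counts = c(ZI = 1, DLR = 0, VMR = 0)),
    action = function(rec, info) info$region)
  expect_identical(length(one$sessions), 1L)
})

test_that("background spectrum decreases over 1-40 Hz apart from the alpha bump", {
  cfg <- short_sim(duration = 60)
  cfg$templates$amplitude_uv <- 0
  cfg$artifact$amplitude_uv <- 0
  rec <- simulate_session(cfg, "ZI", seed = 11)
  sp <- spec.pgram(ts(rec$data[, 1], frequency = 1000), spans = 51,
                   plot = FALSE, taper = 0)
  f <- sp$freq
  bands <- list(c(1, 2), c(2, 4), c(4, 7.5), c(13, 20), c(20, 40))
  pw <- vapply(bands, function(b) mean(sp$spec[f >= b[1] & f < b[2]]), 1.0)
  expect_true(all(diff(pw) < 0))
  # alpha bump: 8-12 Hz power above both neighbours
  alpha <- mean(sp$spec[f >= 8 & f < 12])
  expect_gt(alpha, mean(sp$spec[f >= 13 & f < 17]))
})

test_that("trial-averaged background noise follows the 1/sqrt(N) law", {
  cfg <- short_sim(duration = 90)
  cfg$templates$amplitude_uv <- 0
  cfg$artifact$amplitude_uv <- 0
  rec <- simulate_session(cfg, "ZI", seed = 5)
  ep <- extract_epochs(rec)
  rms_at <- function(N) {
    m <- apply(ep$data[, seq_len(N), , drop = FALSE], c(1, 3), mean)
    sqrt(mean(m^2))
  }
  r <- vapply(c(25, 100, 400), rms_at, 1.0)
  expect_lt(abs(r[1] / r[2] - 2), 0.2)
  expect_lt(abs(r[2] / r[3] - 2), 0.2)
})

test_that("the stimulus artifact dominates the background at onset", {
  cfg <- short_sim(duration = 10)
  rec <- simulate_session(cfg, "VMR", seed = 2)
  m <- rowMeans(rec$data)
  on <- rec$events$onset_sample + 1L
  bg <- sd(m[-unique(as.vector(outer(-2:3, on, "+")))])
  expect_true(all(abs(m[on]) > 3 * bg))
})
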