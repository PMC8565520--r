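# Small-scale simulation settings for fast tests: identical physics to the
# study-scale defaults, shorter pulse trains.
short_sim <- function(duration = 20, ...) {
  simulation_config(duration = duration, ...)
}

# A tiny multi-channel recording with known content.
toy_recording <- function(n_samples = 1000, n_channels = 4, fs = 1000,
                          sd = 1, seed = 1, events = NULL) {
  set.seed(seed)
  recording(matrix(rnorm(n_samples * n_channels, sd = sd),
                   n_samples, n_channels), fs,
            paste0("E", seq_len(n_channels)), events = events)
}

# Feature table with a planted group difference on one column.
toy_feature_table <- function(n_per = 10, delta = 2, p = 5, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  x <- matrix(rnorm(n * p), n, p)
  x[, 1] <- x[, 1] + rep(c(0, delta), each = n_per)
  colnames(x) <- paste0("f", seq_len(p))
  data.frame(session_id = sprintf("S%02d", seq_len(n)),
             region = rep(c("ZI", "VMR"), each = n_per),
             seed = seq_len(n), x, check.names = FALSE)
}
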