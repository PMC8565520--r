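#' @keywords internal
"_PACKAGE"

# Milliseconds -> 0-based sample offset (half-open interval convention).
ms_to_samples <- function(ms, fs) as.integer(round(ms * fs / 1000))

samples_to_ms <- function(samples, fs) samples * 1000 / fs

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Per-session seed derived from a master seed; kept inside 32-bit range.
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 10007 + index) %% 2147483647L)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @useDynLib stnerp, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL
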