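# Independent brute-force oracles used to cross-check the analysis code.

# AUC as the Mann-Whitney pairwise probability, by exhaustive pair
# counting; ties count one half.
auc_paircount <- function(values, labels, positive) {
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# Equal-frequency 3-bin discretisation, written independently of the
# package (same definition: thirds of the average-rank range).
bin3_oracle <- function(x) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  cut(r, breaks = c(-Inf, n / 3, 2 * n / 3, Inf), labels = FALSE)
}

# Mutual information via entropies of table() counts (nats).
mi_oracle <- function(a, b) {
  ent <- function(tab) {
    p <- tab[tab > 0] / sum(tab)
    -sum(p * log(p))
  }
  ent(table(a)) + ent(table(b)) - ent(table(a, b))
}

# Brute-force greedy MRMR (MID criterion) over all candidate features at
# every step.
mrmr_oracle <- function(x, labels, k) {
  x <- as.matrix(x)
  B <- apply(x, 2, bin3_oracle)
  y <- as.character(labels)
  p <- ncol(x)
  rel <- vapply(seq_len(p), function(j) mi_oracle(B[, j], y), 1.0)
  sel <- integer(0)
  for (step in seq_len(k)) {
    score <- rep(-Inf, p)
    for (j in setdiff(seq_len(p), sel)) {
      red <- if (length(sel)) {
        mean(vapply(sel, function(s) mi_oracle(B[, j], B[, s]), 1.0))
      } else 0
      score[j] <- rel[j] - red
    }
    sel <- c(sel, which(score >= max(score) - 1e-9)[1])
  }
  colnames(x)[sel]
}

expect_close <- function(object, expected, tol = 1e-8) {
  expect_lt(max(abs(object - expected)), tol)
}
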