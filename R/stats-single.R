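#' Two-sided independent t-test (pooled variance)
#'
#' Student's t with n_a + n_b - 2 degrees of freedom; a Welch variant is
#' available via `var_equal = FALSE`.
#'
#' @param a,b numeric group samples (each n >= 2).
#' @param var_equal pooled-variance Student test when `TRUE` (default).
#' @return List: `t`, `p`, `df`.
#' @export
ttest_independent <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L) stopf("each group needs n >= 2")
  res <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter))
}

#' ROC curve with Youden cutoff
#'
#' Threshold sweep over the unique feature values (rule: value >= cutoff is
#' called positive). Orientation is chosen so the area under the curve is
#' at least 0.5 (recorded in `direction`: `">="` or `"<="`). The cutoff
#' maximises Youden's J = TPR - FPR; ties resolve to the lower threshold,
#' and the reported cut sits at the midpoint of the value gap below the
#' winning threshold. AUC is the trapezoidal area, which equals the
#' Mann-Whitney pairwise probability with ties counted 1/2.
#'
#' @param values numeric feature values.
#' @param labels class labels, same length.
#' @param positive_class label treated as positive.
#' @return An object of class `roc_result`: `thresholds`, `tpr`, `fpr`,
#'   `auc`, `cutoff`, `direction`, `positive_class`.
#' @export
roc_curve <- function(values, labels, positive_class) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stopf("both classes must be present")
  if (!positive_class %in% labels) stopf("positive class absent")
  sweep_dir <- function(v) {
    thr <- sort(unique(v), decreasing = TRUE)
    pos <- labels == positive_class
    np <- sum(pos); nn <- sum(!pos)
    tp <- vapply(thr, function(th) sum(v >= th & pos), 1.0)
    fp <- vapply(thr, function(th) sum(v >= th & !pos), 1.0)
    tpr <- c(0, tp / np); fpr <- c(0, fp / nn)
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    list(thr = thr, tpr = tpr, fpr = fpr, auc = auc)
  }
  fwd <- sweep_dir(values)
  if (fwd$auc >= 0.5) {
    sw <- fwd; direction <- ">="
  } else {
    sw <- sweep_dir(-values); direction <- "<="
  }
  j <- sw$tpr[-1] - sw$fpr[-1]
  best <- which(j == max(j))
  # ties -> lower threshold; the cut itself sits at the midpoint of the
  # gap below the chosen threshold (generalises better than a cut placed
  # exactly on an observed value)
  k <- max(best)
  cut_w <- if (k < length(sw$thr)) (sw$thr[k] + sw$thr[k + 1]) / 2 else sw$thr[k]
  cutoff <- if (direction == ">=") cut_w else -cut_w
  structure(
    list(thresholds = if (direction == ">=") sw$thr else rev(-sw$thr),
         tpr = sw$tpr, fpr = sw$fpr, auc = sw$auc, cutoff = cutoff,
         direction = direction, positive_class = positive_class),
    class = "roc_result")
}

#' Classify values by a fitted ROC cutoff
#'
#' @param values numeric feature values.
#' @param roc a `roc_result`.
#' @param negative_class label for the complement.
#' @return Character vector of predicted labels.
#' @export
roc_classify <- function(values, roc, negative_class = "other") {
  hit <- if (roc$direction == ">=") values >= roc$cutoff else values <= roc$cutoff
  ifelse(hit, roc$positive_class, negative_class)
}

binary_metrics <- function(truth, pred, positive) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  accuracy <- mean(pred == truth)
  c(precision = precision, recall = recall, accuracy = accuracy)
}

# Seeded stratified k-fold assignment. Within every class fold counts
# differ by at most one; classes' remainders go to the currently
# least-loaded folds, keeping total fold sizes balanced too.
make_stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  load <- integer(k)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      n_c <- length(idx)
      cnt <- rep(n_c %/% k, k)
      extra <- n_c %% k
      if (extra > 0) {
        ord <- order(load, sample.int(k))
        cnt[ord[seq_len(extra)]] <- cnt[ord[seq_len(extra)]] + 1L
      }
      folds[idx] <- rep(seq_len(k), times = cnt)
      load <- load + cnt
    }
  })
  folds
}

summarize_folds <- function(mat) {
  list(mean = colMeans(mat), sd = apply(mat, 2, stats::sd), per_fold = mat)
}

#' Cross-validated single-feature cutoff classifier
#'
#' Stratified k-fold CV: the ROC cutoff (and orientation) is fitted on each
#' training fold and applied to the held-out fold; precision, recall,
#' accuracy and AUC are reported for train and test as mean +/- SD over
#' folds.
#'
#' @param values numeric feature values.
#' @param labels two-class labels.
#' @param positive_class label treated as positive (first-named region of a
#'   comparison, by convention).
#' @param k folds (default 5; reduced with a warning when a class is
#'   smaller than k).
#' @param seed fold-assignment seed.
#' @return A `cv_report` list: `train`, `test` (each mean/sd/per_fold),
#'   `folds`, `k`, `seed`, `positive_class`.
#' @export
cv_single_feature <- function(values, labels, positive_class, k = 5,
                              seed = 1) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L) stopf("single-feature CV is two-class")
  min_n <- min(table(labels))
  if (min_n < k) {
    warnf("class smaller than k; reducing folds to %d", min_n)
    k <- min_n
  }
  folds <- make_stratified_folds(labels, k, seed)
  negative <- setdiff(classes, positive_class)
  met <- c("precision", "recall", "accuracy", "auc")
  train_m <- matrix(NA_real_, k, 4, dimnames = list(NULL, met))
  test_m <- matrix(NA_real_, k, 4, dimnames = list(NULL, met))
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    roc <- roc_curve(values[tr], labels[tr], positive_class)
    pr_tr <- roc_classify(values[tr], roc, negative)
    pr_te <- roc_classify(values[te], roc, negative)
    auc_te <- roc_curve_auc_oriented(values[te], labels[te], positive_class,
                                     roc$direction)
    train_m[f, ] <- c(binary_metrics(labels[tr], pr_tr, positive_class),
                      roc$auc)
    test_m[f, ] <- c(binary_metrics(labels[te], pr_te, positive_class),
                     auc_te)
  }
  structure(
    list(train = summarize_folds(train_m), test = summarize_folds(test_m),
         folds = folds, k = k, seed = seed,
         positive_class = positive_class),
    class = "cv_report")
}

# Test-fold AUC with the orientation fixed on the training fold.
roc_curve_auc_oriented <- function(values, labels, positive_class, direction) {
  v <- if (direction == ">=") values else -values
  pos <- labels == positive_class
  if (!any(pos) || all(pos)) return(NA_real_)
  r <- rank(v)
  # Mann-Whitney from rank sums, ties counted 1/2
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}

#' @export
print.cv_report <- function(x, ...) {
  fmt <- function(s) paste(sprintf("%s %.2f (+/-%.2f)", names(s$mean),
                                   s$mean, s$sd), collapse = "  ")
  cat(sprintf("<cv_report> %d-fold, positive = %s\n  train: %s\n  test:  %s\n",
              x$k, x$positive_class %||% "", fmt(x$train), fmt(x$test)))
  invisible(x)
}
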