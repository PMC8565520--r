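# Equal-frequency discretisation into `bins` levels via average ranks:
# deterministic and invariant under strictly monotone transforms.
discretize_ef <- function(x, bins = 3L) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  b <- 1L
  for (q in seq_len(bins - 1L)) b <- b + (r > q * n / bins)
  as.integer(b)
}

# Mutual information (nats) between two integer codes with alphabet sizes
# na_ and nb_.
mi_disc <- function(a, b, na_, nb_) {
  p <- tabulate((a - 1L) * nb_ + b, na_ * nb_) / length(a)
  pm <- matrix(p, nb_, na_)              # rows: b, cols: a
  denom <- outer(rowSums(pm), colSums(pm))
  nz <- pm > 0
  sum(pm[nz] * log(pm[nz] / denom[nz]))
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy forward selection: the first feature maximises relevance (mutual
#' information between the discretised feature and the class label); each
#' later step maximises relevance minus the mean redundancy (mutual
#' information with the already-selected features) under the MID criterion,
#' or their quotient under MIQ. Features are discretised into
#' equal-frequency bins (3 by default), making the ranking invariant to
#' strictly monotone feature transforms and to feature column order.
#'
#' @param x numeric feature matrix or data frame (rows = sessions).
#' @param labels class labels.
#' @param k number of features to rank.
#' @param criterion `"MID"` (difference, default) or `"MIQ"` (quotient).
#' @param bins discretisation levels.
#' @return An `mrmr_ranking`: `features` (ordered keys), `relevance`,
#'   `redundancy` (mean MI with the prior selection, 0 for the first),
#'   `k`, `criterion`.
#' @export
mrmr_select <- function(x, labels, k, criterion = c("MID", "MIQ"),
                        bins = 3L) {
  criterion <- match.arg(criterion)
  x <- as.matrix(x)
  if (k < 1L || k > ncol(x)) stopf("k must be in [1, %d]", ncol(x))
  if (any(!is.finite(x))) stopf("features must be finite")
  n <- nrow(x)
  y <- as.integer(factor(as.character(labels)))
  ny <- max(y)
  B <- apply(x, 2, discretize_ef, bins = bins)
  rel <- vapply(seq_len(ncol(x)), function(j) mi_disc(B[, j], y, bins, ny), 1.0)
  selected <- integer(0)
  red_sum <- numeric(ncol(x))
  sel_rel <- numeric(0); sel_red <- numeric(0)
  for (step in seq_len(k)) {
    if (step == 1L) {
      score <- rel
    } else {
      mean_red <- red_sum / length(selected)
      score <- if (criterion == "MID") rel - mean_red
               else rel / (mean_red + 1e-12)
    }
    score[selected] <- -Inf
    # ties (equal joint count patterns) resolve to the lowest column index
    pick <- which(score >= max(score) - 1e-9)[1]
    selected <- c(selected, pick)
    sel_rel <- c(sel_rel, rel[pick])
    sel_red <- c(sel_red, if (step == 1L) 0 else red_sum[pick] / (step - 1L))
    if (step < k) {
      mi_new <- vapply(seq_len(ncol(x)), function(j) {
        mi_disc(B[, j], B[, pick], bins, bins)
      }, 1.0)
      red_sum <- red_sum + mi_new
    }
  }
  structure(
    list(features = colnames(x)[selected] %||% selected,
         index = selected, relevance = sel_rel, redundancy = sel_red,
         k = k, criterion = criterion),
    class = "mrmr_ranking")
}

#' @export
print.mrmr_ranking <- function(x, ...) {
  cat(sprintf("<mrmr_ranking> top %d (%s): %s%s\n", x$k, x$criterion,
              paste(utils::head(x$features, 5), collapse = ", "),
              if (x$k > 5) ", ..." else ""))
  invisible(x)
}

standardize_train <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  s <- apply(x_train, 2, stats::sd)
  s[s == 0 | !is.finite(s)] <- 1
  list(train = sweep(sweep(x_train, 2, mu), 2, s, "/"),
       test = sweep(sweep(x_test, 2, mu), 2, s, "/"))
}

fit_predict_svm <- function(x_tr, y_tr, x_te, cost, mode) {
  classes <- levels(y_tr)
  if (mode == "ovr" && length(classes) > 2L) {
    dec <- matrix(NA_real_, nrow(x_te), length(classes))
    dec_tr <- matrix(NA_real_, nrow(x_tr), length(classes))
    for (ci in seq_along(classes)) {
      yb <- factor(ifelse(y_tr == classes[ci], classes[ci], ".rest"),
                   levels = c(classes[ci], ".rest"))
      m <- e1071::svm(x_tr, yb, kernel = "linear", cost = cost,
                      scale = FALSE)
      dv <- function(newx) {
        d <- attr(stats::predict(m, newx, decision.values = TRUE),
                  "decision.values")
        # orientation: positive decision value favours the first class name
        if (startsWith(colnames(d)[1], classes[ci])) d[, 1] else -d[, 1]
      }
      dec[, ci] <- dv(x_te)
      dec_tr[, ci] <- dv(x_tr)
    }
    list(pred_test = classes[max.col(dec, ties.method = "first")],
         pred_train = classes[max.col(dec_tr, ties.method = "first")])
  } else {
    m <- e1071::svm(x_tr, y_tr, kernel = "linear", cost = cost, scale = FALSE)
    list(pred_test = as.character(stats::predict(m, x_te)),
         pred_train = as.character(stats::predict(m, x_tr)))
  }
}

macro_metrics <- function(truth, pred, classes) {
  pr <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl); fp <- sum(pred == cl & truth != cl)
    if (tp + fp > 0) tp / (tp + fp) else 0
  }, 1.0)
  rc <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl); fn <- sum(pred != cl & truth == cl)
    if (tp + fn > 0) tp / (tp + fn) else 0
  }, 1.0)
  c(precision = mean(pr), recall = mean(rc), accuracy = mean(pred == truth))
}

#' Cross-validated linear SVM with optional in-fold MRMR selection
#'
#' Stratified k-fold CV. Within each training fold, features are optionally
#' reduced to the top `select_k` by [mrmr_select()] and standardised by the
#' training fold's mean/SD (linear SVMs on mixed uV/ms units need scaling).
#' One C is chosen for the whole report: the grid value maximising mean
#' validation accuracy across folds (ties to the smaller C). Metrics are
#' reported for train and test folds as mean +/- SD; multiclass precision
#' and recall are macro-averaged and a pooled test confusion matrix is
#' returned.
#'
#' @param x numeric feature matrix or data frame (feature columns only).
#' @param labels class labels (2 for `two_class`, 3 for `ovr`/`ovo`).
#' @param mode `"two_class"`, `"ovr"` or `"ovo"`.
#' @param c_grid candidate C values.
#' @param k_folds folds (default 5).
#' @param seed fold-assignment seed.
#' @param select_k MRMR feature count (`NULL` = use all features).
#' @param select_within_folds fit the selection inside each training fold
#'   (default) or once on the full table before CV.
#' @param positive_class positive label for two-class precision/recall
#'   (defaults to the first label encountered).
#' @param mrmr_criterion passed to [mrmr_select()].
#' @return A `cv_report` with `best_c`, `val_acc_by_c`, `confusion`,
#'   `selected` (per-fold feature lists) added.
#' @export
train_eval_svm <- function(x, labels, mode = c("two_class", "ovr", "ovo"),
                           c_grid = c(0.001, 0.01, 0.1, 0.5, 1, 2),
                           k_folds = 5, seed = 1, select_k = NULL,
                           select_within_folds = TRUE,
                           positive_class = NULL,
                           mrmr_criterion = "MID") {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2L) stopf("need at least two classes")
  if (mode == "two_class" && length(classes) != 2L) {
    stopf("two_class mode needs exactly two labels")
  }
  if (min(table(labels)) < k_folds) {
    stopf(paste("a class has fewer members than folds;",
                "use a larger cohort or fewer folds"))
  }
  positive_class <- positive_class %||% classes[1]
  folds <- make_stratified_folds(labels, k_folds, seed)
  global_sel <- NULL
  if (!is.null(select_k) && !select_within_folds) {
    global_sel <- mrmr_select(x, labels, select_k, mrmr_criterion)$index
  }
  preds <- vector("list", k_folds)
  selected <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    sel <- if (!is.null(global_sel)) {
      global_sel
    } else if (!is.null(select_k)) {
      mrmr_select(x[tr, , drop = FALSE], labels[tr], select_k,
                  mrmr_criterion)$index
    } else {
      seq_len(ncol(x))
    }
    selected[[f]] <- colnames(x)[sel] %||% sel
    st <- standardize_train(x[tr, sel, drop = FALSE],
                            x[!tr, sel, drop = FALSE])
    y_tr <- factor(labels[tr], levels = classes)
    preds[[f]] <- lapply(c_grid, function(cc) {
      fit_predict_svm(st$train, y_tr, st$test, cc, mode)
    })
  }
  val_acc <- vapply(seq_along(c_grid), function(ci) {
    mean(vapply(seq_len(k_folds), function(f) {
      mean(preds[[f]][[ci]]$pred_test == labels[folds == f])
    }, 1.0))
  }, 1.0)
  best_ci <- which(val_acc == max(val_acc))[1]   # ties -> smaller C
  met <- c("precision", "recall", "accuracy")
  train_m <- matrix(NA_real_, k_folds, 3, dimnames = list(NULL, met))
  test_m <- matrix(NA_real_, k_folds, 3, dimnames = list(NULL, met))
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(truth = classes, pred = classes))
  for (f in seq_len(k_folds)) {
    p <- preds[[f]][[best_ci]]
    truth_tr <- labels[folds != f]; truth_te <- labels[folds == f]
    if (mode == "two_class") {
      train_m[f, ] <- binary_metrics(truth_tr, p$pred_train, positive_class)
      test_m[f, ] <- binary_metrics(truth_te, p$pred_test, positive_class)
    } else {
      train_m[f, ] <- macro_metrics(truth_tr, p$pred_train, classes)
      test_m[f, ] <- macro_metrics(truth_te, p$pred_test, classes)
    }
    for (i in seq_along(truth_te)) {
      confusion[truth_te[i], p$pred_test[i]] <-
        confusion[truth_te[i], p$pred_test[i]] + 1L
    }
  }
  structure(
    list(train = summarize_folds(train_m), test = summarize_folds(test_m),
         best_c = c_grid[best_ci], val_acc_by_c = stats::setNames(val_acc, c_grid),
         confusion = confusion, folds = folds, k = k_folds, seed = seed,
         mode = mode, positive_class = positive_class,
         selected = selected, n_features = length(selected[[1]])),
    class = "cv_report")
}

#' The study's five classification analyses in one call
#'
#' Three two-class runs (ZI vs VMR, ZI vs DLR, DLR vs VMR; positive class =
#' first-named region) and the three-region multiclass run as both
#' one-vs-rest and one-vs-one, each on the MRMR-selected top-k features
#' with the C grid and fold settings of the configuration.
#'
#' @param table feature table from [build_feature_table()] (with `region`).
#' @param config a [pipeline_config()].
#' @param seed CV seed (default the config's `rng_seed`).
#' @return List with `runs` (named `cv_report`s) and `summary` (one row per
#'   analysis: chosen C, feature count, train/test precision, recall,
#'   accuracy mean and SD).
#' @export
full_pipeline_classification <- function(table, config = pipeline_config(),
                                         seed = config$rng_seed) {
  x <- feature_matrix(table)
  region <- table$region
  pairs <- list(ZI_vs_VMR = c("ZI", "VMR"), ZI_vs_DLR = c("ZI", "DLR"),
                DLR_vs_VMR = c("DLR", "VMR"))
  runs <- list()
  for (nm in names(pairs)) {
    keep <- region %in% pairs[[nm]]
    runs[[nm]] <- train_eval_svm(
      x[keep, , drop = FALSE], region[keep], mode = "two_class",
      c_grid = config$svm_c_grid, k_folds = config$cv_folds, seed = seed,
      select_k = config$mrmr_k,
      select_within_folds = config$select_within_folds,
      positive_class = pairs[[nm]][1])
  }
  for (mode in c("ovr", "ovo")) {
    runs[[paste0("multiclass_", mode)]] <- train_eval_svm(
      x, region, mode = mode, c_grid = config$svm_c_grid,
      k_folds = config$cv_folds, seed = seed, select_k = config$mrmr_k,
      select_within_folds = config$select_within_folds)
  }
  summary <- do.call(rbind, lapply(names(runs), function(nm) {
    r <- runs[[nm]]
    data.frame(analysis = nm, n_features = r$n_features, c = r$best_c,
               precision_train = r$train$mean["precision"],
               recall_train = r$train$mean["recall"],
               accuracy_train = r$train$mean["accuracy"],
               precision_test = r$test$mean["precision"],
               recall_test = r$test$mean["recall"],
               accuracy_test = r$test$mean["accuracy"],
               precision_test_sd = r$test$sd["precision"],
               recall_test_sd = r$test$sd["recall"],
               accuracy_test_sd = r$test$sd["accuracy"],
               row.names = NULL)
  }))
  list(runs = runs, summary = summary)
}
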