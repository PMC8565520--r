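test_that("MRMR step one is pure relevance and duplicates are deferred", {
  set.seed(71)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  f1 <- y + rnorm(n, sd = 0.1)
  f3 <- y + rnorm(n, sd = 1.5)          # weaker independent signal
  x <- cbind(f1 = f1, f2 = f1, f3 = f3)
  lab <- ifelse(y == 1, "ZI", "VMR")
  r1 <- mrmr_select(x, lab, 1)
  expect_identical(r1$features, "f1")
  r3 <- mrmr_select(x, lab, 3)
  expect_identical(r3$features, c("f1", "f3", "f2"))
  expect_identical(r3$redundancy[1], 0)
  expect_error(mrmr_select(x, lab, 5), "k must be")
})

test_that("MRMR equals the brute-force greedy oracle on random tables", {
  set.seed(72)
  for (i in 1:12) {
    n <- sample(20:40, 1); p <- sample(5:20, 1)
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    lab <- sample(c("ZI", "DLR", "VMR"), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c("ZI", "DLR")
    k <- sample(2:min(8, p), 1)
    expect_identical(mrmr_select(x, lab, k)$features,
                     mrmr_oracle(x, lab, k))
  }
})

test_that("MRMR is invariant to column order and monotone transforms", {
  set.seed(73)
  n <- 40; p <- 8
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  lab <- sample(c("A", "B"), n, replace = TRUE)
  base <- mrmr_select(x, lab, 5)$features
  perm <- sample(p)
  expect_identical(mrmr_select(x[, perm], lab, 5)$features, base)
  xt <- x
  xt[, 1] <- exp(x[, 1]); xt[, 2] <- x[, 2]^3; xt[, 3] <- 2 * x[, 3] - 7
  expect_identical(mrmr_select(xt, lab, 5)$features, base)
  # greedy prefix property: a larger k extends the smaller ranking
  expect_identical(mrmr_select(x, lab, 7)$features[1:5], base)
})

test_that("the linear SVM nails separable data and stays at chance under the null", {
  set.seed(74)
  n <- 40
  x <- cbind(a = c(rnorm(n / 2), rnorm(n / 2) + 8), b = rnorm(n))
  lab <- rep(c("ZI", "VMR"), each = n / 2)
  r <- train_eval_svm(x, lab, mode = "two_class", seed = 1,
                      positive_class = "ZI")
  expect_true(all(r$train$per_fold[, "accuracy"] == 1))
  expect_true(all(r$test$per_fold[, "accuracy"] == 1))
  # training accuracy 1 at every C on separable data
  for (cc in c(0.001, 0.01, 0.1, 0.5, 1, 2)) {
    rc <- train_eval_svm(x, lab, mode = "two_class", c_grid = cc, seed = 1)
    expect_true(all(rc$train$per_fold[, "accuracy"] == 1))
  }

  set.seed(75)
  x0 <- matrix(rnorm(61 * 10), 61, 10,
               dimnames = list(NULL, paste0("f", 1:10)))
  lab0 <- sample(rep(c("ZI", "DLR", "VMR"), times = c(20, 23, 18)))
  r0 <- train_eval_svm(x0, lab0, mode = "ovo", seed = 3)
  band <- qbinom(c(0.025, 0.975), 61, 1 / 3) / 61
  expect_gte(mean(r0$test$per_fold[, "accuracy"]), band[1] - 0.05)
  expect_lte(mean(r0$test$per_fold[, "accuracy"]), band[2] + 0.05)

  # determinism
  r0b <- train_eval_svm(x0, lab0, mode = "ovo", seed = 3)
  expect_identical(r0$test, r0b$test)
  expect_identical(r0$best_c, r0b$best_c)
})

test_that("OvR and OvO multiclass report macro metrics and a 3x3 confusion", {
  set.seed(76)
  centers <- list(ZI = c(0, 0), DLR = c(6, 0), VMR = c(0, 6))
  lab <- rep(names(centers), times = c(20, 23, 18))
  x <- t(vapply(lab, function(l) centers[[l]] + rnorm(2, sd = 0.5),
                numeric(2)))
  colnames(x) <- c("u", "v")
  for (mode in c("ovr", "ovo")) {
    r <- train_eval_svm(x, lab, mode = mode, seed = 4)
    expect_identical(dim(r$confusion), c(3L, 3L))
    expect_identical(sum(r$confusion), 61L)
    expect_gt(sum(diag(r$confusion)) / 61, 0.95)
    expect_true(all(r$test$mean >= 0 & r$test$mean <= 1))
  }
  expect_error(train_eval_svm(x[1:24, ], lab[1:24], mode = "ovr", seed = 1),
               "fewer members than folds")
})

test_that("in-fold MRMR selection feeds the SVM only k features", {
  tab <- toy_feature_table(n_per = 15, delta = 3, p = 12)
  x <- feature_matrix(tab)
  r <- train_eval_svm(x, tab$region, mode = "two_class", select_k = 4,
                      seed = 5, positive_class = "ZI")
  expect_true(all(lengths(r$selected) == 4))
  expect_identical(r$n_features, 4L)
  # the planted feature is always selected
  expect_true(all(vapply(r$selected, function(s) "f1" %in% s, TRUE)))
  rg <- train_eval_svm(x, tab$region, mode = "two_class", select_k = 4,
                       select_within_folds = FALSE, seed = 5)
  expect_identical(length(unique(rg$selected)), 1L)
})

test_that("the five study analyses produce a Table-3-shaped report", {
  set.seed(77)
  lat <- c(ZI = 77, DLR = 69, VMR = 67)
  lab <- rep(names(lat), times = c(8, 8, 8))
  x <- cbind(lat1 = lat[lab] + rnorm(24, sd = 0.8),
             lat2 = lat[lab] * 0.9 + rnorm(24, sd = 0.8),
             noise1 = rnorm(24), noise2 = rnorm(24))
  tab <- data.frame(session_id = sprintf("S%02d", 1:24), region = lab,
                    seed = 1:24, x, check.names = FALSE)
  cfg <- pipeline_config(mrmr_k = 2, cv_folds = 4)
  rep5 <- full_pipeline_classification(tab, cfg, seed = 9)
  expect_identical(nrow(rep5$summary), 5L)
  expect_identical(rep5$summary$analysis,
                   c("ZI_vs_VMR", "ZI_vs_DLR", "DLR_vs_VMR",
                     "multiclass_ovr", "multiclass_ovo"))
  expect_true(all(rep5$summary$c %in% cfg$svm_c_grid))
  expect_identical(dim(rep5$runs$multiclass_ovr$confusion), c(3L, 3L))
  # strong latency separation -> high accuracy everywhere
  expect_true(all(rep5$summary$accuracy_test > 0.7))
})
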