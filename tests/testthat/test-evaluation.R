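# Folds, metrics and the baseline harness.

test_that("folds partition the samples, stratified and reproducibly", {
  df <- tibble::tibble(sample_id = paste0("s", 1:8),
                       label = rep(c("a", "b"), each = 4), x = rnorm(8))
  f <- make_folds(df, n_folds = 4, seed = 1)
  expect_setequal(f$row, 1:8)
  expect_equal(sort(unique(f$fold)), 1:4)
  expect_equal(as.vector(table(f$fold)), rep(2, 4))
  # stratification: each fold holds one sample of each class
  tab <- table(f$label, f$fold)
  expect_true(all(tab == 1))
  expect_identical(make_folds(df, n_folds = 4, seed = 1), f)
  expect_false(identical(make_folds(df, n_folds = 4, seed = 2)$fold, f$fold))
})

test_that("fold assignment follows sample ids, not row order", {
  sim <- tiny_data(11)
  f1 <- make_folds(sim, n_folds = 4, seed = 3)
  perm <- withr::with_seed(99, sample(nrow(sim)))
  f2 <- make_folds(sim[perm, ], n_folds = 4, seed = 3)
  m1 <- setNames(f1$fold, f1$sample_id)
  m2 <- setNames(f2$fold, f2$sample_id)
  expect_identical(m1[sort(names(m1))], m2[sort(names(m2))])
})

test_that("too-small classes fall back to unstratified folds with a warning", {
  df <- tibble::tibble(label = c("a", rep("b", 7)), x = rnorm(8))
  expect_warning(f <- make_folds(df, n_folds = 4, seed = 0), "unstratified")
  expect_setequal(f$row, 1:8)
})

test_that("metrics match hand-enumerated confusion/ROC values", {
  perfect <- compute_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1),
                             c(0.1, 0.9, 0.2, 0.8))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$f1, 1)

  # hand case: thresholds enumerate to AUC 0.75; both class F1 are 0.5
  m <- compute_metrics(c(0, 0, 1, 1), c(0, 1, 0, 1), c(0.1, 0.6, 0.4, 0.9))
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$auc, 0.75)
  expect_equal(m$f1, 0.5)

  # constant prediction on balanced truth
  const <- compute_metrics(c(0, 0, 1, 1), rep(0, 4), rep(0.5, 4))
  expect_equal(const$accuracy, 0.5)

  # hand-computed weighted F1: truth aabb, estimate abbb
  hand <- compute_metrics(c("a", "a", "b", "b"), c("a", "b", "b", "b"))
  expect_equal(hand$f1, (2 * (2 / 3) + 2 * 0.8) / 4)

  # single-class truth: AUC undefined
  expect_true(is.na(compute_metrics(c(1, 1), c(1, 0), c(0.8, 0.3))$auc))
})

test_that("metrics agree with brute-force oracles on random cases", {
  withr::with_seed(29, {
    for (rep in 1:100) {
      n <- sample(5:40, 1)
      truth <- sample(0:1, n, replace = TRUE)
      if (length(unique(truth)) < 2) truth[1:2] <- 0:1
      est <- sample(0:1, n, replace = TRUE)
      score <- round(runif(n), 2)  # rounded scores force ties through the rank path
      m <- compute_metrics(truth, est, score)
      expect_equal(m$accuracy, oracle_accuracy(truth, est))
      expect_equal(m$auc, oracle_auc_binary(truth == 1, score))
      expect_equal(m$f1, oracle_f1_weighted(as.character(truth), as.character(est)))
    }
  })
})

test_that("binary AUC agrees with pROC on probability matrices", {
  skip_if_not_installed("pROC")
  withr::with_seed(37, {
    truth <- sample(c("a", "b"), 50, replace = TRUE)
    p1 <- runif(50)
    prob <- cbind(1 - p1, p1)
  })
  m <- compute_metrics(truth, truth, prob)
  ref <- as.numeric(pROC::auc(pROC::roc(truth, p1, levels = c("a", "b"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(m$auc, ref, tolerance = 1e-12)
})

test_that("multiclass metrics use one-vs-rest AUC and weighted F1", {
  withr::with_seed(41, {
    truth <- sample(c("a", "b", "c"), 30, replace = TRUE)
    prob <- matrix(runif(90), 30, 3)
    prob <- prob / rowSums(prob)
  })
  est <- c("a", "b", "c")[max.col(prob)]
  m <- compute_metrics(truth, est, prob)
  lv <- c("a", "b", "c")
  ovr <- mean(sapply(1:3, function(j) oracle_auc_binary(truth == lv[j], prob[, j])))
  expect_equal(m$auc, ovr)
  expect_equal(m$f1, oracle_f1_weighted(truth, est))
})

test_that("PLS-DA separates well-separated blobs perfectly", {
  blobs <- blob_data(m = 60, d = 5)
  folds <- make_folds(blobs, n_folds = 3, seed = 0)
  res <- run_baseline(blobs, method = "plsda", folds = folds, seed = 0)
  expect_equal(nrow(res), 3)
  expect_equal(mean(res$accuracy), 1)
  expect_equal(res$method, rep("plsda", 3))
})

test_that("the random forest uses 400 trees of depth at most 3", {
  blobs <- blob_data(m = 40, d = 4)
  ft <- saefs:::ft_parse(blobs, "label")
  fit <- saefs:::fit_baseline("rf", ft$X, ft$y, ft$levels, seed = 1,
                              config = sae_config())
  expect_equal(fit$num.trees, 400)
  depth_of <- function(tree) {
    info <- ranger::treeInfo(fit, tree)
    # node depth via parent walking
    depth <- setNames(rep(0L, nrow(info)), info$nodeID)
    for (i in seq_len(nrow(info))) {
      kids <- c(info$leftChild[i], info$rightChild[i])
      kids <- kids[!is.na(kids)]
      depth[as.character(kids)] <- depth[as.character(info$nodeID[i])] + 1L
    }
    max(depth)
  }
  expect_true(all(vapply(1:20, depth_of, integer(1)) <= 3))
})

test_that("the linear SVM grid search picks a cost and classifies blobs", {
  blobs <- blob_data(m = 60, d = 4)
  folds <- make_folds(blobs, n_folds = 3, seed = 0)
  res <- run_baseline(blobs, method = "svm", folds = folds, seed = 0)
  expect_equal(mean(res$accuracy), 1)
})

test_that("all methods are evaluated on identical folds", {
  sim <- tiny_data(12)
  folds <- make_folds(sim, n_folds = 2, seed = 0)
  cfg <- fast_config(eta = 10, epochs = 5)
  a <- run_baseline(sim, method = "plsda", folds = folds, seed = 0, config = cfg)
  b <- run_baseline(sim, method = "nn", folds = folds, seed = 0, config = cfg)
  expect_identical(a[c("seed", "fold")], b[c("seed", "fold")])
})

test_that("cross_validate aggregates split means exactly", {
  sim <- tiny_data(13)
  cv <- cross_validate(sim, config = fast_config(eta = 10, epochs = 5),
                       n_folds = 2, seeds = c(0, 1),
                       methods = c("sae_huber", "plsda"))
  res <- tidy(cv)
  expect_equal(nrow(res), 2 * 2 * 2)   # folds x seeds x methods
  agg <- glance(cv)
  for (mth in agg$method) {
    sub <- res[res$method == mth, ]
    expect_equal(agg$accuracy[agg$method == mth], mean(sub$accuracy),
                 tolerance = 1e-12)
    expect_equal(agg$f1[agg$method == mth], mean(sub$f1), tolerance = 1e-12)
  }
})

test_that("preprocessing statistics come from the training rows only", {
  sim <- tiny_data(14)
  folds <- make_folds(sim, n_folds = 3, seed = 0)
  tr <- sim[folds$fold != 1, ]
  fit <- train_sae(tr, config = fast_config(eta = 10, epochs = 3, seed = 0))
  ft <- saefs:::ft_parse(tr, "label")
  expect_equal(fit$preprocessing$center, colMeans(ft$X), tolerance = 1e-12)
  expect_equal(fit$preprocessing$scale, apply(ft$X, 2, sd), tolerance = 1e-12)
})
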