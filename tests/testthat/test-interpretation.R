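# Confidence scores, feature ranking, weight export, correlations, hold-out.

test_that("confidence scores are bounded by [1/k, 1] and match closed forms", {
  p <- list(W1 = matrix(0, 2, 3), b1 = rep(0, 3),
            W2 = matrix(0, 3, 2), b2 = c(0, 0))
  mdl <- hand_model(p, d = 2, k = 2)
  pred <- predict(mdl, matrix(0, 1, 2))
  expect_equal(pred$.confidence, 0.5)   # latent (0, 0) -> uniform softmax

  mdl$params$b2 <- c(10, 0)             # latent (10, 0)
  pred <- predict(mdl, matrix(0, 1, 2))
  expect_equal(pred$.confidence, exp(10) / (exp(10) + 1), tolerance = 1e-9)
  expect_equal(pred$.confidence, 0.9999546, tolerance = 1e-5)

  sim <- tiny_data(20)
  fit <- train_sae(sim, config = fast_config(eta = 10, epochs = 5, seed = 0))
  preds <- predict_with_confidence(fit, sim)
  expect_true(all(preds$.confidence >= 0.5 - 1e-12))
  expect_true(all(preds$.confidence <= 1 + 1e-12))
  probs <- as.matrix(preds[paste0(".prob_", fit$levels)])
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-9)
})

test_that("a duplicated training sample predicts identically to the original", {
  sim <- tiny_data(21)
  fit <- train_sae(sim, config = fast_config(eta = 10, epochs = 5, seed = 0))
  one <- sim[5, ]
  p1 <- predict(fit, sim)[5, ]
  p2 <- predict(fit, one)
  expect_equal(as.matrix(p2[paste0(".prob_", fit$levels)]),
               as.matrix(p1[paste0(".prob_", fit$levels)]))
})

test_that("row-norm ranking equals the selected set of nonzero rows", {
  sim <- tiny_data(22)
  fit <- train_sae(sim, config = fast_config(eta = 5, epochs = 8, seed = 1))
  rk <- rank_features(fit)
  expect_true(all(diff(rk$score) <= 0))
  nz <- sum(l1_norm_rows(fit$params$W1) > 0)
  expect_equal(sum(rk$selected), nz)
  expect_true(all(rk$score[rk$selected] > 0))
  expect_true(all(rk$score[!rk$selected] == 0))
})

test_that("attribution scores follow feature names regardless of column order", {
  sim <- tiny_data(23)
  fit <- train_sae(sim, config = fast_config(eta = 10, epochs = 5, seed = 1))
  rk1 <- rank_features(fit, sim, method = "gradient_input")
  shuffled <- sim[, c("sample_id", "label",
                      withr::with_seed(1, sample(setdiff(names(sim), c("sample_id", "label")))))]
  rk2 <- rank_features(fit, shuffled, method = "gradient_input")
  expect_equal(rk1, rk2)
  expect_error(rank_features(fit, method = "gradient_input"), "data")
})

test_that("planted informative features dominate the ranking on easy data", {
  sim <- tiny_data(24)
  fit <- train_sae(sim, config = fast_config(eta = 10, epochs = 15, seed = 0,
                                             log_transform = TRUE))
  rk <- rank_features(fit)
  planted <- attr(sim, "informative_features")
  expect_gte(sum(planted %in% head(rk$feature, 8)), 5)
})

test_that("the exported weight matrix round-trips through TSV", {
  sim <- tiny_data(25)
  fit <- train_sae(sim, config = fast_config(eta = 5, epochs = 8, seed = 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- export_weight_matrix(fit, path)
  expect_equal(nrow(out), fit$d)
  expect_equal(ncol(out), fit$config$hidden_width + 1)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(as.matrix(back[-1]), fit$params$W1, ignore_attr = TRUE)
  expect_gt(sum(rowSums(abs(fit$params$W1)) == 0), 0)  # small eta kills rows
})

test_that("correlation matrices are symmetric, unit-diagonal and PSD", {
  sim <- tiny_data(26)
  feats <- names(sim)[3:10]
  fc <- feature_correlations(sim, feats)
  C <- fc$matrix
  expect_equal(C, t(C))
  expect_equal(diag(C), rep(1, length(feats)), ignore_attr = TRUE)
  expect_true(all(C >= -1 - 1e-12 & C <= 1 + 1e-12))
  expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_equal(nrow(fc$pairs), choose(length(feats), 2))
})

test_that("correlations recover affine relationships exactly", {
  df <- tibble::tibble(x = rnorm(50))
  df$y <- 2 * df$x + 3
  df$z <- -df$x
  fc <- feature_correlations(df, c("x", "y", "z"))
  expect_equal(fc$matrix["x", "y"], 1)
  expect_equal(fc$matrix["x", "z"], -1)
})

test_that("zero-variance features are flagged and excluded", {
  df <- tibble::tibble(a = rnorm(20), b = rnorm(20), c = rep(1, 20))
  expect_warning(fc <- feature_correlations(df, c("a", "b", "c")), "zero-variance")
  expect_equal(nrow(fc$matrix), 2)
  expect_error(feature_correlations(df, "a"), "two features")
})

test_that("configured adduct correlation is recovered on the log scale", {
  spec <- synthetic_spec(m = 500, d = 30, n_informative = 2, effect_size = 1,
                         adduct_groups = list(c(4, 0.9)), outlier_fraction = 0,
                         seed = 5)
  sim <- generate_metabolomics(spec)
  group <- attr(sim, "adduct_groups")[[1]]
  logged <- dplyr::mutate(sim, dplyr::across(dplyr::all_of(group), log))
  fc <- feature_correlations(logged, group)
  off <- fc$pairs$pearson
  expect_true(all(abs(off - 0.9) < 0.05))
})

test_that("hold-out simulation withholds one patient per class", {
  sim <- tiny_data(27)
  cfg <- fast_config(eta = 10, epochs = 25, seed = 0, log_transform = TRUE)
  sim_res <- holdout_simulation(sim, config = cfg, seed = 4)
  expect_equal(nrow(sim_res$predictions), 2)
  expect_equal(nrow(sim_res$latent), nrow(sim) - 2)
  expect_setequal(unique(sim_res$densities$class), levels(sim$label))
  # strongly separated classes: both held-out patients classified correctly
  expect_equal(as.character(sim_res$predictions$.pred_class),
               as.character(sim_res$predictions$.true_class))
  expect_true(all(sim_res$predictions$.confidence > 0.9))
  # reproducible
  sim_res2 <- holdout_simulation(sim, config = cfg, seed = 4)
  expect_identical(sim_res$held_out, sim_res2$held_out)
  expect_equal(sim_res$predictions, sim_res2$predictions)
  # class of size one is rejected
  small <- sim[c(which(sim$label == "class_0"), which(sim$label == "class_1")[1]), ]
  expect_error(holdout_simulation(small, config = cfg), "two samples")
})
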