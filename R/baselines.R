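# Classical comparators, each behind the same per-fold evaluation surface as
# the SAE: PLS-DA (4 components, mixOmics), random forest (400 trees, depth
# <= 3, Gini impurity importance, ranger), linear-kernel SVM with the
# regularisation constant C chosen by an inner cross-validated grid search
# (e1071), and the plain neural network (train_nn_baseline).

baseline_methods <- c("plsda", "rf", "svm", "nn")

fit_baseline <- function(method, Xtr, ytr, levels, seed, config) {
  k <- length(levels)
  switch(method,
    plsda = {
      ncomp <- min(4L, ncol(Xtr), nrow(Xtr) - 1L)
      fit <- mixOmics::plsda(Xtr, factor(levels[ytr + 1L], levels = levels),
                             ncomp = ncomp)
      list(fit = fit, ncomp = ncomp)
    },
    rf = ranger::ranger(
      x = as.data.frame(Xtr), y = factor(levels[ytr + 1L], levels = levels),
      num.trees = 400, max.depth = 3, probability = TRUE,
      importance = "impurity", seed = seed, num.threads = 1
    ),
    svm = {
      C <- svm_select_cost(Xtr, ytr, levels, seed)
      # class scores come from the decision values (k = 2) rather than the
      # Platt probability model, which is unstable at small C
      fit <- e1071::svm(Xtr, factor(levels[ytr + 1L], levels = levels),
                        kernel = "linear", cost = C, probability = k > 2)
      list(fit = fit, cost = C)
    },
    nn = {
      cfg <- config
      cfg$seed <- seed
      df <- tibble::as_tibble(as.data.frame(Xtr))
      df$label <- factor(levels[ytr + 1L], levels = levels)
      # features already preprocessed by the harness
      cfg$standardize <- FALSE; cfg$log_transform <- FALSE
      train_nn_baseline(df, "label", cfg)
    },
    stop(sprintf("unknown baseline method '%s'.", method), call. = FALSE)
  )
}

predict_baseline <- function(method, fit, Xte, levels) {
  switch(method,
    plsda = {
      pr <- stats::predict(fit$fit, Xte)
      scores <- pr$predict[, , fit$ncomp, drop = TRUE]
      if (is.null(dim(scores))) scores <- matrix(scores, nrow = nrow(Xte))
      colnames(scores) <- levels
      cls <- levels[max.col(scores, ties.method = "first")]
      # regressed class-indicator scores: valid for ranking (AUC), rescale to
      # a probability-like simplex for reporting
      prob <- t(apply(scores, 1, function(s) {
        e <- exp(s - max(s)); e / sum(e)
      }))
      list(class = cls, prob = prob)
    },
    rf = {
      prob <- stats::predict(fit, data = as.data.frame(Xte),
                             num.threads = 1)$predictions
      prob <- prob[, levels, drop = FALSE]
      list(class = levels[max.col(prob, ties.method = "first")], prob = prob)
    },
    svm = {
      if (length(levels) == 2) {
        pr <- stats::predict(fit$fit, Xte, decision.values = TRUE)
        dv <- attr(pr, "decision.values")
        pos <- strsplit(colnames(dv)[1], "/")[[1]][1]  # positive decision class
        p_pos <- stats::plogis(as.numeric(dv))
        prob <- cbind(p_pos, 1 - p_pos)
        colnames(prob) <- c(pos, setdiff(levels, pos))
        prob <- prob[, levels, drop = FALSE]
      } else {
        pr <- stats::predict(fit$fit, Xte, probability = TRUE)
        prob <- attr(pr, "probabilities")[, levels, drop = FALSE]
      }
      list(class = as.character(pr), prob = prob)
    },
    nn = {
      pred <- stats::predict(fit, Xte)
      prob <- as.matrix(pred[paste0(".prob_", levels)])
      list(class = as.character(pred$.pred_class), prob = prob)
    }
  )
}

svm_select_cost <- function(Xtr, ytr, levels, seed, grid = 10^(-3:3),
                            inner_folds = 3) {
  y <- factor(levels[ytr + 1L], levels = levels)
  df <- tibble::tibble(label = y)
  folds <- make_folds(df, "label", n_folds = min(inner_folds, min(table(y))),
                      seed = seed)
  acc <- vapply(grid, function(C) {
    mean(vapply(unique(folds$fold), function(f) {
      tr <- folds$fold != f
      fit <- e1071::svm(Xtr[tr, , drop = FALSE], y[tr], kernel = "linear", cost = C)
      mean(stats::predict(fit, Xtr[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(acc)]  # first maximiser = smallest C
}

#' Evaluate one classifier over a set of cross-validation folds
#'
#' Runs one method (`"plsda"`, `"rf"`, `"svm"`, `"nn"`, or the SAE variants
#' `"sae_huber"` / `"sae_l2"`) over the folds produced by [make_folds()],
#' fitting on the training part of each fold and scoring the held-out part
#' with [compute_metrics()]. Feature preprocessing (centring/scaling, optional
#' log transform) is fitted inside each training fold only.
#'
#' @param data Data frame with feature columns and a label column.
#' @param label Name of the label column.
#' @param method One of `"sae_huber"`, `"sae_l2"`, `"plsda"`, `"rf"`,
#'   `"svm"`, `"nn"`.
#' @param folds Fold assignment tibble from [make_folds()].
#' @param seed Seed forwarded to stochastic fitters.
#' @param config [sae_config()] used for the SAE/NN methods and for the
#'   preprocessing switches.
#' @return A tibble with one row per fold: `seed`, `fold`, `method`,
#'   `accuracy`, `auc`, `f1`.
#' @export
run_baseline <- function(data, label = "label", method, folds,
                         seed = 0, config = sae_config()) {
  method <- match.arg(method, c("sae_huber", "sae_l2", baseline_methods))
  data <- tibble::as_tibble(data)
  ft <- ft_parse(data, label)
  purrr::map_dfr(sort(unique(folds$fold)), function(f) {
    tr_idx <- folds$row[folds$fold != f]
    te_idx <- folds$row[folds$fold == f]
    truth <- ft$levels[ft$y[te_idx] + 1L]
    if (method %in% c("sae_huber", "sae_l2")) {
      cfg <- config
      cfg$seed <- as.integer(seed)
      cfg$recon_loss <- if (method == "sae_huber") "huber" else "l2"
      fit <- train_sae(data[tr_idx, , drop = FALSE], label, cfg)
      pred <- stats::predict(fit, data[te_idx, , drop = FALSE])
      cls <- as.character(pred$.pred_class)
      prob <- as.matrix(pred[paste0(".prob_", ft$levels)])
    } else {
      pp <- preproc_fit(ft$X[tr_idx, , drop = FALSE],
                        config$standardize, config$log_transform)
      Xtr <- preproc_apply(pp, ft$X[tr_idx, , drop = FALSE])
      Xte <- preproc_apply(pp, ft$X[te_idx, , drop = FALSE])
      fit <- fit_baseline(method, Xtr, ft$y[tr_idx], ft$levels, seed, config)
      pr <- predict_baseline(method, fit, Xte, ft$levels)
      cls <- pr$class; prob <- pr$prob
    }
    dplyr::bind_cols(
      tibble::tibble(seed = seed, fold = f, method = method),
      compute_metrics(truth, cls, prob)
    )
  })
}

#' Feature importance rankings from the classical baselines
#'
#' Fits one baseline on the full table and extracts its native importance
#' measure: absolute PLS loading weights (summed over components), random
#' forest Gini impurity importance, absolute linear-SVM coefficients
#' (one-vs-one coefficients summed in absolute value), or the NN first-layer
#' row norms.
#'
#' @inheritParams run_baseline
#' @return A tibble `feature`, `score`, `rank`, `method`, sorted by
#'   non-increasing score.
#' @export
rank_features_baseline <- function(data, label = "label",
                                   method = c("plsda", "rf", "svm", "nn"),
                                   seed = 0, config = sae_config()) {
  method <- match.arg(method)
  ft <- ft_parse(data, label)
  pp <- preproc_fit(ft$X, config$standardize, config$log_transform)
  X <- preproc_apply(pp, ft$X)
  fit <- fit_baseline(method, X, ft$y, ft$levels, seed, config)
  score <- switch(method,
    plsda = rowSums(abs(fit$fit$loadings$X)),
    rf = {
      imp <- ranger::importance(fit)
      imp[ft$feature_names]
    },
    svm = {
      co <- t(fit$fit$coefs) %*% fit$fit$SV
      colSums(abs(co))[seq_len(ft$d)]
    },
    nn = l1_norm_rows(fit$params$W1)
  )
  score <- as.numeric(score)
  tag <- c(plsda = "loading", rf = "gini", svm = "coefficient", nn = "row_norm")[[method]]
  ranking_tibble(ft$feature_names, score, tag)
}

ranking_tibble <- function(features, score, method) {
  ord <- order(-score, seq_along(score))
  tibble::tibble(
    feature = features[ord],
    score = score[ord],
    rank = seq_along(score),
    method = method
  )
}
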