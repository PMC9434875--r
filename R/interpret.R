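#' Rank input features of a trained supervised autoencoder
#'
#' The primary ranking is the l1 norm of each feature's row in the (projected)
#' first encoder layer: the l1,1 constraint zeroes whole rows, so features
#' with a zero row norm are exactly the deselected ones and the selected set
#' is the set of nonzero rows. An alternative attribution ranking
#' (`method = "gradient_input"`) scores each feature by the mean absolute
#' gradient-times-input of the predicted-class probability over the supplied
#' samples.
#'
#' @param model A fitted `trained_sae` or `trained_nn`.
#' @param data Data frame of samples; required for the attribution ranking.
#' @param method `"row_norm"` (default) or `"gradient_input"`.
#' @return A tibble `feature`, `score`, `rank`, `method`, `selected`, sorted
#'   by non-increasing score. For `row_norm`, `selected` marks nonzero rows.
#' @export
rank_features <- function(model, data = NULL,
                          method = c("row_norm", "gradient_input")) {
  stopifnot(inherits(model, "sae_model"))
  method <- match.arg(method)
  if (method == "row_norm") {
    score <- l1_norm_rows(model$params$W1)
    out <- ranking_tibble(model$feature_names, score, "row_norm")
    out$selected <- out$score > 0
    return(out)
  }
  if (is.null(data)) {
    stop("`data` is required for the gradient_input attribution.", call. = FALSE)
  }
  X <- preproc_apply(model$preprocessing, model_matrix(model, data))
  p <- model$params
  fw <- sae_forward(p, X, decoder = FALSE)
  P <- classify_logits(fw$logits)
  pred <- max.col(P, ties.method = "first")
  # d p_c / d logits = p_c * (e_c - p), rows vectorised over samples
  G <- -P * P[cbind(seq_len(nrow(P)), pred)]
  G[cbind(seq_len(nrow(P)), pred)] <- G[cbind(seq_len(nrow(P)), pred)] +
    P[cbind(seq_len(nrow(P)), pred)]
  if (!is.null(p$Wh)) G <- G %*% t(p$Wh)
  G1 <- (G %*% t(p$W2)) * (fw$H1p > 0)
  GX <- G1 %*% t(p$W1)
  score <- colMeans(abs(GX * X))
  out <- ranking_tibble(model$feature_names, score, "gradient_input")
  out$selected <- out$score > 0
  out
}

#' Write the first-layer weight matrix to a TSV file
#'
#' Exports the d x hidden connection matrix between the input features and the
#' hidden layer, with feature names as the first column — the heatmap-ready
#' matrix used to contrast the row-structured (l1,1) and unstructured (l1)
#' sparsity patterns.
#'
#' @param model A fitted `trained_sae` or `trained_nn`.
#' @param path Output file path.
#' @return The exported tibble, invisibly.
#' @export
export_weight_matrix <- function(model, path) {
  stopifnot(inherits(model, "sae_model"))
  W <- model$params$W1
  out <- dplyr::bind_cols(
    tibble::tibble(feature = model$feature_names),
    tibble::as_tibble(as.data.frame(W), .name_repair = ~ paste0("h", seq_len(ncol(W))))
  )
  readr::write_tsv(out, path)
  invisible(out)
}

#' Pairwise Pearson correlations among selected features
#'
#' Computes the symmetric unit-diagonal Pearson correlation matrix of a
#' feature subset across all samples — used to inspect whether selected
#' features are adducts/isotopes of the same metabolite (highly correlated
#' columns). Zero-variance features are dropped with a warning.
#'
#' @param data Data frame containing the feature columns.
#' @param features Character vector of feature column names (>= 2).
#' @return An object of class `feature_correlations`: list with `matrix` (the
#'   correlation matrix) and `pairs` (a tibble of the distinct pairs sorted by
#'   absolute correlation). `autoplot()` draws the heatmap.
#' @export
feature_correlations <- function(data, features) {
  data <- tibble::as_tibble(data)
  missing <- setdiff(features, names(data))
  if (length(missing) > 0) {
    stop("features not found: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  if (length(features) < 2) stop("need at least two features.", call. = FALSE)
  X <- as.matrix(data[features])
  if (!is.numeric(X)) stop("selected features must be numeric.", call. = FALSE)
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance features: ",
            paste(features[v == 0], collapse = ", "), call. = FALSE)
    X <- X[, v > 0, drop = FALSE]
    features <- features[v > 0]
    if (length(features) < 2) stop("fewer than two non-constant features.", call. = FALSE)
  }
  C <- stats::cor(X)
  idx <- which(upper.tri(C), arr.ind = TRUE)
  pairs <- tibble::tibble(
    feature_a = features[idx[, 1]],
    feature_b = features[idx[, 2]],
    pearson = C[idx]
  )
  pairs <- dplyr::arrange(pairs, dplyr::desc(abs(.data$pearson)))
  structure(list(matrix = C, pairs = pairs), class = "feature_correlations")
}

#' @export
print.feature_correlations <- function(x, ...) {
  cat(sprintf("<feature_correlations> %d features\n", nrow(x$matrix)))
  print(utils::head(x$pairs, 5))
  invisible(x)
}

#' Hold-one-patient-per-class diagnosis simulation
#'
#' Emulates the clinical deployment scenario: one sample per class is removed
#' (seeded random choice), the SAE is trained on the remaining samples, and
#' the withheld "new patients" are pushed through the trained network to get a
#' predicted class, a softmax confidence score, and their position in the
#' latent space among the training cloud. Per-class Gaussian kernel densities
#' along the class-discriminant latent direction summarise how separable the
#' cohorts are.
#'
#' @param data Data frame with feature columns and a label column; every class
#'   needs at least two samples.
#' @param label Name of the label column.
#' @param config [sae_config()].
#' @param seed Seed for the held-out choice (default `config$seed`).
#' @return An object of class `sae_holdout`: list with `predictions` (one row
#'   per held-out sample, with `.confidence` and latent coordinates), `latent`
#'   (training-sample latent coordinates), `densities` (per-class kernel
#'   density curves along the discriminant axis), and `model`.
#' @export
holdout_simulation <- function(data, label = "label", config = sae_config(),
                               seed = config$seed) {
  data <- tibble::as_tibble(data)
  ft <- ft_parse(data, label)
  counts <- tabulate(ft$y + 1L, ft$k)
  if (any(counts < 2)) stop("every class needs at least two samples.", call. = FALSE)
  held <- withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    vapply(seq_len(ft$k) - 1L, function(cl) {
      idx <- which(ft$y == cl)
      idx[sample.int(length(idx), 1L)]
    }, integer(1))
  })
  train <- data[-held, , drop = FALSE]
  test <- data[held, , drop = FALSE]
  model <- train_sae(train, label, config)

  preds <- stats::predict(model, test)
  preds$.true_class <- factor(as.character(test[[label]]), levels = ft$levels)

  Ztr <- encode(model, train)
  lat <- tibble::as_tibble(as.data.frame(Ztr),
                           .name_repair = ~ paste0(".z", seq_len(ncol(Ztr))))
  lat$.sample <- ft$sample_ids[-held]
  lat$.class <- factor(as.character(train[[label]]), levels = ft$levels)

  densities <- latent_densities(Ztr, lat$.class)

  structure(
    list(predictions = preds, latent = lat, densities = densities,
         model = model, held_out = ft$sample_ids[held]),
    class = "sae_holdout"
  )
}

# 1-D class densities along the discriminant direction in the latent space:
# the direction between the two class means (k = 2), or the leading
# discriminant of the between-class means for k > 2. Gaussian kernel with
# Scott-type bandwidth (stats::bw.nrd).
latent_densities <- function(Z, class) {
  mu <- rowsum(Z, class) / as.vector(table(class))
  dir <- if (nrow(mu) == 2) mu[2, ] - mu[1, ] else {
    mc <- sweep(mu, 2, colMeans(mu))
    svd(mc)$v[, 1]
  }
  nrm <- sqrt(sum(dir^2))
  if (nrm == 0) dir <- c(1, rep(0, ncol(Z) - 1)) else dir <- dir / nrm
  proj <- as.numeric(Z %*% dir)
  purrr::map_dfr(levels(droplevels(class)), function(cl) {
    x <- proj[class == cl]
    if (length(x) < 2 || stats::sd(x) == 0) {
      return(tibble::tibble(class = cl, x = x[1], density = 1))
    }
    d <- stats::density(x, bw = stats::bw.nrd(x), n = 256)
    tibble::tibble(class = cl, x = d$x, density = d$y)
  })
}

#' @export
print.sae_holdout <- function(x, ...) {
  cat(sprintf("<sae_holdout> %d held-out samples\n", nrow(x$predictions)))
  print(dplyr::select(x$predictions, ".sample", ".true_class", ".pred_class",
                      ".confidence"))
  invisible(x)
}
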