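# Internal representation of a samples-by-features table: numeric matrix X,
# 0-based integer labels y, the label level mapping, and bookkeeping fields.

ft_parse <- function(data, label = "label", require_label = TRUE) {
  data <- tibble::as_tibble(data)
  has_label <- label %in% names(data)
  if (require_label && !has_label) {
    stop(sprintf("label column '%s' not found in `data`.", label), call. = FALSE)
  }
  id_col <- intersect(c("sample_id", ".sample"), names(data))[1]
  sample_ids <- if (!is.na(id_col)) as.character(data[[id_col]]) else paste0("sample_", seq_len(nrow(data)))
  drop <- c(label[has_label], if (!is.na(id_col)) id_col)
  feats <- data[setdiff(names(data), drop)]
  bad <- names(feats)[!vapply(feats, is.numeric, logical(1))]
  if (length(bad) > 0) {
    stop("non-numeric feature columns: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(feats)
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at row %d, column '%s'; impute or drop before modelling.",
                 idx[1], colnames(X)[idx[2]]), call. = FALSE)
  }
  if (!all(is.finite(X))) stop("non-finite feature values found.", call. = FALSE)

  out <- list(X = X, feature_names = colnames(X), sample_ids = sample_ids,
              m = nrow(X), d = ncol(X))
  if (has_label) {
    lab <- data[[label]]
    levels <- if (is.factor(lab)) levels(droplevels(lab)) else sort(unique(as.character(lab)))
    y <- match(as.character(lab), levels) - 1L
    if (anyNA(y)) stop("labels could not be mapped to levels.", call. = FALSE)
    out$y <- y
    out$levels <- levels
    out$k <- length(levels)
    if (out$k < 2) stop("need at least two classes.", call. = FALSE)
    if (out$m < 2 * out$k) stop("need at least two samples per class overall (m >= 2k).", call. = FALSE)
  }
  out
}

# Preprocessing fitted on training data only (no leakage): optional log1p,
# then per-feature centring/scaling. Constant features get scale 1.
preproc_fit <- function(X, standardize = TRUE, log_transform = FALSE) {
  if (log_transform) X <- log1p(X)
  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  } else {
    center <- rep(0, ncol(X))
    scale <- rep(1, ncol(X))
  }
  list(center = center, scale = scale, log_transform = log_transform,
       standardize = standardize)
}

preproc_apply <- function(pp, X) {
  if (pp$log_transform) X <- log1p(X)
  sweep(sweep(X, 2, pp$center, "-"), 2, pp$scale, "/")
}
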