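# The double-descent projected training loop.
#
# Phase 1: minibatch ADAM on the composite loss, with the l1,1 projection
# applied to the first encoder layer (after each epoch by default). Phase 2
# ("double descent", the prune-and-retrain scheme with thresholding replaced
# by the projection): rows of W1 that are zero at the end of phase 1 are
# frozen out of all further updates, and the survivors are retrained for a
# second run of epochs with a fresh optimizer state, projection still active.
# Projection radii are always computed from the post-ADAM-step weights.

epoch_seed <- function(seed, epoch) ((abs(seed) %% 100000L) * 10000L + epoch) %% .Machine$integer.max

sae_engine <- function(ft, config, decoder = TRUE) {
  m <- ft$m; d <- ft$d; k <- ft$k
  latent <- if (is.null(config$latent_dim)) k else config$latent_dim
  if (!config$linear_head && latent != k) {
    stop("latent_dim must equal the number of classes unless linear_head = TRUE.",
         call. = FALSE)
  }
  if (any(tabulate(ft$y + 1L, k) == 0L)) {
    stop("every class must occur in the training data.", call. = FALSE)
  }
  pp <- preproc_fit(ft$X, config$standardize, config$log_transform)
  X <- preproc_apply(pp, ft$X)
  y <- ft$y
  bs <- min(config$batch_size, m)
  project_on <- is.finite(config$eta)

  p <- withr::with_seed(config$seed, sae_init_params(
    d, config$hidden_width, latent, k,
    decoder = decoder, linear_head = config$linear_head
  ))
  if (project_on) p$W1 <- project_l11(p$W1, config$eta)

  history <- list()
  trace <- if (config$trace_weights) list() else NULL
  mask <- rep(TRUE, d)   # rows of W1 still trainable
  global_epoch <- 0L

  for (phase in 1:2) {
    st <- adam_init(p)
    for (e in seq_len(config$epochs)) {
      global_epoch <- global_epoch + 1L
      ord <- withr::with_seed(epoch_seed(config$seed, global_epoch), sample.int(m))
      starts <- seq(1L, m, by = bs)
      for (s in starts) {
        idx <- ord[s:min(s + bs - 1L, m)]
        Xb <- X[idx, , drop = FALSE]
        yb <- y[idx]
        fw <- sae_forward(p, Xb, decoder = decoder && config$lambda > 0)
        g <- sae_backward(p, Xb, yb, fw, config$lambda, config$recon_loss,
                          config$huber_delta)
        if (!all(mask)) g$W1[!mask, ] <- 0  # biases stay trainable; only feature rows freeze
        upd <- adam_step(p, g, st, config$learning_rate)
        p <- upd$p; st <- upd$st
        if (!all(mask)) p$W1[!mask, ] <- 0
        if (project_on && config$project_every == "batch") {
          p$W1 <- project_l11(p$W1, config$eta)
        }
      }
      if (project_on && config$project_every == "epoch") {
        p$W1 <- project_l11(p$W1, config$eta)
      }
      losses <- total_loss(p, X, y, config$lambda, config$recon_loss,
                           config$huber_delta)
      history[[global_epoch]] <- tibble::tibble(
        phase = phase, epoch = global_epoch,
        total = losses$total, classification = losses$classification,
        reconstruction = losses$reconstruction,
        nonzero_rows = sum(rowSums(abs(p$W1)) > 0),
        l11_norm = sum(abs(p$W1))
      )
      if (config$trace_weights) {
        trace[[global_epoch]] <- list(W1 = p$W1, b1 = p$b1, W2 = p$W2, b2 = p$b2)
      }
    }
    if (phase == 1L) mask <- rowSums(abs(p$W1)) > 0
  }

  structure(
    list(
      params = p, config = config, preprocessing = pp,
      feature_names = ft$feature_names, levels = ft$levels,
      k = k, latent_dim = latent, d = d, n_train = m,
      mask = mask,
      history = if (length(history)) dplyr::bind_rows(history) else
        tibble::tibble(phase = integer(), epoch = integer(), total = double(),
                       classification = double(), reconstruction = double(),
                       nonzero_rows = integer(), l11_norm = double()),
      weight_trace = trace,
      decoder = decoder
    ),
    class = if (decoder) c("trained_sae", "sae_model") else c("trained_nn", "sae_model")
  )
}

#' Train a sparse supervised autoencoder
#'
#' Fits the supervised autoencoder on a samples-by-features table: an encoder
#' `d -> hidden (ReLU) -> k`, a mirrored decoder, a softmax classifier on the
#' latent coordinates, and the composite loss `cross-entropy + lambda * Huber
#' reconstruction`, minimised by minibatch ADAM under the l1,1 constraint
#' `sum(abs(W1)) <= eta` on the first encoder layer. Training runs the
#' double-descent loop: a constrained first pass, then pruning of the
#' zeroed feature rows and retraining of the survivors. Feature selection is
#' read off the trained first layer with [rank_features()].
#'
#' Preprocessing (optional `log1p`, per-feature centring/scaling) is fitted on
#' the supplied data and stored in the model, so predictions on new data reuse
#' the training statistics.
#'
#' @param data Data frame with numeric feature columns, one label column, and
#'   optionally a `sample_id` column.
#' @param label Name of the label column. Default `"label"`.
#' @param config An [sae_config()].
#' @return An object of class `trained_sae` with elements `params` (weights),
#'   `history` (per-epoch loss tibble), `mask` (features surviving phase 1),
#'   and stored preprocessing. Methods: [predict.sae_model()], `tidy()`,
#'   `glance()`, `autoplot()`.
#' @export
#' @examples
#' sim <- generate_metabolomics(synthetic_preset("tiny"))
#' fit <- train_sae(sim, config = sae_config(eta = 10, epochs = 5, seed = 1))
#' glance(fit)
train_sae <- function(data, label = "label", config = sae_config()) {
  ft <- ft_parse(data, label)
  sae_engine(ft, config, decoder = TRUE)
}

#' Train the plain neural-network baseline
#'
#' The comparator network: identical encoder architecture and softmax head,
#' identical optimizer and schedule, but trained with cross-entropy only — no
#' decoder, no reconstruction term, and no sparsity projection. With
#' `lambda = 0`, `eta = Inf` the SAE's encoder trajectory coincides with this
#' baseline step for step.
#'
#' @inheritParams train_sae
#' @return An object of class `trained_nn`.
#' @export
train_nn_baseline <- function(data, label = "label", config = sae_config()) {
  config$lambda <- 0
  config$eta <- Inf
  ft <- ft_parse(data, label)
  sae_engine(ft, config, decoder = FALSE)
}

#' Map samples to the latent space
#'
#' Applies the model's stored preprocessing and the encoder forward pass
#' `Z = W2' relu(W1' x + b1) + b2`.
#'
#' @param model A fitted `trained_sae` or `trained_nn`.
#' @param data Data frame (or numeric matrix on the raw intensity scale) with
#'   the model's `d` feature columns; a label column, if present, is ignored.
#' @return Numeric matrix (samples x latent_dim) of latent coordinates.
#' @export
encode <- function(model, data) {
  stopifnot(inherits(model, "sae_model"))
  X <- model_matrix(model, data)
  sae_forward(model$params, preproc_apply(model$preprocessing, X),
              decoder = FALSE)$Z
}

#' Reconstruct samples from latent coordinates
#'
#' Decoder forward pass (mirror architecture, ReLU hidden layer, linear
#' output). The reconstruction lives in the preprocessed space in which the
#' network was trained.
#'
#' @param model A fitted `trained_sae`.
#' @param Z Numeric matrix with `latent_dim` columns.
#' @return Numeric matrix (samples x d), preprocessed scale.
#' @export
decode <- function(model, Z) {
  stopifnot(inherits(model, "trained_sae"))
  Z <- as.matrix(Z)
  if (ncol(Z) != model$latent_dim) {
    stop(sprintf("Z must have %d columns.", model$latent_dim), call. = FALSE)
  }
  p <- model$params
  H3 <- pmax(affine(Z, p$W3, p$b3), 0)
  affine(H3, p$W4, p$b4)
}

model_matrix <- function(model, data) {
  if (is.matrix(data)) {
    if (ncol(data) != model$d) stop(sprintf("expected %d feature columns.", model$d), call. = FALSE)
    return(data)
  }
  data <- tibble::as_tibble(data)
  if (all(model$feature_names %in% names(data))) {
    X <- as.matrix(data[model$feature_names])
  } else {
    ft <- ft_parse(data, label = "label", require_label = FALSE)
    if (ft$d != model$d) stop(sprintf("expected %d feature columns.", model$d), call. = FALSE)
    X <- ft$X
  }
  if (anyNA(X) || !all(is.finite(X))) stop("missing or non-finite feature values.", call. = FALSE)
  X
}

#' Select the l1,1 budget by cross-validated accuracy
#'
#' Runs stratified k-fold cross-validation of the supervised autoencoder for
#' every candidate `eta` in `config$eta_grid` and returns the value with the
#' highest mean held-out accuracy; ties are broken towards the smallest `eta`
#' (the sparser model).
#'
#' @inheritParams train_sae
#' @param n_folds Number of folds (default 4).
#' @param seed Seed for the fold assignment (default `config$seed`).
#' @return A list with `eta` (the chosen budget) and `cv_accuracy`, a tibble
#'   of mean held-out accuracy per candidate.
#' @export
select_eta <- function(data, label = "label", config = sae_config(),
                       n_folds = 4, seed = config$seed) {
  grid <- config$eta_grid
  if (length(grid) == 0) stop("`config$eta_grid` is empty.", call. = FALSE)
  if (any(grid < 0)) stop("eta candidates must be non-negative.", call. = FALSE)
  data <- tibble::as_tibble(data)
  folds <- make_folds(data, label, n_folds = n_folds, seed = seed)
  acc <- vapply(grid, function(eta) {
    cfg <- config; cfg$eta <- eta
    per_fold <- vapply(seq_len(n_folds), function(f) {
      tr <- data[folds$fold != f, , drop = FALSE]
      te <- data[folds$fold == f, , drop = FALSE]
      fit <- train_sae(tr, label, cfg)
      pred <- stats::predict(fit, te)
      mean(as.character(pred$.pred_class) == as.character(te[[label]]))
    }, numeric(1))
    mean(per_fold)
  }, numeric(1))
  ord <- order(grid)
  grid <- grid[ord]; acc <- acc[ord]
  list(
    eta = grid[which.max(acc)],  # which.max takes the first (smallest) maximiser
    cv_accuracy = tibble::tibble(eta = grid, accuracy = acc)
  )
}
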