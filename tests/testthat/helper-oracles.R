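# Independent oracles used to verify the package's numerics. These are kept
# deliberately naive (bisection, scalar loops, pairwise enumeration) and share
# no code with the implementation.

# Lagrangian bisection for the Euclidean projection onto the l1 ball:
# find theta >= 0 with sum(pmax(|v| - theta, 0)) = radius, then soft-threshold.
oracle_project_l1 <- function(v, radius) {
  if (sum(abs(v)) <= radius) return(v)
  if (radius == 0) return(rep(0, length(v)))
  lo <- 0
  hi <- max(abs(v))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (sum(pmax(abs(v) - mid, 0)) > radius) lo <- mid else hi <- mid
  }
  theta <- (lo + hi) / 2
  sign(v) * pmax(abs(v) - theta, 0)
}

# Two-stage l1,1 oracle built on the bisection projection.
oracle_project_l11 <- function(W, eta) {
  norms <- apply(W, 1, function(r) sum(abs(r)))
  if (sum(norms) <= eta) return(W)
  t <- pmax(oracle_project_l1(norms, eta), 0)
  out <- W
  for (i in seq_len(nrow(W))) {
    out[i, ] <- if (t[i] == 0) 0 else oracle_project_l1(W[i, ], t[i])
  }
  out
}

# Brute-force metrics: confusion-table scalar loops and pairwise AUC.
oracle_accuracy <- function(truth, estimate) {
  n_ok <- 0
  for (i in seq_along(truth)) if (truth[i] == estimate[i]) n_ok <- n_ok + 1
  n_ok / length(truth)
}

oracle_auc_binary <- function(pos, score) {
  num <- 0; den <- 0
  for (i in which(pos)) {
    for (j in which(!pos)) {
      den <- den + 1
      if (score[i] > score[j]) num <- num + 1
      else if (score[i] == score[j]) num <- num + 0.5
    }
  }
  if (den == 0) NA_real_ else num / den
}

oracle_f1_weighted <- function(truth, estimate) {
  levels <- sort(unique(c(truth, estimate)))
  total <- 0
  for (cl in levels) {
    tp <- fp <- fn <- 0
    for (i in seq_along(truth)) {
      if (truth[i] == cl && estimate[i] == cl) tp <- tp + 1
      if (truth[i] != cl && estimate[i] == cl) fp <- fp + 1
      if (truth[i] == cl && estimate[i] != cl) fn <- fn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    total <- total + f1 * sum(truth == cl)
  }
  total / length(truth)
}

# A hand-checkable model wrapper around explicit weights, bypassing training.
hand_model <- function(params, d, k, latent = k,
                       levels = paste0("class_", seq_len(k) - 1)) {
  structure(
    list(params = params, config = sae_config(),
         preprocessing = list(center = rep(0, d), scale = rep(1, d),
                              log_transform = FALSE, standardize = FALSE),
         feature_names = paste0("f", seq_len(d)), levels = levels,
         k = k, latent_dim = latent, d = d, n_train = 0,
         decoder = !is.null(params$W3)),
    class = c("trained_sae", "sae_model")
  )
}

tiny_data <- function(seed = 0) generate_metabolomics(synthetic_preset("tiny", seed = seed))

# Two well-separated Gaussian blobs, m samples, d features.
blob_data <- function(m = 100, d = 5, sep = 6, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(0:1, length.out = m)
    X <- matrix(rnorm(m * d), m, d) + sep * y
  })
  out <- tibble::as_tibble(as.data.frame(X, check.names = FALSE),
                           .name_repair = ~ paste0("f", seq_len(d)))
  out$label <- factor(paste0("class_", y))
  out$sample_id <- paste0("s", seq_len(m))
  out
}

fast_config <- function(..., epochs = 10, hidden_width = 32) {
  sae_config(epochs = epochs, hidden_width = hidden_width, ...)
}
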