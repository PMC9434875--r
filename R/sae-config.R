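#' Hyperparameter configuration for a supervised autoencoder run
#'
#' One immutable record drives a training run. The composite loss is
#' \eqn{\phi(Z, y) + \lambda\,\psi(\hat X - X)} with \eqn{\phi} the softmax
#' cross-entropy in the latent space and \eqn{\psi} the reconstruction loss
#' (Huber by default, plain squared error via `recon_loss = "l2"`), minimised
#' subject to the l1,1 constraint \eqn{\|W\|_{1,1} \le \eta} on the first
#' encoder layer.
#'
#' @param lambda Non-negative weight of the reconstruction term. Default 1.
#' @param eta Non-negative l1,1 budget for the first encoder layer; `Inf`
#'   disables the constraint. Expressed in standardized-input units.
#' @param hidden_width Hidden layer width (default 96, the reference
#'   architecture for metabolomic tables).
#' @param latent_dim Latent dimension; `NULL` (default) means "number of
#'   classes", fixed when training starts.
#' @param recon_loss `"huber"` (smooth l1; robust to outlier samples) or
#'   `"l2"` (half squared error).
#' @param huber_delta Huber transition point, in standardized units. Default 1.
#' @param learning_rate ADAM step size. Default 1e-3.
#' @param epochs Epochs per descent phase (the double-descent loop runs two
#'   phases of this length). Default 30.
#' @param batch_size Minibatch size; clipped to the number of training samples.
#' @param seed Integer seed controlling initialisation and batch shuffling.
#' @param eta_grid Candidate `eta` values for [select_eta()].
#' @param project_every `"epoch"` (default) applies the l1,1 projection after
#'   each full epoch; `"batch"` after every minibatch.
#' @param standardize Centre/scale each feature using training-set statistics
#'   (default `TRUE`).
#' @param log_transform Apply `log1p()` to intensities before standardising
#'   (default `FALSE`).
#' @param linear_head Add a trainable linear layer between the latent code and
#'   the softmax instead of classifying the latent coordinates directly
#'   (default `FALSE`; the default ties the latent geometry to the classes).
#' @param trace_weights Keep a per-epoch copy of the encoder weights in the
#'   training history (memory-hungry; for diagnostics only).
#' @return A list of class `"sae_config"`.
#' @export
sae_config <- function(lambda = 1,
                       eta = Inf,
                       hidden_width = 96L,
                       latent_dim = NULL,
                       recon_loss = c("huber", "l2"),
                       huber_delta = 1,
                       learning_rate = 1e-3,
                       epochs = 30L,
                       batch_size = 8L,
                       seed = 0L,
                       eta_grid = c(1, 10, 50, 100),
                       project_every = c("epoch", "batch"),
                       standardize = TRUE,
                       log_transform = FALSE,
                       linear_head = FALSE,
                       trace_weights = FALSE) {
  recon_loss <- match.arg(recon_loss)
  project_every <- match.arg(project_every)
  stopifnot(
    lambda >= 0, eta >= 0, hidden_width >= 1, huber_delta > 0,
    learning_rate > 0, epochs >= 0, batch_size >= 1,
    all(eta_grid >= 0)
  )
  structure(
    list(
      lambda = lambda, eta = eta,
      hidden_width = as.integer(hidden_width),
      latent_dim = if (is.null(latent_dim)) NULL else as.integer(latent_dim),
      recon_loss = recon_loss, huber_delta = huber_delta,
      learning_rate = learning_rate, epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), seed = as.integer(seed),
      eta_grid = eta_grid, project_every = project_every,
      standardize = isTRUE(standardize), log_transform = isTRUE(log_transform),
      linear_head = isTRUE(linear_head), trace_weights = isTRUE(trace_weights)
    ),
    class = "sae_config"
  )
}

#' @export
print.sae_config <- function(x, ...) {
  cat("<sae_config>\n")
  cat(sprintf("  loss: cross-entropy + %g * %s reconstruction\n", x$lambda, x$recon_loss))
  cat(sprintf("  constraint: ||W1||_1,1 <= %g\n", x$eta))
  cat(sprintf("  architecture: d -> %d (ReLU) -> k; mirrored decoder\n", x$hidden_width))
  cat(sprintf("  ADAM lr %g, %d epochs x 2 phases, batch %d, seed %d\n",
              x$learning_rate, x$epochs, x$batch_size, x$seed))
  invisible(x)
}
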