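# Network arithmetic for the supervised autoencoder.
#
# Architecture (the reference layout): encoder d -> hidden_width (ReLU) ->
# latent_dim (linear); decoder mirrors it, latent_dim -> hidden_width (ReLU)
# -> d (linear). Classification is softmax applied directly to the latent
# coordinates (latent_dim = number of classes), optionally through one extra
# linear layer when `linear_head = TRUE`.
#
# Parameters are drawn with the uniform fan-in scheme U(-1/sqrt(fan_in),
# 1/sqrt(fan_in)). Encoder parameters are drawn before decoder parameters so
# that, for a given seed, a decoder-free network (the plain NN baseline) gets
# bit-identical encoder initialisation.

init_linear <- function(fan_in, fan_out) {
  b <- 1 / sqrt(fan_in)
  list(W = matrix(stats::runif(fan_in * fan_out, -b, b), fan_in, fan_out),
       b = stats::runif(fan_out, -b, b))
}

sae_init_params <- function(d, hidden, latent, k, decoder = TRUE, linear_head = FALSE) {
  l1 <- init_linear(d, hidden)
  l2 <- init_linear(hidden, latent)
  p <- list(W1 = l1$W, b1 = l1$b, W2 = l2$W, b2 = l2$b)
  if (linear_head) {
    lh <- init_linear(latent, k)
    p$Wh <- lh$W; p$bh <- lh$b
  }
  if (decoder) {
    l3 <- init_linear(latent, hidden)
    l4 <- init_linear(hidden, d)
    p$W3 <- l3$W; p$b3 <- l3$b; p$W4 <- l4$W; p$b4 <- l4$b
  }
  p
}

affine <- function(X, W, b) sweep(X %*% W, 2, b, "+")

# Full forward pass; keeps pre-activations for backprop.
sae_forward <- function(p, X, decoder = TRUE) {
  H1p <- affine(X, p$W1, p$b1)
  H1 <- pmax(H1p, 0)
  Z <- affine(H1, p$W2, p$b2)
  out <- list(H1p = H1p, H1 = H1, Z = Z)
  out$logits <- if (!is.null(p$Wh)) affine(Z, p$Wh, p$bh) else Z
  if (decoder && !is.null(p$W3)) {
    H3p <- affine(Z, p$W3, p$b3)
    H3 <- pmax(H3p, 0)
    out$H3p <- H3p; out$H3 <- H3
    out$Xhat <- affine(H3, p$W4, p$b4)
  }
  out
}

#' Row-wise softmax class probabilities from latent coordinates
#'
#' The classifier head of the supervised autoencoder: softmax applied directly
#' to the latent coordinates (one per class). Numerically stabilised by
#' subtracting the row maximum, so it is invariant to adding a constant to a
#' row.
#'
#' @param Z Numeric matrix (samples x classes) of latent coordinates / logits.
#' @return Matrix of the same shape; rows are non-negative and sum to one.
#' @export
classify_logits <- function(Z) {
  Z <- as.matrix(Z)
  Zs <- Z - apply(Z, 1, max)
  E <- exp(Zs)
  E / rowSums(E)
}

cross_entropy <- function(P, y) {
  # y is 0-based; P rows are softmax probabilities
  p <- P[cbind(seq_len(nrow(P)), y + 1L)]
  -mean(log(pmax(p, 1e-300)))
}

huber_value <- function(r, delta) {
  a <- abs(r)
  ifelse(a <= delta, 0.5 * r^2, delta * (a - 0.5 * delta))
}

huber_grad <- function(r, delta) pmax(pmin(r, delta), -delta)

recon_value <- function(r, recon_loss, delta) {
  if (recon_loss == "huber") mean(huber_value(r, delta)) else mean(0.5 * r^2)
}

recon_grad <- function(r, recon_loss, delta) {
  g <- if (recon_loss == "huber") huber_grad(r, delta) else r
  g / length(r)
}

#' Composite supervised-autoencoder loss on preprocessed data
#'
#' Evaluates the training criterion `cross-entropy + lambda * reconstruction`
#' for a fitted (or hand-constructed) network on data already in the model's
#' preprocessed space. The cross-entropy is averaged over samples; the
#' reconstruction loss (Huber: quadratic below `huber_delta`, linear above; or
#' half squared error) is averaged over all matrix entries.
#'
#' @param params Named list of network weights (`W1`, `b1`, ... as produced by
#'   training; decoder weights required unless `lambda = 0`).
#' @param X Numeric matrix (samples x features), preprocessed scale.
#' @param y Integer class labels in `0:(k-1)`.
#' @param lambda Non-negative reconstruction weight.
#' @param recon_loss `"huber"` or `"l2"`.
#' @param huber_delta Huber transition point.
#' @return A list with components `total`, `classification`, `reconstruction`.
#' @export
total_loss <- function(params, X, y, lambda = 1, recon_loss = "huber",
                       huber_delta = 1) {
  X <- as.matrix(X)
  y <- as.integer(y)
  k <- ncol(if (!is.null(params$Wh)) params$Wh else params$W2)
  if (any(y < 0L | y >= k)) stop("labels out of range 0..k-1.", call. = FALSE)
  fw <- sae_forward(params, X, decoder = lambda > 0)
  cls <- cross_entropy(classify_logits(fw$logits), y)
  rec <- if (lambda > 0) {
    if (is.null(fw$Xhat)) stop("decoder weights required when lambda > 0.", call. = FALSE)
    recon_value(fw$Xhat - X, recon_loss, huber_delta)
  } else if (!is.null(params$W3)) {
    recon_value(sae_forward(params, X, decoder = TRUE)$Xhat - X, recon_loss, huber_delta)
  } else 0
  list(total = cls + lambda * rec, classification = cls, reconstruction = rec)
}

# Gradients of the per-batch loss wrt all parameters. Returns a list with the
# same names as `p`. ReLU subgradient at 0 is taken as 0.
sae_backward <- function(p, X, y, fw, lambda, recon_loss, delta) {
  nb <- nrow(X)
  k <- ncol(fw$logits)
  P <- classify_logits(fw$logits)
  Yh <- matrix(0, nb, k)
  Yh[cbind(seq_len(nb), y + 1L)] <- 1
  Glog <- (P - Yh) / nb

  g <- list()
  if (!is.null(p$Wh)) {
    g$Wh <- crossprod(fw$Z, Glog)
    g$bh <- colSums(Glog)
    GZ <- Glog %*% t(p$Wh)
  } else {
    GZ <- Glog
  }

  if (lambda > 0 && !is.null(p$W4)) {
    R <- fw$Xhat - X
    G4 <- lambda * recon_grad(R, recon_loss, delta)
    g$W4 <- crossprod(fw$H3, G4)
    g$b4 <- colSums(G4)
    G3 <- (G4 %*% t(p$W4)) * (fw$H3p > 0)
    g$W3 <- crossprod(fw$Z, G3)
    g$b3 <- colSums(G3)
    GZ <- GZ + G3 %*% t(p$W3)
  } else if (!is.null(p$W4)) {
    g$W4 <- p$W4 * 0; g$b4 <- p$b4 * 0
    g$W3 <- p$W3 * 0; g$b3 <- p$b3 * 0
  }

  g$W2 <- crossprod(fw$H1, GZ)
  g$b2 <- colSums(GZ)
  G1 <- (GZ %*% t(p$W2)) * (fw$H1p > 0)
  g$W1 <- crossprod(X, G1)
  g$b1 <- colSums(G1)
  g
}

adam_init <- function(p) {
  list(m = lapply(p, function(x) x * 0), v = lapply(p, function(x) x * 0), t = 0L)
}

adam_step <- function(p, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(g)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    p[[nm]] <- p[[nm]] - lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(p = p, st = st)
}
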