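#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Training-history curves of a fitted model
#'
#' Loss components and the number of selected features per epoch; the dashed
#' vertical line marks the phase-1 to phase-2 (prune and retrain) transition.
#'
#' @param object A `trained_sae` or `trained_nn`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sae_model <- function(object, ...) {
  h <- tidyr::pivot_longer(
    object$history,
    c("total", "classification", "reconstruction"),
    names_to = "component", values_to = "loss"
  )
  phase2 <- min(object$history$epoch[object$history$phase == 2], Inf)
  p <- ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$loss,
                                       colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss",
                  title = "Supervised autoencoder training history") +
    ggplot2::theme_minimal()
  if (is.finite(phase2)) {
    p <- p + ggplot2::geom_vline(xintercept = phase2 - 0.5, linetype = "dashed")
  }
  p
}

#' Latent-space plot of training samples and held-out patients
#'
#' The two-dimensional latent space (one coordinate per class): training
#' samples as points coloured by true class, held-out "new patients" as
#' squares labelled with their softmax confidence score.
#'
#' @param object An `sae_holdout` from [holdout_simulation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sae_holdout <- function(object, ...) {
  stopifnot(".z2" %in% names(object$latent))
  pr <- object$predictions
  ggplot2::ggplot(object$latent, ggplot2::aes(.data$.z1, .data$.z2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$.class), alpha = 0.7) +
    ggplot2::geom_point(data = pr,
                        ggplot2::aes(fill = .data$.pred_class),
                        shape = 22, size = 4, colour = "black") +
    ggplot2::geom_text(data = pr,
                       ggplot2::aes(label = sprintf("%.2f", .data$.confidence)),
                       vjust = -1.2, size = 3) +
    ggplot2::labs(x = "latent coordinate 1", y = "latent coordinate 2",
                  title = "Latent space with held-out patients (squares)",
                  colour = "class", fill = "predicted") +
    ggplot2::theme_minimal()
}

#' Kernel-density separation of the classes in the latent space
#'
#' Per-class Gaussian kernel densities along the discriminant direction of the
#' latent space, as computed by [holdout_simulation()].
#'
#' @param x An `sae_holdout`.
#' @return A ggplot object.
#' @export
plot_latent_densities <- function(x) {
  stopifnot(inherits(x, "sae_holdout"))
  ggplot2::ggplot(x$densities,
                  ggplot2::aes(.data$x, .data$density, colour = .data$class,
                               fill = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_area(alpha = 0.2, position = "identity") +
    ggplot2::labs(x = "discriminant latent coordinate", y = "density",
                  title = "Class distributions in the latent space") +
    ggplot2::theme_minimal()
}

#' Benchmark comparison plot
#'
#' Per-split metric values by method, with the per-method mean overlaid.
#'
#' @param object An `sae_cv` from [cross_validate()].
#' @param metric One of `"f1"`, `"accuracy"`, `"auc"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sae_cv <- function(object, metric = c("f1", "accuracy", "auc"), ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object$results,
                  ggplot2::aes(.data$method, .data[[metric]])) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "red") +
    ggplot2::labs(title = sprintf("Cross-validated %s by method", metric)) +
    ggplot2::theme_minimal()
}

#' Heatmap of the first-layer weight matrix
#'
#' Features versus hidden units; under the l1,1 constraint most feature rows
#' are exactly zero (horizontal stripes of colour on a blank background),
#' whereas the unstructured l1 projection scatters the surviving weights.
#'
#' @param model A `trained_sae` or `trained_nn`.
#' @param max_features Show at most this many features (those with the
#'   largest row norms), to keep wide tables readable. Default 100.
#' @return A ggplot object.
#' @export
plot_weight_matrix <- function(model, max_features = 100) {
  stopifnot(inherits(model, "sae_model"))
  W <- model$params$W1
  norms <- rowSums(abs(W))
  keep <- order(-norms)[seq_len(min(max_features, nrow(W)))]
  keep <- sort(keep)
  df <- tidyr::expand_grid(
    feature = factor(model$feature_names[keep], levels = model$feature_names[keep]),
    hidden = seq_len(ncol(W))
  )
  df$weight <- as.numeric(t(W[keep, , drop = FALSE]))
  ggplot2::ggplot(df, ggplot2::aes(.data$hidden, .data$feature,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "hidden unit", y = "feature",
                  title = "First-layer connection weights") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' Correlation heatmap of selected features
#'
#' @param object A `feature_correlations` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_correlations <- function(object, ...) {
  C <- object$matrix
  df <- tidyr::expand_grid(
    feature_a = factor(rownames(C), levels = rownames(C)),
    feature_b = factor(colnames(C), levels = colnames(C))
  )
  df$pearson <- as.numeric(t(C))
  ggplot2::ggplot(df, ggplot2::aes(.data$feature_b, .data$feature_a,
                                   fill = .data$pearson)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "blue",
                                  mid = "white", high = "red") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Pearson correlations of selected features") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
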