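#' Predict class labels with softmax confidence scores
#'
#' Applies the model's stored preprocessing, encodes each sample to the latent
#' space, and converts the latent coordinates to class probabilities with the
#' softmax head. The confidence score of a prediction is the maximum softmax
#' probability, which for k classes lies in `[1/k, 1]`.
#'
#' @param object A fitted `trained_sae` or `trained_nn`.
#' @param new_data Data frame with the model's feature columns (a label
#'   column, if present, is ignored).
#' @param ... Unused.
#' @return A tibble with one row per sample: `.sample`, `.pred_class` (factor
#'   on the training levels), one `.prob_<level>` column per class,
#'   `.confidence`, and latent coordinates `.z1 ... .z<latent_dim>`.
#' @export
predict.sae_model <- function(object, new_data, ...) {
  new_data <- if (is.matrix(new_data)) new_data else tibble::as_tibble(new_data)
  Z <- encode(object, new_data)
  fw_logits <- if (!is.null(object$params$Wh)) {
    affine(Z, object$params$Wh, object$params$bh)
  } else Z
  P <- classify_logits(fw_logits)
  pred_idx <- max.col(P, ties.method = "first")
  ids <- if (!is.matrix(new_data) && "sample_id" %in% names(new_data)) {
    as.character(new_data$sample_id)
  } else paste0("sample_", seq_len(nrow(Z)))
  out <- tibble::tibble(
    .sample = ids,
    .pred_class = factor(object$levels[pred_idx], levels = object$levels),
    .confidence = P[cbind(seq_len(nrow(P)), pred_idx)]
  )
  probs <- tibble::as_tibble(as.data.frame(P))
  names(probs) <- paste0(".prob_", object$levels)
  lat <- tibble::as_tibble(as.data.frame(Z))
  names(lat) <- paste0(".z", seq_len(ncol(Z)))
  dplyr::bind_cols(out[1:2], probs, out[3], lat)
}

#' Per-sample predictions with confidence and latent coordinates
#'
#' Convenience alias of [predict.sae_model()] for use in diagnosis workflows:
#' each new sample gets a predicted class, the full softmax probability
#' vector, a confidence score (maximum probability), and its latent
#' coordinates for plotting among the training cloud.
#'
#' @inheritParams predict.sae_model
#' @param model A fitted `trained_sae` or `trained_nn`.
#' @return See [predict.sae_model()].
#' @export
predict_with_confidence <- function(model, new_data) {
  stats::predict(model, new_data)
}

#' @export
print.sae_model <- function(x, ...) {
  kind <- if (inherits(x, "trained_sae")) "supervised autoencoder" else "NN baseline"
  cat(sprintf("<%s> %d features -> %d hidden -> %d latent, %d classes\n",
              kind, x$d, x$config$hidden_width, x$latent_dim, x$k))
  cat(sprintf("  trained on %d samples, %d epochs x 2 phases\n",
              x$n_train, x$config$epochs))
  if (is.finite(x$config$eta)) {
    cat(sprintf("  l1,1 budget %g; %d / %d feature rows selected\n",
                x$config$eta, sum(rowSums(abs(x$params$W1)) > 0), x$d))
  }
  invisible(x)
}
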