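#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fitted model
#'
#' @param x A `trained_sae` or `trained_nn`.
#' @param ... Unused.
#' @return A tibble with one row per epoch: `phase`, `epoch`, the loss
#'   components, the number of nonzero feature rows of the first layer, and
#'   its l1,1 norm.
#' @export
tidy.sae_model <- function(x, ...) x$history

#' One-row summary of a fitted model
#'
#' @param x A `trained_sae` or `trained_nn`.
#' @param ... Unused.
#' @return A one-row tibble: final losses, number of selected features,
#'   l1,1 norm and budget.
#' @export
glance.sae_model <- function(x, ...) {
  last <- utils::tail(x$history, 1)
  tibble::tibble(
    n_train = x$n_train, d = x$d, k = x$k,
    epochs = nrow(x$history),
    total_loss = last$total,
    classification_loss = last$classification,
    reconstruction_loss = last$reconstruction,
    n_selected = sum(rowSums(abs(x$params$W1)) > 0),
    l11_norm = sum(abs(x$params$W1)),
    eta = x$config$eta
  )
}

#' Per-split benchmark results
#'
#' @param x An `sae_cv` object from [cross_validate()].
#' @param ... Unused.
#' @return A tibble with one row per (seed, fold, method): `accuracy`, `auc`,
#'   `f1`.
#' @export
tidy.sae_cv <- function(x, ...) x$results

#' Aggregated benchmark results
#'
#' Means over all train/test splits, per method — the quantities reported by
#' the benchmark protocol.
#'
#' @param x An `sae_cv` object.
#' @param ... Unused.
#' @return A tibble with one row per method: `n_splits`, mean `accuracy`,
#'   `auc` and `f1`.
#' @export
glance.sae_cv <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$results, .data$method),
    n_splits = dplyr::n(),
    accuracy = mean(.data$accuracy),
    auc = mean(.data$auc, na.rm = TRUE),
    f1 = mean(.data$f1),
    .groups = "drop"
  )
}
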