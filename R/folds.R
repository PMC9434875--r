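#' Assign samples to cross-validation folds
#'
#' Partitions the rows of `data` into `n_folds` disjoint, covering folds.
#' Folds are stratified by class by default (each class is shuffled and dealt
#' out round-robin) so that small-class datasets keep every class represented
#' in every training split; if some class has fewer members than folds, the
#' assignment falls back to an unstratified random partition with a warning.
#'
#' @param data Data frame with a label column.
#' @param label Name of the label column.
#' @param n_folds Number of folds (>= 2). Default 4.
#' @param seed Integer seed; the same seed always yields the same folds.
#' @param stratified Stratify by class (default `TRUE`).
#' @return A tibble with columns `row` (1..m), `sample_id`, `label`, `fold`.
#' @export
make_folds <- function(data, label = "label", n_folds = 4, seed = 0,
                       stratified = TRUE) {
  if (n_folds < 2) stop("`n_folds` must be at least 2.", call. = FALSE)
  data <- tibble::as_tibble(data)
  if (!label %in% names(data)) {
    stop(sprintf("label column '%s' not found.", label), call. = FALSE)
  }
  y <- as.character(data[[label]])
  m <- length(y)
  if (m < n_folds) stop("fewer samples than folds.", call. = FALSE)
  fold <- integer(m)
  if (stratified && min(table(y)) < n_folds) {
    warning("some class has fewer members than folds; falling back to unstratified folds.",
            call. = FALSE)
    stratified <- FALSE
  }
  ids <- if ("sample_id" %in% names(data)) as.character(data$sample_id) else
    paste0("sample_", seq_len(m))
  # iterate classes in sorted order and order candidates by sample id before
  # shuffling, so the id -> fold map does not depend on the row order
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    if (stratified) {
      for (cl in sort(unique(y))) {
        idx <- which(y == cl)
        idx <- idx[order(ids[idx])]
        fold[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      idx <- order(ids)
      fold[sample(idx)] <- rep_len(seq_len(n_folds), m)
    }
  })
  tibble::tibble(row = seq_len(m), sample_id = ids, label = y, fold = fold)
}
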