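#' Classification metrics: accuracy, AUC, weighted F1
#'
#' Computes the three benchmark metrics from true labels, predicted labels and
#' class probability scores.
#'
#' * accuracy — fraction of correct predictions;
#' * AUC — area under the ROC curve, computed by the rank (Mann–Whitney)
#'   statistic on the class-1 probability for two classes; for more classes,
#'   the unweighted mean of one-vs-rest AUCs. `NA` when the truth contains a
#'   single class;
#' * F1 — per-class F1 combined as the support-weighted average (the
#'   convention preferred for unbalanced datasets); `f1_average = "macro"`
#'   gives the plain mean instead.
#'
#' @param truth True labels (factor, character or integer).
#' @param estimate Predicted labels, same coding as `truth`.
#' @param prob Probability scores: for two classes either a vector with the
#'   probability of the second (positive) level or a matrix of per-class
#'   probabilities; for k > 2 a samples-by-classes matrix whose columns follow
#'   the sorted class levels.
#' @param f1_average `"weighted"` (default) or `"macro"`.
#' @return A one-row tibble with columns `accuracy`, `auc`, `f1`.
#' @export
#' @examples
#' compute_metrics(c(0, 0, 1, 1), c(0, 1, 0, 1), c(0.1, 0.6, 0.4, 0.9))
compute_metrics <- function(truth, estimate, prob = NULL,
                            f1_average = c("weighted", "macro")) {
  f1_average <- match.arg(f1_average)
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  if (length(truth) != length(estimate)) stop("length mismatch.", call. = FALSE)
  levels <- sort(unique(c(truth, estimate)))
  acc <- mean(truth == estimate)
  tibble::tibble(
    accuracy = acc,
    auc = metric_auc(truth, prob, levels),
    f1 = metric_f1(truth, estimate, levels, f1_average)
  )
}

# Rank-statistic AUC for one positive class: P(score_pos > score_neg) with
# ties counted half.
auc_binary <- function(pos, score) {
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

metric_auc <- function(truth, prob, levels) {
  if (is.null(prob)) return(NA_real_)
  if (length(unique(truth)) < 2) return(NA_real_)
  if (is.matrix(prob) || is.data.frame(prob)) {
    prob <- as.matrix(prob)
    if (length(levels) == 2) return(auc_binary(truth == levels[2], prob[, 2]))
    # one-vs-rest macro average over classes present in the truth
    present <- which(levels %in% unique(truth))
    mean(vapply(present, function(j) auc_binary(truth == levels[j], prob[, j]),
                numeric(1)))
  } else {
    if (length(levels) != 2) {
      stop("vector `prob` is only valid for two classes.", call. = FALSE)
    }
    auc_binary(truth == levels[2], as.numeric(prob))
  }
}

metric_f1 <- function(truth, estimate, levels, average) {
  f1 <- support <- numeric(length(levels))
  for (j in seq_along(levels)) {
    cl <- levels[j]
    tp <- sum(truth == cl & estimate == cl)
    fp <- sum(truth != cl & estimate == cl)
    fn <- sum(truth == cl & estimate != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[j] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    support[j] <- sum(truth == cl)
  }
  if (average == "weighted") {
    sum(f1 * support) / sum(support)
  } else {
    mean(f1[support > 0])
  }
}
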