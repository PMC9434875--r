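#' Row-wise l1 norms of a weight matrix
#'
#' @param W Numeric matrix (rows index input features, columns hidden units).
#' @return Numeric vector of length `nrow(W)`; entry i is `sum(abs(W[i, ]))`.
#' @export
#' @examples
#' l1_norm_rows(rbind(c(1, -2), c(0, 0)))
l1_norm_rows <- function(W) {
  W <- as.matrix(W)
  if (!all(is.finite(W))) stop("`W` must contain only finite values.", call. = FALSE)
  rowSums(abs(W))
}

#' Euclidean projection onto the l1 ball
#'
#' Projects a vector onto \eqn{\{u : \|u\|_1 \le r\}} with the exact sort-based
#' algorithm (O(n log n)): find the soft-threshold \eqn{\theta \ge 0} such that
#' \eqn{\sum_i \max(|v_i| - \theta, 0) = r} and shrink every coordinate towards
#' zero by \eqn{\theta}. Vectors already inside the ball are returned unchanged.
#'
#' @param v Finite numeric vector.
#' @param radius Non-negative l1 budget.
#' @return Numeric vector, the projection of `v`.
#' @export
#' @examples
#' project_l1_ball(c(2, 1), 1)   # c(1, 0)
project_l1_ball <- function(v, radius) {
  if (length(radius) != 1L || !is.finite(radius) || radius < 0) {
    stop("`radius` must be a single non-negative finite number.", call. = FALSE)
  }
  if (!all(is.finite(v))) stop("`v` must contain only finite values.", call. = FALSE)
  a <- abs(v)
  if (sum(a) <= radius) return(v)
  if (radius == 0) return(rep(0, length(v)))
  u <- sort(a, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u > (css - radius) / seq_along(u)))
  theta <- (css[rho] - radius) / rho
  sign(v) * pmax(a - theta, 0)
}

#' Per-row l1 budgets for the l1,1 projection
#'
#' First stage of the two-stage l1,1 projection: the vector of row l1 norms is
#' itself projected onto the l1 ball of radius `eta`, yielding a non-negative
#' budget \eqn{t_i} per row. Rows with small norms receive \eqn{t_i = 0}, which
#' eliminates the corresponding feature entirely in the second stage.
#'
#' @param row_norms Non-negative numeric vector of per-row l1 norms.
#' @param eta Non-negative total l1,1 budget.
#' @return Non-negative numeric vector `t` with `sum(t) <= eta`.
#' @export
compute_row_radii <- function(row_norms, eta) {
  if (length(eta) != 1L || is.na(eta) || eta < 0) {
    stop("`eta` must be a single non-negative number.", call. = FALSE)
  }
  if (any(row_norms < 0)) stop("`row_norms` must be non-negative.", call. = FALSE)
  if (is.infinite(eta)) return(as.numeric(row_norms))
  pmax(project_l1_ball(as.numeric(row_norms), eta), 0)
}

#' Two-stage l1,1 (row-structured) projection
#'
#' Projects a weight matrix so that the sum over rows of each row's l1 norm is
#' at most `eta`. The operator is the composition used for embedded feature
#' selection: compute the per-row radii \eqn{t_i} with [compute_row_radii()],
#' then project each row onto its own l1 ball of radius \eqn{t_i}. Rows whose
#' radius is zero come out exactly zero — whole features are deselected, unlike
#' the unstructured projection [project_l1_matrix()], which only zeroes
#' individual weights.
#'
#' @param W Finite numeric matrix.
#' @param eta Non-negative l1,1 budget.
#' @return Matrix of the same shape with `sum(abs(.)) <= eta`.
#' @export
#' @examples
#' project_l11(rbind(c(2, 0), c(0, 1)), 1)  # second row eliminated
project_l11 <- function(W, eta) {
  W <- as.matrix(W)
  if (!all(is.finite(W))) stop("`W` must contain only finite values.", call. = FALSE)
  if (length(eta) != 1L || is.na(eta) || eta < 0) {
    stop("`eta` must be a single non-negative number.", call. = FALSE)
  }
  if (is.infinite(eta)) return(W)
  norms <- rowSums(abs(W))
  if (sum(norms) <= eta) return(W)
  t <- compute_row_radii(norms, eta)
  out <- W
  out[t == 0, ] <- 0
  shrink <- which(t > 0 & norms > t)
  for (i in shrink) out[i, ] <- project_l1_ball(W[i, ], t[i])
  out
}

#' Unstructured l1 projection of a matrix
#'
#' Euclidean projection of the vectorised matrix onto the l1 ball of radius
#' `eta` (a single global soft-threshold). Provided as the unstructured
#' comparator to [project_l11()]: it sparsifies individual weights but does not
#' zero whole rows, so it selects weights rather than features.
#'
#' @inheritParams project_l11
#' @return Matrix of the same shape with `sum(abs(.)) <= eta`.
#' @export
project_l1_matrix <- function(W, eta) {
  W <- as.matrix(W)
  if (!all(is.finite(W))) stop("`W` must contain only finite values.", call. = FALSE)
  if (length(eta) != 1L || is.na(eta) || eta < 0) {
    stop("`eta` must be a single non-negative number.", call. = FALSE)
  }
  if (is.infinite(eta)) return(W)
  out <- project_l1_ball(as.numeric(W), eta)
  matrix(out, nrow = nrow(W), ncol = ncol(W), dimnames = dimnames(W))
}
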