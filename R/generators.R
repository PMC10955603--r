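#' Hierarchical semantic task (binary tree of items and features)
#'
#' Builds the classic semantic-learning task in which \eqn{P = 2^{depth}}
#' items (the leaves of a balanced binary tree, e.g. eight members of the
#' living kingdom for `depth = 3`) are mapped to hierarchically structured
#' feature vectors. Inputs are one-hot item codes scaled by \eqn{\sqrt{P}} so
#' that the input correlation is exactly whitened (\eqn{\Sigma^{xx} = I}).
#'
#' Targets assign one feature slot per tree node: a root-membership slot of
#' value 1 shared by all items, and, for every internal node at level
#' \eqn{\ell = 0, \dots, depth - 1}, a slot holding \eqn{+\sigma_\ell} for
#' items under the node's left child, \eqn{-\sigma_\ell} for items under its
#' right child and 0 for items outside the node's subtree, with per-level
#' magnitude \eqn{\sigma_\ell = 1/\sqrt{\ell + 2}}. This yields
#' \eqn{N_i = N_o = P}, a full-rank \eqn{\Sigma^{yx}} (the feature rows are
#' mutually orthogonal), and the nested block structure of the tree in the
#' task's input representational similarity \eqn{\tilde V \tilde S \tilde
#' V^T}: items under the same subtree are more similar. The construction is
#' deterministic; any full-rank hierarchical feature assignment defines the
#' same class of task, and this one is fixed for reproducibility.
#'
#' @param depth tree depth, at least 1 (`depth = 3` gives the 8-item task).
#' @param seed accepted for interface symmetry with the random generators;
#'   unused, since the construction is deterministic.
#' @return A [linear_task()] with `ni = no = p = 2^depth`.
#' @examples
#' task <- make_hierarchy_task(3)
#' task_svd(task)$rank # 8
#' @export
make_hierarchy_task <- function(depth, seed = NULL) {
  stopifnot(is.numeric(depth), length(depth) == 1L, depth >= 1, depth == round(depth))
  p <- 2L^as.integer(depth)
  rows <- vector("list", p)
  rows[[1]] <- rep(1, p) # root membership
  r <- 1L
  for (lev in 0:(depth - 1L)) {
    n_nodes <- 2L^lev
    width <- p %/% n_nodes
    half <- width %/% 2L
    mag <- 1 / sqrt(lev + 2)
    for (node in seq_len(n_nodes)) {
      vec <- numeric(p)
      left <- (node - 1L) * width
      vec[left + seq_len(half)] <- mag
      vec[left + half + seq_len(half)] <- -mag
      r <- r + 1L
      rows[[r]] <- vec
    }
  }
  Y <- do.call(rbind, rows)
  X <- sqrt(p) * diag(p)
  linear_task(X, Y)
}

#' Random whitened task with controllable singular values
#'
#' Generates a task whose input matrix has orthogonal columns scaled so that
#' \eqn{\Sigma^{xx} = I} exactly (with \eqn{P = N_i} samples), and whose
#' input-output correlation \eqn{\Sigma^{yx}} is synthesised from random
#' orthonormal singular vectors with full rank \eqn{\min(N_i, N_o)}. By
#' default the singular values are drawn uniformly from \eqn{[0.5, 2]} and
#' sorted, keeping every mode's learning timescale within a factor of four
#' of the others; supplying `singular_values` realises them exactly.
#'
#' @param ni,no input and output dimensions (at least 1).
#' @param seed integer seed; the same seed reproduces the task exactly.
#' @param singular_values optional vector of `min(ni, no)` positive values,
#'   descending order not required (they are sorted).
#' @return A [linear_task()] with `p = ni` samples.
#' @export
make_random_whitened_task <- function(ni, no, seed = NULL, singular_values = NULL) {
  stopifnot(ni >= 1, no >= 1)
  k <- min(ni, no)
  if (!is.null(singular_values)) {
    if (length(singular_values) > k) {
      stop(sprintf(
        "got %d singular values but min(ni, no) = %d admits at most %d",
        length(singular_values), k, k
      ), call. = FALSE)
    }
    if (length(singular_values) < k) {
      stop(sprintf(
        "need all %d = min(ni, no) singular values to build a full-rank task",
        k
      ), call. = FALSE)
    }
    if (any(singular_values <= 0)) {
      stop("singular values must be positive", call. = FALSE)
    }
  }
  with_seed(seed, {
    s <- if (is.null(singular_values)) {
      sort(stats::runif(k, 0.5, 2), decreasing = TRUE)
    } else {
      sort(as.numeric(singular_values), decreasing = TRUE)
    }
    u <- rand_orthonormal(no, k)
    v <- rand_orthonormal(ni, k)
    m <- u %*% (s * t(v)) # U diag(s) V^T
    q <- rand_orthonormal(ni, ni)
    X <- sqrt(ni) * q # Sigma_xx = (1/P) X X^T = I exactly
    linear_task(X, m %*% X)
  })
}
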