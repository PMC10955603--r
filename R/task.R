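#' Supervised task as paired input/target matrices
#'
#' Bundles the \eqn{P} training pairs of a supervised task into an input
#' matrix \eqn{X} (\eqn{N_i \times P}, one column per sample) and a target
#' matrix \eqn{Y} (\eqn{N_o \times P}). All downstream dynamics depend on the
#' data only through the correlation statistics of [compute_correlations()].
#'
#' @param X numeric matrix, `ni` rows and `p` columns (inputs as columns).
#' @param Y numeric matrix, `no` rows and the same `p` columns (targets).
#' @return An object of class `linear_task` with elements `X`, `Y`, `ni`,
#'   `no`, `p`.
#' @examples
#' task <- linear_task(sqrt(2) * diag(2), sqrt(2) * diag(c(1, 2)))
#' compute_correlations(task)
#' @export
linear_task <- function(X, Y) {
  check_finite_matrix(X, "X")
  check_finite_matrix(Y, "Y")
  if (ncol(X) != ncol(Y)) {
    stop("X and Y must have the same number of columns (samples)", call. = FALSE)
  }
  if (ncol(X) < 1L) stop("a task needs at least one sample", call. = FALSE)
  structure(
    list(X = X, Y = Y, ni = nrow(X), no = nrow(Y), p = ncol(X)),
    class = "linear_task"
  )
}

#' @export
print.linear_task <- function(x, ...) {
  cat(sprintf(
    "<linear_task> Ni = %d inputs, No = %d targets, P = %d samples\n",
    x$ni, x$no, x$p
  ))
  invisible(x)
}

#' Correlation statistics of a task
#'
#' Computes the sample-average input correlation
#' \eqn{\Sigma^{xx} = \frac{1}{P}\sum_n x_n x_n^T}, input-output correlation
#' \eqn{\Sigma^{yx} = \frac{1}{P}\sum_n y_n x_n^T} and the mean squared
#' target norm \eqn{\frac{1}{P}\sum_n \|y_n\|^2}. These three statistics
#' fully determine the gradient-flow dynamics of a linear network on the task.
#'
#' @param task a [linear_task()].
#' @return An object of class `task_correlations` with elements `sigma_xx`,
#'   `sigma_yx`, `mean_sq_target`, `ni`, `no`, `p`.
#' @export
compute_correlations <- function(task) {
  stopifnot(inherits(task, "linear_task"))
  p <- task$p
  structure(
    list(
      sigma_xx = symmetrize(tcrossprod(task$X) / p),
      sigma_yx = tcrossprod(task$Y, task$X) / p,
      mean_sq_target = sum(task$Y^2) / p,
      ni = task$ni, no = task$no, p = p
    ),
    class = "task_correlations"
  )
}

#' @export
print.task_correlations <- function(x, ...) {
  cat(sprintf(
    "<task_correlations> Ni = %d, No = %d, P = %d; whitening deviation |Sxx - I|_F = %.3g\n",
    x$ni, x$no, x$p, fnorm(x$sigma_xx - diag(x$ni))
  ))
  invisible(x)
}

#' Compact singular value decomposition with orthogonal-complement projectors
#'
#' Thin SVD \eqn{M = U S V^T} retaining only singular values above
#' `rank_tol` times the largest, together with the projectors
#' \eqn{I - U U^T} and \eqn{I - V V^T} onto the orthogonal complements of the
#' retained singular subspaces. Only these projectors (never an explicit
#' basis completion) are needed by the closed-form dynamics, which makes the
#' representation unique even when the complement basis is not.
#'
#' @param M numeric matrix with at least one nonzero entry.
#' @param rank_tol relative tolerance for dropping singular values
#'   (default `1e-10` of the largest singular value).
#' @return An object of class `compact_svd` with elements `u` (left singular
#'   vectors), `d` (singular values, descending), `v` (right singular
#'   vectors), `rank`, `pu_perp`, `pv_perp`.
#' @examples
#' sv <- compact_svd(diag(c(3, 0)))
#' sv$rank # 1
#' @export
compact_svd <- function(M, rank_tol = 1e-10) {
  check_finite_matrix(M, "M")
  sv <- svd(M)
  if (length(sv$d) == 0L || sv$d[1] == 0) {
    stop("matrix is identically zero: rank-0 input has no compact SVD ",
         "(and violates the full-rank requirement downstream)", call. = FALSE)
  }
  keep <- sv$d > rank_tol * sv$d[1]
  nm <- sum(keep)
  u <- sv$u[, seq_len(nm), drop = FALSE]
  v <- sv$v[, seq_len(nm), drop = FALSE]
  structure(
    list(
      u = u, d = sv$d[seq_len(nm)], v = v, rank = nm,
      pu_perp = diag(nrow(M)) - tcrossprod(u),
      pv_perp = diag(ncol(M)) - tcrossprod(v)
    ),
    class = "compact_svd"
  )
}

#' @export
print.compact_svd <- function(x, ...) {
  cat(sprintf(
    "<compact_svd> rank %d; singular values: %s\n",
    x$rank, paste(signif(x$d, 4), collapse = ", ")
  ))
  invisible(x)
}

#' Compact SVD of a task's input-output correlation
#'
#' Convenience wrapper applying [compact_svd()] to \eqn{\Sigma^{yx}}.
#'
#' @param x a [linear_task()], [compute_correlations()] result, a
#'   `compact_svd` (returned unchanged), or a plain matrix taken to be
#'   \eqn{\Sigma^{yx}} itself.
#' @param rank_tol passed to [compact_svd()].
#' @return A `compact_svd` of \eqn{\Sigma^{yx}}.
#' @export
task_svd <- function(x, rank_tol = 1e-10) {
  if (inherits(x, "compact_svd")) return(x)
  if (inherits(x, "linear_task")) x <- compute_correlations(x)
  if (inherits(x, "task_correlations")) return(compact_svd(x$sigma_yx, rank_tol))
  if (is.matrix(x)) return(compact_svd(x, rank_tol))
  stop("cannot extract a task SVD from an object of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}
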