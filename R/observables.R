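#' Training loss of a network function on a whitened task
#'
#' For whitened inputs the mean-squared-error loss
#' \eqn{\frac{1}{2}\langle\|\hat y - y\|^2\rangle} of any end-to-end map
#' \eqn{W_{tot}} reduces exactly to the quadratic form
#' \deqn{L = \tfrac{1}{2}\|W_{tot} - \Sigma^{yx}\|_F^2 + c, \qquad
#'   c = \tfrac{1}{2}\left(\langle\|y\|^2\rangle - \|\Sigma^{yx}\|_F^2\right),}
#' where \eqn{c} is the irreducible loss at the global minimum
#' \eqn{W_{tot} = \Sigma^{yx}}.
#'
#' @param wtot network function (`no` x `ni` matrix).
#' @param corr [compute_correlations()] of a whitened task.
#' @param tol whitening tolerance; non-whitened correlations are an error
#'   (compute the loss sample-by-sample via the simulator instead).
#' @return Scalar loss.
#' @export
loss_from_function <- function(wtot, corr, tol = 1e-6) {
  stopifnot(inherits(corr, "task_correlations"))
  check_finite_matrix(wtot, "wtot")
  wdev <- fnorm(corr$sigma_xx - diag(corr$ni))
  if (wdev > tol) {
    stop(sprintf(
      "inputs are not whitened (|Sxx - I|_F = %.3g); this quadratic form only equals the sample loss for whitened data - use the sample-based loss in simulate_gd()",
      wdev
    ), call. = FALSE)
  }
  0.5 * sum((wtot - corr$sigma_yx)^2) +
    0.5 * (corr$mean_sq_target - sum(corr$sigma_yx^2))
}

#' Global-minimum (irreducible) loss of a task
#'
#' @param corr [compute_correlations()] of a whitened task.
#' @return The constant \eqn{c} of [loss_from_function()].
#' @export
minimum_loss <- function(corr) {
  stopifnot(inherits(corr, "task_correlations"))
  0.5 * (corr$mean_sq_target - sum(corr$sigma_yx^2))
}

#' Hidden-layer representational similarity matrix
#'
#' Kernel matrix \eqn{\phi(x_n)^T \phi(x_m)} of the hidden representations
#' \eqn{\phi(x) = W_1 x}, computed from the weight statistics in
#' \eqn{Q Q^T} without reconstructing the weights. Two equivalent routes
#' exist for zero-balanced states:
#' \describe{
#'   \item{`side = "input"`}{\eqn{K = X^T (W_1^T W_1) X} from the top-left
#'     block.}
#'   \item{`side = "output"`}{\eqn{K = X^T (W_2 W_1)^T (W_2 W_2^T)^+
#'     (W_2 W_1) X} from the bottom blocks, with \eqn{+} the Moore-Penrose
#'     pseudoinverse.}
#' }
#' Under zero-balancedness \eqn{W_1^T W_1 = (W_2 W_1)^T (W_2 W_2^T)^+
#' (W_2 W_1)} and both sides agree; comparing them is a useful internal
#' consistency check. At the converged fixed point with one-hot inputs
#' \eqn{X = \sqrt{P} I} the RSM equals \eqn{P \tilde V \tilde S \tilde
#' V^T}, the task's own similarity structure (the rich-regime signature).
#'
#' @param qq a [qq_block()].
#' @param X input matrix (columns are samples).
#' @param side `"input"` or `"output"` (which weights to read it from).
#' @return Symmetric PSD `P` x `P` matrix.
#' @export
hidden_rsm <- function(qq, X, side = c("input", "output")) {
  side <- match.arg(side)
  stopifnot(inherits(qq, "qq_block"))
  check_finite_matrix(X, "X")
  if (nrow(X) != qq$ni) stop("X rows must match the input dimension", call. = FALSE)
  k <- if (side == "input") {
    crossprod(X, input_gram(qq) %*% X)
  } else {
    wx <- network_function(qq) %*% X
    crossprod(wx, MASS::ginv(output_gram(qq)) %*% wx)
  }
  symmetrize(k)
}

#' Finite-width neural tangent kernel from QQ^T
#'
#' The NTK of the two-layer linear network,
#' \eqn{\Theta_{(n,a),(m,b)} = \sum_\theta \frac{\partial \hat y_{n,a}}
#' {\partial \theta} \frac{\partial \hat y_{m,b}}{\partial \theta}},
#' assembles exactly from the weight statistics:
#' \deqn{\Theta = (X^T X) \otimes (W_2 W_2^T) +
#'   (X^T W_1^T W_1 X) \otimes I,}
#' in sample-major ordering (the \eqn{(n, m)} block of size
#' \eqn{N_o \times N_o} couples samples \eqn{n} and \eqn{m}). A near-constant
#' NTK over training is the signature of the lazy regime.
#'
#' @param qq a [qq_block()].
#' @param X input matrix (columns are samples).
#' @return Symmetric PSD matrix of size `(P * no) x (P * no)`.
#' @seealso [ntk_jacobian()] for the brute-force parameter-space oracle.
#' @export
ntk <- function(qq, X) {
  stopifnot(inherits(qq, "qq_block"))
  check_finite_matrix(X, "X")
  if (nrow(X) != qq$ni) stop("X rows must match the input dimension", call. = FALSE)
  symmetrize(
    kronecker(crossprod(X), output_gram(qq)) +
      kronecker(crossprod(X, input_gram(qq) %*% X), diag(qq$no))
  )
}

#' Brute-force NTK by explicit Jacobian contraction
#'
#' Builds the full parameter Jacobian \eqn{\partial \hat y / \partial
#' (W_1, W_2)} entry by entry and contracts it, providing an independent
#' oracle for [ntk()] on small networks. Ordering matches [ntk()]
#' (sample-major).
#'
#' @param state a [network_state()].
#' @param X input matrix (columns are samples).
#' @return Symmetric PSD matrix of size `(P * no) x (P * no)`.
#' @export
ntk_jacobian <- function(state, X) {
  stopifnot(inherits(state, "network_state"))
  check_finite_matrix(X, "X")
  p <- ncol(X)
  no <- state$no
  nh <- state$nh
  ni <- state$ni
  n_par <- nh * ni + no * nh
  jac <- matrix(0, p * no, n_par)
  for (n in seq_len(p)) {
    x <- X[, n]
    for (a in seq_len(no)) {
      row <- (n - 1) * no + a
      # d yhat_a / d W1[i, j] = W2[a, i] * x[j]; vec(W1) column-major
      jac[row, seq_len(nh * ni)] <- as.vector(outer(state$W2[a, ], x))
      # d yhat_a / d W2[a, i] = (W1 x)[i]
      h <- state$W1 %*% x
      idx <- nh * ni + a + no * (seq_len(nh) - 1)
      jac[row, idx] <- h
    }
  }
  symmetrize(tcrossprod(jac))
}

#' Catastrophic-forgetting loss after convergence on another task
#'
#' After training to convergence on task \eqn{j} (from any zero-balanced
#' initialisation), the network function equals \eqn{\Sigma^{yx}_j}, so the
#' loss it incurs on task \eqn{i} is exactly
#' \deqn{L_i(T_j) = \tfrac{1}{2}\|\Sigma^{yx}_j - \Sigma^{yx}_i\|_F^2 + c_i,}
#' where \eqn{c_i} depends only on task \eqn{i}'s data. Forgetting is thus
#' fully determined by task similarity and can be tabulated before training
#' even starts.
#'
#' @param sigma_j input-output correlation of the trained task (matrix, or
#'   anything [task_svd()]-compatible holding one is *not* accepted here:
#'   pass the matrix or a `task_correlations`).
#' @param corr_i [compute_correlations()] of the evaluated task.
#' @return Scalar loss of task `i` at task `j`'s optimum.
#' @export
forgetting_loss <- function(sigma_j, corr_i) {
  if (inherits(sigma_j, "task_correlations")) sigma_j <- sigma_j$sigma_yx
  stopifnot(inherits(corr_i, "task_correlations"))
  check_finite_matrix(sigma_j, "sigma_j")
  if (!all(dim(sigma_j) == dim(corr_i$sigma_yx))) {
    stop("task dimensions differ", call. = FALSE)
  }
  0.5 * sum((sigma_j - corr_i$sigma_yx)^2) + minimum_loss(corr_i)
}

#' Analytic forgetting table for a task sequence
#'
#' Entry `[j, i]` is [forgetting_loss()] of task `i` evaluated at task `j`'s
#' optimum: rows index the task just trained, columns the task evaluated.
#'
#' @param corrs list of [compute_correlations()] results, matching dims.
#' @return `T` x `T` numeric matrix with dimnames `trained`/`evaluated`.
#' @export
forgetting_matrix <- function(corrs) {
  stopifnot(length(corrs) >= 1, all(vapply(corrs, inherits, TRUE, "task_correlations")))
  n <- length(corrs)
  out <- matrix(NA_real_, n, n,
                dimnames = list(trained = paste0("T", seq_len(n)),
                                evaluated = paste0("T", seq_len(n))))
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      out[j, i] <- forgetting_loss(corrs[[j]]$sigma_yx, corrs[[i]])
    }
  }
  out
}
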