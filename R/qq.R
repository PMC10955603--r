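#' Weight-statistics block matrix QQ^T
#'
#' The dynamics are tracked through the symmetric positive semidefinite
#' \eqn{(N_i + N_o) \times (N_i + N_o)} matrix \eqn{Q Q^T}, where
#' \eqn{Q = [W_1^T; W_2]} stacks the weights. Its quadrants have direct
#' meaning: the top-left \eqn{N_i \times N_i} block is \eqn{W_1^T W_1}
#' (input-weight correlation), the bottom-right \eqn{N_o \times N_o} block
#' is \eqn{W_2 W_2^T} (output-weight correlation), and the bottom-left
#' \eqn{N_o \times N_i} block is the network function \eqn{W_2 W_1}.
#'
#' @param m symmetric PSD matrix of size `(ni + no) x (ni + no)`.
#' @param ni,no input and output dimensions fixing the block layout.
#' @return An object of class `qq_block`.
#' @seealso [qq_from_state()], [network_function()], [input_gram()],
#'   [output_gram()]
#' @export
qq_block <- function(m, ni, no) {
  check_finite_matrix(m, "m")
  if (nrow(m) != ni + no || ncol(m) != ni + no) {
    stop("m must be (ni + no) x (ni + no)", call. = FALSE)
  }
  asym <- max(abs(m - t(m)))
  if (asym > 1e-8 * max(1, max(abs(m)))) {
    stop(sprintf("m is not symmetric (max asymmetry %.3g)", asym), call. = FALSE)
  }
  m <- symmetrize(m)
  structure(list(m = m, ni = ni, no = no), class = "qq_block")
}

#' Form QQ^T from a network state
#'
#' @param state a [network_state()].
#' @return A [qq_block()].
#' @export
qq_from_state <- function(state) {
  stopifnot(inherits(state, "network_state"))
  q <- rbind(t(state$W1), state$W2)
  qq_block(tcrossprod(q), state$ni, state$no)
}

#' @rdname qq_block
#' @param qq a `qq_block`.
#' @export
input_gram <- function(qq) {
  stopifnot(inherits(qq, "qq_block"))
  qq$m[seq_len(qq$ni), seq_len(qq$ni), drop = FALSE]
}

#' @rdname qq_block
#' @export
output_gram <- function(qq) {
  stopifnot(inherits(qq, "qq_block"))
  idx <- qq$ni + seq_len(qq$no)
  qq$m[idx, idx, drop = FALSE]
}

#' Network function stored in QQ^T
#'
#' Extracts the bottom-left \eqn{N_o \times N_i} block, i.e. the end-to-end
#' map \eqn{W_2 W_1}.
#'
#' @param qq a [qq_block()].
#' @return `no` x `ni` matrix.
#' @export
network_function <- function(qq) {
  stopifnot(inherits(qq, "qq_block"))
  qq$m[qq$ni + seq_len(qq$no), seq_len(qq$ni), drop = FALSE]
}

#' @export
print.qq_block <- function(x, ...) {
  cat(sprintf(
    "<qq_block> Ni = %d, No = %d; |W2 W1|_F = %.4g; |W1' W1|_F = %.4g; |W2 W2'|_F = %.4g\n",
    x$ni, x$no, fnorm(network_function(x)), fnorm(input_gram(x)), fnorm(output_gram(x))
  ))
  invisible(x)
}

#' Global-minimum fixed point of the gradient flow
#'
#' Under the whitened, zero-balanced, full-rank assumptions the flow
#' converges to the rich task-specific solution: network function
#' \eqn{\tilde U \tilde S \tilde V^T}, input-weight correlation
#' \eqn{W_1^T W_1 = \tilde V \tilde S \tilde V^T} and output-weight
#' correlation \eqn{W_2 W_2^T = \tilde U \tilde S \tilde U^T}.
#'
#' @param tsvd task SVD (anything accepted by [task_svd()]).
#' @return A [qq_block()] holding the converged statistics.
#' @export
fixed_point <- function(tsvd) {
  tsvd <- task_svd(tsvd)
  ni <- nrow(tsvd$v)
  no <- nrow(tsvd$u)
  sv <- tsvd$d * t(tsvd$v) # diag(S) V^T
  su <- tsvd$d * t(tsvd$u)
  m <- rbind(
    cbind(tsvd$v %*% sv, t(tsvd$u %*% sv)),
    cbind(tsvd$u %*% sv, tsvd$u %*% su)
  )
  qq_block(symmetrize(m), ni, no)
}

#' Recover a zero-balanced state from QQ^T
#'
#' Any \eqn{Q Q^T} arising from a zero-balanced state determines the weights
#' up to an orthogonal transformation of the hidden layer: if the function
#' block has compact SVD \eqn{U S V^T}, then zero-balancedness forces
#' \eqn{W_1^T W_1 = V S V^T} and \eqn{W_2 W_2^T = U S U^T}, and
#' \eqn{W_1 = O S^{1/2} V^T}, \eqn{W_2 = U S^{1/2} O^T} reproduces all
#' blocks for any orthonormal gauge \eqn{O} (seed-controlled here). Used to
#' chain analytic continual-learning legs.
#'
#' @param qq a [qq_block()] from a zero-balanced state (the diagonal blocks
#'   must be consistent with the function block; checked to `tol`).
#' @param nh hidden width of the recovered state, at least the function
#'   rank.
#' @param seed seed controlling the orthogonal gauge.
#' @param tol absolute reconstruction tolerance (default `1e-8`).
#' @return A [network_state()] whose `qq_from_state()` reproduces `qq`.
#' @export
factor_qqt <- function(qq, nh, seed = NULL, tol = 1e-8) {
  stopifnot(inherits(qq, "qq_block"))
  ev_min <- min(eigen(qq$m, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8 * max(1, fnorm(qq$m))) {
    stop(sprintf("qq is not positive semidefinite (min eigenvalue %.3g)", ev_min),
         call. = FALSE)
  }
  f <- network_function(qq)
  if (all(abs(f) < tol)) {
    # zero function with balancedness implies zero weights
    return(network_state(matrix(0, nh, qq$ni), matrix(0, qq$no, nh)))
  }
  sv <- compact_svd(f)
  if (nh < sv$rank) {
    stop(sprintf("nh = %d below the function rank %d", nh, sv$rank), call. = FALSE)
  }
  state <- with_seed(seed, balanced_state_from_svd(sv$u, sv$d, sv$v, nh))
  err <- fnorm(qq_from_state(state)$m - qq$m)
  if (err > tol * max(1, fnorm(qq$m))) {
    stop(sprintf(
      "qq does not factor as a zero-balanced state (reconstruction error %.3g); its diagonal blocks are inconsistent with the function block",
      err
    ), call. = FALSE)
  }
  state
}
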