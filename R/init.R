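#' Two-layer network state
#'
#' Holds the weight matrices \eqn{W_1} (\eqn{N_h \times N_i}) and \eqn{W_2}
#' (\eqn{N_o \times N_h}) of the linear network \eqn{\hat y = W_2 W_1 x}.
#'
#' @param W1 hidden-from-input weights, `nh` rows.
#' @param W2 output-from-hidden weights, `nh` columns.
#' @return An object of class `network_state` with elements `W1`, `W2`,
#'   `ni`, `nh`, `no`.
#' @export
network_state <- function(W1, W2) {
  check_finite_matrix(W1, "W1")
  check_finite_matrix(W2, "W2")
  if (ncol(W2) != nrow(W1)) {
    stop("hidden dimensions disagree: ncol(W2) must equal nrow(W1)", call. = FALSE)
  }
  structure(
    list(W1 = W1, W2 = W2, ni = ncol(W1), nh = nrow(W1), no = nrow(W2)),
    class = "network_state"
  )
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf(
    "<network_state> Ni = %d -> Nh = %d -> No = %d; balancedness gap %.3g; |W2 W1|_F = %.3g\n",
    x$ni, x$nh, x$no, balancedness_gap(x), fnorm(x$W2 %*% x$W1)
  ))
  invisible(x)
}

#' Balancedness defect of a network state
#'
#' Zero-balanced weights satisfy \eqn{W_1 W_1^T = W_2^T W_2}, a conserved
#' quantity of the gradient flow that the closed-form solutions require at
#' initialisation. This returns the Frobenius norm of the defect
#' \eqn{\|W_1 W_1^T - W_2^T W_2\|_F}.
#'
#' @param state a [network_state()].
#' @return Non-negative scalar; 0 means exactly balanced.
#' @export
balancedness_gap <- function(state) {
  stopifnot(inherits(state, "network_state"))
  fnorm(tcrossprod(state$W1) - crossprod(state$W2))
}

# Shared balanced factorisation: given a function-space target U diag(s) V^T,
# split the singular values symmetrically (sqrt in each layer) and insert a
# random orthonormal hidden gauge O. Any asymmetric split would break
# zero-balancedness.
balanced_state_from_svd <- function(u, s, v, nh) {
  k <- length(s)
  o <- rand_orthonormal(nh, k)
  s_half <- sqrt(s)
  network_state(
    W1 = o %*% (s_half * t(v)),
    W2 = u %*% (s_half * t(o))
  )
}

#' Random task-agnostic zero-balanced initialisation
#'
#' Draws a random \eqn{N_o \times N_i} matrix with independent centred
#' Gaussian entries of standard deviation `scale`, takes its compact SVD
#' \eqn{U S V^T}, and factors it into exactly zero-balanced weights
#' \eqn{W_1 = O S^{1/2} V^T}, \eqn{W_2 = U S^{1/2} O^T} with a random
#' orthonormal hidden gauge \eqn{O}. The resulting network function
#' \eqn{W_2 W_1} is full rank with probability 1, and the construction never
#' looks at any task: "large" versus "small" prior knowledge is expressed
#' solely through `scale`.
#'
#' @param ni,no,nh network dimensions; `nh` must be at least `min(ni, no)`
#'   so the network is not bottlenecked.
#' @param scale standard deviation of the entries of the random function.
#' @param seed integer seed for reproducibility.
#' @return A [network_state()] with balancedness gap at float level.
#' @export
random_balanced_init <- function(ni, no, nh, scale = 1, seed = NULL) {
  stopifnot(ni >= 1, no >= 1, nh >= 1, scale > 0)
  if (nh < min(ni, no)) {
    stop("nh < min(ni, no) bottlenecks the network and breaks the full-rank ",
         "requirement of the exact solutions", call. = FALSE)
  }
  with_seed(seed, {
    m <- matrix(stats::rnorm(no * ni, sd = scale), no, ni)
    sv <- compact_svd(m)
    balanced_state_from_svd(sv$u, sv$d, sv$v, nh)
  })
}

#' Zero-balanced state realising a prescribed network function
#'
#' Factors a given matrix `M` into zero-balanced weights with
#' \eqn{W_2 W_1 = M}, using the same symmetric square-root construction as
#' [random_balanced_init()]. Used to start a solver from a prescribed
#' function, e.g. the converged solution of a previous task in a continual
#' learning sequence, or an exactly sign-reversed task.
#'
#' @param M target network function (`no` x `ni`).
#' @param nh hidden width, at least `rank(M)`.
#' @param seed seed for the random hidden gauge.
#' @param rank_tol relative rank tolerance passed to [compact_svd()].
#' @return A [network_state()] with `W2 %*% W1` equal to `M` up to float
#'   rounding.
#' @export
balanced_init_from_product <- function(M, nh, seed = NULL, rank_tol = 1e-10) {
  sv <- compact_svd(M, rank_tol)
  if (nh < sv$rank) {
    stop(sprintf("nh = %d is smaller than rank(M) = %d", nh, sv$rank),
         call. = FALSE)
  }
  with_seed(seed, balanced_state_from_svd(sv$u, sv$d, sv$v, nh))
}

#' Task-aligned initialisation
#'
#' Builds the initialisation \eqn{W_1 = A_0 \tilde V^T},
#' \eqn{W_2 = \tilde U A_0^T} whose singular vectors share the task's
#' pairing, so that the whole trajectory stays expressible in the task's
#' singular basis (see [aligned_dynamics()]). Requires the square full-rank
#' setting \eqn{N_m = N_i = N_o}. The state is zero-balanced for any
#' \eqn{A_0} since \eqn{W_1 W_1^T = A_0 A_0^T = W_2^T W_2}.
#'
#' @param A0 arbitrary `nh` x `ni` matrix with full column rank.
#' @param tsvd task SVD (anything accepted by [task_svd()]).
#' @return A [network_state()].
#' @export
aligned_init <- function(A0, tsvd) {
  tsvd <- task_svd(tsvd)
  check_finite_matrix(A0, "A0")
  ni <- nrow(tsvd$v)
  no <- nrow(tsvd$u)
  if (tsvd$rank < ni || ni != no) {
    stop("aligned initialisation requires the square full-rank setting ",
         "(task rank = Ni = No)", call. = FALSE)
  }
  if (ncol(A0) != ni) stop("A0 must have Ni columns", call. = FALSE)
  network_state(W1 = A0 %*% t(tsvd$v), W2 = tsvd$u %*% t(A0))
}

#' Random balanced initialisation compatible with a task's alignment assumption
#'
#' [random_balanced_init()] is task-agnostic, but the general closed form
#' additionally needs the alignment matrix \eqn{B} (see [build_bc()]) to be
#' well conditioned. On square tasks this fails *exactly* (not merely
#' numerically) for half of all random draws: whenever
#' \eqn{\det(W_2 W_1(0))} and \eqn{\det(\Sigma^{yx})} have opposite signs,
#' an eigenvalue-parity argument forces \eqn{B} to be singular — the
#' orientation-mismatched init lies on a separatrix in at least one mode,
#' of which full reversal learning is the extreme case. This sampler
#' redraws (deterministically from `seed`) until
#' \eqn{\min \mathrm{sv}(B) > } `min_sv_b`, i.e. it samples random balanced
#' initialisations conditioned on the solver's assumptions.
#'
#' @param task anything accepted by [task_svd()].
#' @param nh hidden width.
#' @param scale initialisation scale, as in [random_balanced_init()].
#' @param seed integer seed; redraws use deterministic offsets of it.
#' @param min_sv_b acceptance threshold on the smallest singular value of
#'   `B` (default 0.1, well clear of both exact singularity and numerical
#'   ill-conditioning).
#' @param max_tries redraw budget before giving up.
#' @return A [network_state()] whose [build_bc()] against `task` passes.
#' @export
compatible_balanced_init <- function(task, nh, scale = 1, seed = NULL,
                                     min_sv_b = 0.1, max_tries = 50L) {
  tsvd <- task_svd(task)
  ni <- nrow(tsvd$v)
  no <- nrow(tsvd$u)
  for (k in seq_len(max_tries)) {
    s <- if (is.null(seed)) NULL else as.integer((seed + (k - 1) * 7919) %% 2147483647)
    init <- random_balanced_init(ni, no, nh, scale, s)
    bc <- build_bc(compact_svd(init$W2 %*% init$W1), tsvd)
    if (bc$min_sv_B > min_sv_b) return(init)
  }
  stop(sprintf(
    "no balanced init with min sv(B) > %g found in %d draws", min_sv_b, max_tries
  ), call. = FALSE)
}

#' Alignment matrices between an initial function and a task
#'
#' From the compact SVDs \eqn{U S V^T} of the initial network function and
#' \eqn{\tilde U \tilde S \tilde V^T} of the task correlation, forms
#' \eqn{B = U^T \tilde U + V^T \tilde V} and
#' \eqn{C = U^T \tilde U - V^T \tilde V}. The general closed-form solution
#' requires \eqn{B} to be non-singular; \eqn{B} becomes exactly singular for
#' sign-reversed (reversal-learning) initialisations, which lie on the
#' separatrix of a saddle.
#'
#' @param init_svd compact SVD of the initial network function
#'   (a `compact_svd`, e.g. `compact_svd(W2 %*% W1)`).
#' @param tsvd task SVD (anything accepted by [task_svd()]).
#' @return An object of class `alignment` with elements `B`, `C`,
#'   `min_sv_B`, and logical `b_singular` (`TRUE` when `min_sv_B <= 1e-10`,
#'   the double-precision threshold below which inverting `B` is
#'   meaningless).
#' @export
build_bc <- function(init_svd, tsvd) {
  stopifnot(inherits(init_svd, "compact_svd"))
  tsvd <- task_svd(tsvd)
  if (init_svd$rank != tsvd$rank) {
    stop(sprintf(
      "retained ranks differ (init %d, task %d); the alignment matrices are only defined at equal rank",
      init_svd$rank, tsvd$rank
    ), call. = FALSE)
  }
  uu <- crossprod(init_svd$u, tsvd$u)
  vv <- crossprod(init_svd$v, tsvd$v)
  b <- uu + vv
  min_sv <- min(svd(b)$d)
  structure(
    list(B = b, C = uu - vv, min_sv_B = min_sv, b_singular = min_sv <= 1e-10),
    class = "alignment"
  )
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf(
    "<alignment> rank %d; min singular value of B = %.3g%s\n",
    nrow(x$B), x$min_sv_B,
    if (x$b_singular) " (SINGULAR: general closed form not applicable)" else ""
  ))
  invisible(x)
}
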