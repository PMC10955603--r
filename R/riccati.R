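#' Stable general closed-form dynamics of QQ^T
#'
#' Evaluates the exact solution of the gradient flow for \eqn{Q Q^T(t)} from
#' a zero-balanced initialisation on a whitened full-rank task, valid for
#' equal and unequal input/output dimensions. Writing \eqn{U S V^T} for the
#' compact SVD of the initial function, \eqn{\tilde U \tilde S \tilde V^T}
#' for the task correlation, \eqn{B = U^T\tilde U + V^T\tilde V},
#' \eqn{C = U^T\tilde U - V^T\tilde V} and
#' \eqn{E(t) = e^{-\tilde S t/\tau}} (elementwise on the diagonal), the
#' solution takes the form \eqn{Z(t) [\,\cdot\,]^{-1} Z(t)^T} where the
#' bracket collects four terms:
#' \eqn{4 E B^{-1} S^{-1} B^{-T} E},
#' \eqn{(I - E^2)\tilde S^{-1}},
#' \eqn{E B^{-1} C (I - E^2) \tilde S^{-1} C^T B^{-T} E}, and a
#' linear-in-\eqn{t} term
#' \eqn{4 (t/\tau) E B^{-1}(V^T P_{\tilde V}^\perp V + U^T P_{\tilde U}^\perp U) B^{-T} E}
#' built from the projectors \eqn{P^\perp = I - \tilde V \tilde V^T} (resp.
#' \eqn{\tilde U}) onto the task's orthogonal complements, which vanishes
#' identically in the square full-rank case. Because every time dependence
#' enters through decaying exponentials, the expression is numerically
#' stable at arbitrarily large \eqn{t}, unlike the reference
#' matrix-exponential form [riccati_fukumizu()].
#'
#' When the alignment matrix \eqn{B} is singular (exactly sign-reversed
#' initialisations: reversal learning), the initial state lies on the
#' separatrix of a saddle and no inverse exists. Passing `b_fallback_eps`
#' enables a diagnostic fallback that perturbs the initial function by
#' \eqn{\varepsilon} times a random balanced state (normalised to unit
#' function norm) and solves from there; the \eqn{\varepsilon \to 0} limit
#' exhibits the saddle (the function transits through zero norm). The
#' perturbation is never applied silently: without `b_fallback_eps` a
#' singular \eqn{B} is an error.
#'
#' @param init a [network_state()] (zero-balanced; validated internally).
#' @param task the task: a [linear_task()], [compute_correlations()] result,
#'   `compact_svd`, or the \eqn{\Sigma^{yx}} matrix.
#' @param times increasing vector of evaluation times.
#' @param tau time constant of the flow (\eqn{1/\eta}).
#' @param b_fallback_eps optional perturbation size for singular `B`
#'   (e.g. `1e-6`); reported in the result as attribute `b_fallback_eps`.
#' @param seed seed for the fallback perturbation.
#' @param rank_tol relative rank tolerance for the compact SVDs.
#' @param cond_max condition-number ceiling for the bracket solve; beyond it
#'   the evaluation refuses rather than return garbage.
#' @return A `trajectory` with one [qq_block()] per time.
#' @references The solution and its assumptions are checked numerically
#'   against full-batch gradient descent by [simulate_gd()].
#' @export
exact_qqt <- function(init, task, times, tau = 1, b_fallback_eps = NULL,
                      seed = NULL, rank_tol = 1e-10, cond_max = 1e12) {
  stopifnot(inherits(init, "network_state"), all(is.finite(times)), tau > 0)
  tsvd <- task_svd(task, rank_tol)
  eps_used <- NULL

  isvd <- compact_svd(init$W2 %*% init$W1, rank_tol)
  if (isvd$rank != tsvd$rank) {
    stop(sprintf(
      "initial function rank (%d) and task rank (%d) differ; the solution requires both full rank",
      isvd$rank, tsvd$rank
    ), call. = FALSE)
  }
  bc <- build_bc(isvd, tsvd)
  if (bc$b_singular) {
    if (is.null(b_fallback_eps)) {
      stop(sprintf(
        paste0(
          "alignment matrix B is singular (min singular value %.3g): the ",
          "initialisation lies on the separatrix of a saddle (reversal ",
          "learning). Supply b_fallback_eps for a perturbative diagnostic, ",
          "or use simulate_gd()."
        ), bc$min_sv_B
      ), call. = FALSE)
    }
    # the perturbation direction is arbitrary: retry a few draws in case one
    # happens to land too close to the singular set
    for (try in 0:4) {
      s_try <- if (is.null(seed)) NULL else seed + try
      pert <- with_seed(s_try,
                        random_balanced_init(init$ni, init$no, init$nh, scale = 1))
      pf <- pert$W2 %*% pert$W1
      m <- init$W2 %*% init$W1 + b_fallback_eps * pf / fnorm(pf)
      isvd <- compact_svd(m, rank_tol)
      if (isvd$rank != tsvd$rank) next
      bc <- build_bc(isvd, tsvd)
      if (!bc$b_singular) break
    }
    if (isvd$rank != tsvd$rank || bc$b_singular) {
      stop("B still singular after perturbation; increase b_fallback_eps",
           call. = FALSE)
    }
    eps_used <- b_fallback_eps
  }

  nm <- tsvd$rank
  ni <- nrow(tsvd$v)
  no <- nrow(tsvd$u)
  binv <- solve(bc$B)
  btinv <- t(binv)
  # B^{-1} S^{-1} B^{-T} (init singular values) and B^{-1} C
  k1 <- binv %*% ((1 / isvd$d) * btinv)
  k3 <- binv %*% bc$C
  pv_v <- tsvd$pv_perp %*% isvd$v # P_perp V (idempotent P => V' P V = (PV)'(PV))
  pu_u <- tsvd$pu_perp %*% isvd$u
  gproj <- crossprod(pv_v) + crossprod(pu_u)
  k4 <- binv %*% gproj %*% btinv
  ident <- diag(nm)

  qq_blocks <- lapply(times, function(t) {
    e <- exp(-tsvd$d * t / tau)
    ee <- tcrossprod(e)
    w <- (1 - e^2) / tsvd$d # (I - E^2) Stilde^{-1}, diagonal
    br <- 4 * ee * k1 +
      diag(w, nm) +
      ee * (k3 %*% (w * t(k3))) +
      4 * (t / tau) * ee * k4
    br <- symmetrize(br)
    rc <- rcond(br)
    if (!is.finite(rc) || rc < 1 / cond_max) {
      stop(sprintf(
        "bracket condition number %.3g exceeds %g at t = %.4g; solution not numerically trustworthy",
        1 / rc, cond_max, t
      ), call. = FALSE)
    }
    ecb <- ee * (t(bc$C) %*% btinv) # E C^T B^{-T} E
    z <- rbind(
      tsvd$v %*% (ident - ecb) + 2 * colscale(pv_v %*% btinv, e),
      tsvd$u %*% (ident + ecb) + 2 * colscale(pu_u %*% btinv, e)
    )
    qq_block(symmetrize(z %*% solve(br, t(z))), ni, no)
  })

  new_trajectory(times, qq_blocks, tau, "analytic",
                 extra = list(task_svd = tsvd, init_svd = isvd,
                              alignment = bc, b_fallback_eps = eps_used))
}

#' Reference matrix-exponential solution of the Riccati dynamics
#'
#' Literal evaluation of the original closed form
#' \deqn{Q Q^T(t) = e^{F t/\tau} Q_0 \left[I + \tfrac{1}{2} Q_0^T
#'   \left(e^{F t/\tau} F^{-1} e^{F t/\tau} - F^{-1}\right) Q_0\right]^{-1}
#'   Q_0^T e^{F t/\tau}}
#' with \eqn{F = [[0, \Sigma^{yx\,T}], [\Sigma^{yx}, 0]]}, valid only for a
#' square non-singular \eqn{\Sigma^{yx}} (equal input/output dimensions) and
#' kept as an independent cross-validation route: the positive exponentials
#' make it numerically unstable at large \eqn{t}, which is why [exact_qqt()]
#' is the production solver.
#'
#' @param init a [network_state()].
#' @param sigma_yx square non-singular input-output correlation matrix (or
#'   anything [compute_correlations()]-like holding one).
#' @param times increasing vector of evaluation times.
#' @param tau time constant.
#' @param cond_max condition-number ceiling for the inner bracket.
#' @return A `trajectory`.
#' @export
riccati_fukumizu <- function(init, sigma_yx, times, tau = 1, cond_max = 1e12) {
  stopifnot(inherits(init, "network_state"))
  if (inherits(sigma_yx, "task_correlations")) sigma_yx <- sigma_yx$sigma_yx
  if (inherits(sigma_yx, "linear_task")) {
    sigma_yx <- compute_correlations(sigma_yx)$sigma_yx
  }
  check_finite_matrix(sigma_yx, "sigma_yx")
  if (!is_square_matrix(sigma_yx)) {
    stop("sigma_yx must be square (equal input/output dimensions assumption)",
         call. = FALSE)
  }
  d <- svd(sigma_yx)$d
  if (min(d) <= 1e-12 * max(d)) {
    stop("sigma_yx is singular, so F is not invertible (full-rank assumption violated)",
         call. = FALSE)
  }
  n <- nrow(sigma_yx)
  f <- rbind(
    cbind(matrix(0, n, n), t(sigma_yx)),
    cbind(sigma_yx, matrix(0, n, n))
  )
  finv <- solve(f)
  q0 <- rbind(t(init$W1), init$W2)
  nh <- ncol(q0)

  qq_blocks <- lapply(times, function(t) {
    ef <- as.matrix(Matrix::expm(f * (t / tau)))
    inner <- diag(nh) + 0.5 * crossprod(q0, (ef %*% finv %*% ef - finv) %*% q0)
    rc <- rcond(inner)
    if (!is.finite(rc) || rc < 1 / cond_max) {
      stop(sprintf(
        "inner bracket condition number %.3g exceeds %g at t = %.4g (this form is unstable at large t; use exact_qqt)",
        1 / rc, cond_max, t
      ), call. = FALSE)
    }
    efq <- ef %*% q0
    qq_block(symmetrize(efq %*% solve(inner, t(efq))), n, n)
  })
  new_trajectory(times, qq_blocks, tau, "analytic")
}

#' Aligned-initialisation dynamics in the task's singular basis
#'
#' For initialisations of the form \eqn{W_1 = A_0 \tilde V^T},
#' \eqn{W_2 = \tilde U A_0^T} (see [aligned_init()]) the whole trajectory is
#' carried by the single matrix
#' \deqn{A^T A(t) = \left[E (A_0^T A_0)^{-1} E +
#'   (I - E^2) \tilde S^{-1}\right]^{-1}, \qquad E = e^{-\tilde S t/\tau}.}
#' Diagonal entries are the per-mode connection strengths (which must reach
#' the task singular values), off-diagonal entries the counterproductive
#' cross-mode coupling (which must decay to zero); their dynamics expose the
#' decoupling/alignment process directly.
#'
#' @param ata0 symmetric positive-definite matrix \eqn{A_0^T A_0}.
#' @param stilde task singular values (vector, one per mode).
#' @param times increasing vector of evaluation times.
#' @param tau time constant.
#' @return List of \eqn{A^T A(t)} matrices, one per time.
#' @seealso [aligned_trajectory()] to lift the result to a full `trajectory`.
#' @export
aligned_dynamics <- function(ata0, stilde, times, tau = 1) {
  check_finite_matrix(ata0, "ata0")
  stopifnot(is_square_matrix(ata0), length(stilde) == nrow(ata0), all(stilde > 0))
  if (max(abs(ata0 - t(ata0))) > 1e-10 * max(1, max(abs(ata0)))) {
    stop("ata0 must be symmetric (it is a Gram matrix A0' A0)", call. = FALSE)
  }
  ev <- eigen(symmetrize(ata0), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(abs(ev))) {
    stop("ata0 is singular; the aligned closed form requires an invertible A0' A0",
         call. = FALSE)
  }
  ainv <- solve(symmetrize(ata0))
  nm <- nrow(ata0)
  lapply(times, function(t) {
    e <- exp(-stilde * t / tau)
    br <- tcrossprod(e) * ainv + diag((1 - e^2) / stilde, nm)
    symmetrize(solve(symmetrize(br)))
  })
}

#' Lift aligned dynamics to a full QQ^T trajectory
#'
#' Reconstructs \eqn{Q Q^T(t)} from the aligned solution:
#' \eqn{W_1^T W_1 = \tilde V A^T A \tilde V^T},
#' \eqn{W_2 W_2^T = \tilde U A^T A \tilde U^T}, network function
#' \eqn{\tilde U A^T A \tilde V^T}.
#'
#' @inheritParams aligned_dynamics
#' @param tsvd task SVD (anything accepted by [task_svd()]); must be the
#'   square full-rank case.
#' @return A `trajectory`.
#' @export
aligned_trajectory <- function(ata0, tsvd, times, tau = 1) {
  tsvd <- task_svd(tsvd)
  ni <- nrow(tsvd$v)
  no <- nrow(tsvd$u)
  ata <- aligned_dynamics(ata0, tsvd$d, times, tau)
  qq_blocks <- lapply(ata, function(a) {
    av <- a %*% t(tsvd$v)
    au <- a %*% t(tsvd$u)
    m <- rbind(
      cbind(tsvd$v %*% av, t(tsvd$u %*% av)),
      cbind(tsvd$u %*% av, tsvd$u %*% au)
    )
    qq_block(symmetrize(m), ni, no)
  })
  new_trajectory(times, qq_blocks, tau, "analytic",
                 extra = list(task_svd = tsvd, ata = ata))
}

#' Peak time of the 2x2 cross-coupling
#'
#' In the two-mode aligned setting with equal task singular values
#' \eqn{s_1 = s_2 = s}, the off-diagonal element \eqn{b(t)} of
#' \eqn{A^T A(t)} can rise to a transient interior peak before decaying to
#' zero; its time is
#' \deqn{t_{peak} = \frac{\tau}{4 s}
#'   \ln\frac{s (s - a_1 - a_2)}{a_1 a_2 - b(0)^2}.}
#' A genuine interior peak exists only when the logarithm's argument exceeds
#' 1; otherwise (large initialisations, or `b0 = 0` which stays identically
#' zero) the function returns `NA`.
#'
#' @param a1,a2 aligned diagonal components at \eqn{t = 0}.
#' @param b0 cross-coupling at \eqn{t = 0}; must satisfy
#'   \eqn{a_1 a_2 - b_0^2 > 0} (Gram positive-definiteness).
#' @param s1,s2 task singular values; the formula's regime is
#'   \eqn{s_1 = s_2} and unequal values are an error.
#' @param tau time constant.
#' @return The peak time, or `NA` when the off-diagonal is monotone.
#' @export
two_by_two_offdiag_peak <- function(a1, a2, b0, s1, s2 = s1, tau = 1) {
  stopifnot(is.finite(a1), is.finite(a2), is.finite(b0), s1 > 0, s2 > 0, tau > 0)
  if (abs(s1 - s2) > 1e-12 * max(s1, s2)) {
    stop("the peak-time formula holds for equal task singular values (s1 = s2)",
         call. = FALSE)
  }
  det0 <- a1 * a2 - b0^2
  if (det0 <= 0) {
    stop("a1 * a2 - b0^2 must be positive (A0' A0 is a Gram matrix)", call. = FALSE)
  }
  if (b0 == 0) return(NA_real_) # decoupled init stays decoupled
  s <- s1
  arg <- s * (s - a1 - a2) / det0
  if (!is.finite(arg) || arg <= 1) return(NA_real_) # monotone off-diagonal
  tau / (4 * s) * log(arg)
}

#' Sigmoidal single-mode trajectory (small aligned initialisation)
#'
#' In the small-initialisation limit of the two-mode setting with equal task
#' singular values \eqn{s}, the aligned diagonal follows the sigmoid
#' \deqn{a_1(t) = \frac{s\, a_1(0)}{e^{-2 s t/\tau}[s - a_1(0) - a_2(0)]
#'   + a_1(0) + a_2(0)}.}
#' The formula is evaluated as printed for any arguments; it is accurate in
#' the regime \eqn{|a_1(0)|, |a_2(0)| \ll s}.
#'
#' @param a1_0,a2_0 aligned diagonal components at \eqn{t = 0}.
#' @param s task singular value.
#' @param times evaluation times.
#' @param tau time constant.
#' @return Numeric vector \eqn{a_1(t)}; exact zeros of the denominator are
#'   guarded and yield 0.
#' @export
sigmoid_mode <- function(a1_0, a2_0, s, times, tau = 1) {
  stopifnot(s > 0, tau > 0)
  den <- exp(-2 * s * times / tau) * (s - a1_0 - a2_0) + a1_0 + a2_0
  out <- s * a1_0 / den
  out[den == 0] <- 0
  out
}

#' Closed-form shallow (single-layer) dynamics
#'
#' A single linear layer trained on a whitened task follows the linear ODE
#' \eqn{\tau\, dW/dt = \Sigma^{yx} - W}, whose solution
#' \deqn{W(t) = \Sigma^{yx} + (W_0 - \Sigma^{yx})\, e^{-t/\tau}}
#' is a plain exponential with no saddle: shallow networks relearn
#' sign-reversed tasks without the catastrophic slowing that deep linear
#' networks exhibit.
#'
#' @param W0 initial weight matrix.
#' @param sigma_yx task input-output correlation (matching dimensions).
#' @param times evaluation times.
#' @param tau time constant.
#' @return List of weight matrices \eqn{W(t)}, one per time.
#' @export
shallow_dynamics <- function(W0, sigma_yx, times, tau = 1) {
  check_finite_matrix(W0, "W0")
  check_finite_matrix(sigma_yx, "sigma_yx")
  stopifnot(all(dim(W0) == dim(sigma_yx)), tau > 0)
  dev0 <- W0 - sigma_yx
  lapply(times, function(t) sigma_yx + dev0 * exp(-t / tau))
}
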