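#' Numerically check the assumptions behind the exact solutions
#'
#' The closed-form solvers rest on a small set of structural assumptions:
#' equal input/output dimensions (needed only by the reference
#' matrix-exponential solution, [riccati_fukumizu()]); whitened inputs
#' (\eqn{\Sigma^{xx} = I}); zero-balanced initial weights
#' (\eqn{W_1 W_1^T = W_2^T W_2}); full rank of both the task correlation and
#' the initial network function (rank \eqn{= \min(N_i, N_o)}, implying the
#' network is not bottlenecked); and non-singularity of the alignment matrix
#' \eqn{B} (needed by the general stable solution, [exact_qqt()]). This
#' function evaluates all five numerically and reports, alongside each flag,
#' the numeric evidence that justified it. It never raises.
#'
#' @param task a [linear_task()] or [compute_correlations()] result.
#' @param state a [network_state()] with compatible dimensions.
#' @param tol numeric tolerance for the whitening and balancedness checks.
#' @return An object of class `assumption_report`: a list of per-assumption
#'   entries (`equal_dims`, `whitened`, `balanced`, `full_rank`,
#'   `b_nonsingular`), each carrying `pass` plus its numeric evidence, and
#'   two applicability flags: `fukumizu_ok` (all of equal dims, whitened,
#'   balanced, full rank) and `general_ok` (whitened, balanced, full rank,
#'   B non-singular).
#' @export
validate_assumptions <- function(task, state, tol = 1e-8) {
  corr <- if (inherits(task, "task_correlations")) task else compute_correlations(task)
  stopifnot(inherits(state, "network_state"))

  equal_dims <- list(pass = corr$ni == corr$no, ni = corr$ni, no = corr$no)

  wdev <- fnorm(corr$sigma_xx - diag(corr$ni))
  whitened <- list(pass = wdev <= tol, deviation = wdev)

  gap <- balancedness_gap(state)
  balanced <- list(pass = gap <= tol, gap = gap)

  k <- min(corr$ni, corr$no)
  rank_task <- qr(corr$sigma_yx)$rank
  rank_init <- qr(state$W2 %*% state$W1)$rank
  full_rank <- list(
    pass = rank_task == k && rank_init == k,
    rank_sigma_yx = rank_task, rank_init_function = rank_init, required = k
  )

  b_nonsingular <- list(pass = FALSE, min_sv_B = NA_real_)
  if (full_rank$pass) {
    bc <- tryCatch(
      build_bc(compact_svd(state$W2 %*% state$W1), task_svd(corr)),
      error = function(e) NULL
    )
    if (!is.null(bc)) {
      b_nonsingular <- list(pass = !bc$b_singular, min_sv_B = bc$min_sv_B)
    }
  }

  structure(
    list(
      equal_dims = equal_dims, whitened = whitened, balanced = balanced,
      full_rank = full_rank, b_nonsingular = b_nonsingular,
      fukumizu_ok = equal_dims$pass && whitened$pass && balanced$pass && full_rank$pass,
      general_ok = whitened$pass && balanced$pass && full_rank$pass && b_nonsingular$pass,
      tol = tol
    ),
    class = "assumption_report"
  )
}

#' @export
print.assumption_report <- function(x, ...) {
  mark <- function(p) if (isTRUE(p)) "PASS" else "FAIL"
  cat("<assumption_report>\n")
  cat(sprintf("  equal dims      %s  (Ni = %d, No = %d)\n",
              mark(x$equal_dims$pass), x$equal_dims$ni, x$equal_dims$no))
  cat(sprintf("  whitened inputs %s  (|Sxx - I|_F = %.3g)\n",
              mark(x$whitened$pass), x$whitened$deviation))
  cat(sprintf("  zero-balanced   %s  (gap = %.3g)\n",
              mark(x$balanced$pass), x$balanced$gap))
  cat(sprintf("  full rank       %s  (task %d, init %d, required %d)\n",
              mark(x$full_rank$pass), x$full_rank$rank_sigma_yx,
              x$full_rank$rank_init_function, x$full_rank$required))
  cat(sprintf("  B non-singular  %s  (min sv = %.3g)\n",
              mark(x$b_nonsingular$pass), x$b_nonsingular$min_sv_B))
  cat(sprintf("  => reference (matrix-exponential) solver applicable: %s\n",
              mark(x$fukumizu_ok)))
  cat(sprintf("  => general stable solver applicable: %s\n", mark(x$general_ok)))
  invisible(x)
}

# Plain-list view used when embedding reports in JSON summaries.
as_list_assumption_report <- function(x) {
  x <- unclass(x)
  x
}
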