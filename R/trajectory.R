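# Trajectory container shared by the analytic solvers and the simulator.

new_trajectory <- function(times, qq_blocks, tau, source,
                           losses = NULL, extra = list()) {
  stopifnot(length(times) == length(qq_blocks), all(diff(times) > 0) || length(times) <= 1)
  structure(
    c(
      list(times = times, qq = qq_blocks, tau = tau, source = source,
           losses = losses),
      extra
    ),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %s; %d time points on [%.4g, %.4g], tau = %.4g\n",
    x$source, length(x$times), min(x$times), max(x$times), x$tau
  ))
  invisible(x)
}

#' Default time grid for a task
#'
#' 200 log-spaced points over \eqn{[10^{-3}, 50] \cdot \tau / \min \tilde S},
#' covering everything from the earliest transients to well past the slowest
#' mode's convergence timescale.
#'
#' @param tsvd task SVD (anything accepted by [task_svd()]), or a single
#'   number taken to be \eqn{\min \tilde S} directly.
#' @param tau time constant (\eqn{1/\eta}).
#' @param n number of grid points.
#' @return Increasing numeric vector of length `n`.
#' @export
default_time_grid <- function(tsvd, tau = 1, n = 200) {
  s_min <- if (is.numeric(tsvd) && length(tsvd) == 1L) tsvd else min(task_svd(tsvd)$d)
  exp(seq(log(1e-3), log(50), length.out = n)) * tau / s_min
}

#' Loss along a trajectory
#'
#' Evaluates the whitened-input quadratic loss [loss_from_function()] on the
#' network function at every recorded time.
#'
#' @param traj a `trajectory` (from [exact_qqt()], [simulate_gd()], ...).
#' @param corr [compute_correlations()] of the task the loss refers to.
#' @return Numeric vector of losses, one per `traj$times`.
#' @export
loss_trajectory <- function(traj, corr) {
  stopifnot(inherits(traj, "trajectory"))
  vapply(traj$qq, function(qq) loss_from_function(network_function(qq), corr),
         numeric(1))
}
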