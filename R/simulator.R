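#' Simulator configuration
#'
#' @param eta learning rate of full-batch gradient descent; the matching
#'   flow time constant is \eqn{\tau = 1/\eta} and iteration \eqn{k}
#'   corresponds to flow time \eqn{t = k} on that clock (so
#'   \eqn{t/\tau = k\,\eta}).
#' @param steps iteration budget.
#' @param record_stride iterations between recorded snapshots.
#' @param activation `"linear"`, `"tanh"` or `"relu"` (hidden layer only).
#' @param conv_tol convergence threshold: loss above the analytic global
#'   minimum at which training counts as converged.
#' @param seed seed for any explicit perturbation noise.
#' @param noise_scale standard deviation of optional Gaussian noise added to
#'   the weights once at the start (default 0). A tiny value (e.g. `1e-12`)
#'   knocks trajectories off exact saddles, which pure float rounding may
#'   preserve indefinitely.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(eta = 5e-3, steps = 100000L, record_stride = 100L,
                       activation = c("linear", "tanh", "relu"),
                       conv_tol = 1e-8, seed = NULL, noise_scale = 0) {
  activation <- match.arg(activation)
  stopifnot(eta > 0, steps >= 1, record_stride >= 1, conv_tol > 0, noise_scale >= 0)
  structure(
    list(eta = eta, steps = as.integer(steps),
         record_stride = as.integer(record_stride), activation = activation,
         conv_tol = conv_tol, seed = seed, noise_scale = noise_scale),
    class = "sim_config"
  )
}

apply_start_noise <- function(state, cfg) {
  if (cfg$noise_scale <= 0) return(state)
  with_seed(cfg$seed, network_state(
    state$W1 + matrix(stats::rnorm(length(state$W1), sd = cfg$noise_scale),
                      nrow(state$W1)),
    state$W2 + matrix(stats::rnorm(length(state$W2), sd = cfg$noise_scale),
                      nrow(state$W2))
  ))
}

#' Full-batch gradient descent on a linear network (verification oracle)
#'
#' Iterates the exact full-batch updates
#' \eqn{W_1 \leftarrow W_1 + \eta\, W_2^T(\Sigma^{yx} - W_2 W_1 \Sigma^{xx})},
#' \eqn{W_2 \leftarrow W_2 + \eta\, (\Sigma^{yx} - W_2 W_1 \Sigma^{xx}) W_1^T}
#' (simultaneous), recording \eqn{Q Q^T} and the loss every `record_stride`
#' iterations. Discretisation error relative to the gradient flow is
#' \eqn{O(\eta)}, so agreement with the closed forms tightens as \eqn{\eta}
#' shrinks; this is the package's primary numerical check on every analytic
#' expression.
#'
#' @param init a [network_state()].
#' @param task a [linear_task()] or [compute_correlations()] result.
#' @param cfg a [sim_config()] with `activation = "linear"`.
#' @return A `trajectory` (`source = "simulated"`) with recorded times
#'   (iteration counts, starting at 0), `qq` blocks and `losses`.
#' @export
simulate_gd <- function(init, task, cfg = sim_config()) {
  stopifnot(inherits(init, "network_state"), inherits(cfg, "sim_config"))
  if (cfg$activation != "linear") {
    stop("simulate_gd is the linear-network oracle; use simulate_nonlinear for tanh/relu",
         call. = FALSE)
  }
  corr <- if (inherits(task, "task_correlations")) task else compute_correlations(task)
  sxx <- corr$sigma_xx
  syx <- corr$sigma_yx
  msq <- corr$mean_sq_target
  eta <- cfg$eta
  state <- apply_start_noise(init, cfg)
  w1 <- state$W1
  w2 <- state$W2

  loss_of <- function(w1, w2) {
    wt <- w2 %*% w1
    0.5 * (sum(wt * (wt %*% sxx)) - 2 * sum(wt * syx) + msq)
  }
  rec_k <- unique(c(seq(0L, cfg$steps, by = cfg$record_stride), cfg$steps))
  qq_blocks <- vector("list", length(rec_k))
  losses <- numeric(length(rec_k))
  snap <- function(slot) {
    q <- rbind(t(w1), w2)
    qq_blocks[[slot]] <<- qq_block(tcrossprod(q), init$ni, init$no)
    losses[slot] <<- loss_of(w1, w2)
  }
  snap(1L)
  loss0 <- max(losses[1], msq, 1)
  slot <- 1L
  for (k in seq_len(cfg$steps)) {
    g <- syx - w2 %*% (w1 %*% sxx)
    w1n <- w1 + eta * crossprod(w2, g)
    w2 <- w2 + eta * tcrossprod(g, w1)
    w1 <- w1n
    if (k == rec_k[slot + 1L]) {
      if (!all(is.finite(w1)) || !all(is.finite(w2))) {
        stop(sprintf(
          "gradient descent diverged at iteration %d (non-finite weights); reduce eta below the discrete stability threshold",
          k
        ), call. = FALSE)
      }
      slot <- slot + 1L
      snap(slot)
      if (losses[slot] > 1e6 * loss0) {
        stop(sprintf(
          "gradient descent diverged at iteration %d (loss %.3g); reduce eta below the discrete stability threshold",
          k, losses[slot]
        ), call. = FALSE)
      }
    }
  }
  new_trajectory(rec_k, qq_blocks, 1 / eta, "simulated", losses = losses,
                 extra = list(final_state = network_state(w1, w2)))
}

#' Full-batch gradient descent with a hidden-layer nonlinearity
#'
#' Per-sample forward/backward passes for
#' \eqn{\hat y = W_2\, \phi(W_1 x)} with \eqn{\phi} the identity, tanh or
#' ReLU applied at the hidden layer only. Returns the loss and the
#' balancedness gap over training: in nonlinear networks the gap grows
#' rapidly (balancedness is only conserved by the linear flow), which is
#' why pre-computed forgetting predictions fail there. With
#' `activation = "linear"` the updates coincide with [simulate_gd()]
#' exactly (the correlation-matrix gradients are the same algebra).
#'
#' @inheritParams simulate_gd
#' @param cfg a [sim_config()]; any activation.
#' @return List with `times` (iterations), `losses`, `balancedness_gap`
#'   (both per recorded step) and the `final_state`.
#' @export
simulate_nonlinear <- function(init, task, cfg = sim_config(activation = "tanh")) {
  stopifnot(inherits(init, "network_state"), inherits(task, "linear_task"),
            inherits(cfg, "sim_config"))
  X <- task$X
  Y <- task$Y
  p <- task$p
  eta <- cfg$eta
  act <- switch(cfg$activation,
    linear = list(f = identity, df = function(h) 1),
    tanh = list(f = tanh, df = function(h) 1 - tanh(h)^2),
    relu = list(f = function(h) pmax(h, 0), df = function(h) (h > 0) * 1)
  )
  state <- apply_start_noise(init, cfg)
  w1 <- state$W1
  w2 <- state$W2
  rec_k <- unique(c(seq(0L, cfg$steps, by = cfg$record_stride), cfg$steps))
  losses <- numeric(length(rec_k))
  gaps <- numeric(length(rec_k))
  loss_of <- function(w1, w2) sum((w2 %*% act$f(w1 %*% X) - Y)^2) / (2 * p)
  losses[1] <- loss_of(w1, w2)
  gaps[1] <- fnorm(tcrossprod(w1) - crossprod(w2))
  loss0 <- max(losses[1], 1)
  slot <- 1L
  for (k in seq_len(cfg$steps)) {
    h <- w1 %*% X
    phi <- act$f(h)
    err <- w2 %*% phi - Y
    g2 <- tcrossprod(err, phi) / p
    g1 <- (crossprod(w2, err) * act$df(h)) %*% t(X) / p
    w1 <- w1 - eta * g1
    w2 <- w2 - eta * g2
    if (k == rec_k[slot + 1L]) {
      if (!all(is.finite(w1)) || !all(is.finite(w2))) {
        stop(sprintf(
          "gradient descent diverged at iteration %d (non-finite weights); reduce eta",
          k
        ), call. = FALSE)
      }
      slot <- slot + 1L
      losses[slot] <- loss_of(w1, w2)
      gaps[slot] <- fnorm(tcrossprod(w1) - crossprod(w2))
      if (!is.finite(losses[slot]) || losses[slot] > 1e6 * loss0) {
        stop(sprintf(
          "gradient descent diverged at iteration %d (loss %.3g); reduce eta",
          k, losses[slot]
        ), call. = FALSE)
      }
    }
  }
  list(times = rec_k, losses = losses, balancedness_gap = gaps,
       final_state = network_state(w1, w2))
}

#' Continual learning over a task sequence
#'
#' Trains to convergence (loss within `conv_tol` of each task's global
#' minimum) on each task in turn, the converged state of one leg becoming
#' the initialisation of the next. The analytic engine solves each leg with
#' [exact_qqt()] and chains states through [factor_qqt()]; the simulated
#' engine runs [simulate_gd()] in chunks until converged. After every leg,
#' all tasks' losses are evaluated and compared with the pre-computable
#' analytic forgetting predictions of [forgetting_loss()].
#'
#' @param tasks list of whitened [linear_task()]s with matching dimensions.
#' @param init initial [network_state()].
#' @param cfg a [sim_config()]; `eta` sets both engines' time constant and
#'   `conv_tol` the convergence criterion.
#' @param engine `"analytic"` or `"simulated"`.
#' @return An object of class `continual_result`: `final_losses` (rows =
#'   after training leg `j`, columns = evaluated task `i`), `predicted`
#'   (the [forgetting_matrix()]), per-leg `loss_curves` (each a data frame
#'   of time and every task's loss), `assumptions` (one
#'   [validate_assumptions()] report per leg) and `engine`.
#' @export
continual_run <- function(tasks, init, cfg = sim_config(),
                          engine = c("analytic", "simulated")) {
  engine <- match.arg(engine)
  stopifnot(length(tasks) >= 1, all(vapply(tasks, inherits, TRUE, "linear_task")),
            inherits(init, "network_state"))
  corrs <- lapply(tasks, compute_correlations)
  dims <- vapply(corrs, function(cc) c(cc$ni, cc$no), numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all tasks in the sequence must share dimensions", call. = FALSE)
  }
  tsvds <- lapply(corrs, task_svd)
  minima <- vapply(corrs, minimum_loss, numeric(1))
  n_task <- length(tasks)
  tau <- 1 / cfg$eta

  state <- init
  final_losses <- matrix(NA_real_, n_task, n_task,
                         dimnames = dimnames(forgetting_matrix(corrs)))
  loss_curves <- vector("list", n_task)
  reports <- vector("list", n_task)

  for (j in seq_len(n_task)) {
    reports[[j]] <- validate_assumptions(corrs[[j]], state)
    if (engine == "analytic") {
      isvd <- tryCatch(compact_svd(state$W2 %*% state$W1), error = function(e) NULL)
      bc <- if (is.null(isvd) || isvd$rank != tsvds[[j]]$rank) NULL else
        build_bc(isvd, tsvds[[j]])
      if (is.null(bc) || bc$b_singular) {
        stop(sprintf(
          paste0("leg %d: alignment matrix B is singular or rank-deficient ",
                 "(reversal-type leg); the analytic engine cannot cross the ",
                 "saddle - use engine = \"simulated\" or the b_fallback_eps ",
                 "diagnostic of exact_qqt()"), j
        ), call. = FALSE)
      }
      s_min <- min(tsvds[[j]]$d)
      horizon <- 50 * tau / s_min
      grid <- default_time_grid(tsvds[[j]], tau)
      for (attempt in 1:4) {
        traj <- exact_qqt(state, tsvds[[j]], unique(c(grid, horizon)), tau)
        final_qq <- traj$qq[[length(traj$times)]]
        leg_loss <- loss_from_function(network_function(final_qq), corrs[[j]])
        if (leg_loss - minima[j] <= cfg$conv_tol) break
        horizon <- 2 * horizon
        grid <- c(grid, horizon)
      }
      if (leg_loss - minima[j] > cfg$conv_tol) {
        stop(sprintf("leg %d failed to converge analytically", j), call. = FALSE)
      }
      curves <- data.frame(time = traj$times)
      for (i in seq_len(n_task)) {
        curves[[paste0("loss_T", i)]] <- loss_trajectory(traj, corrs[[i]])
      }
      state <- factor_qqt(final_qq, init$nh, seed = cfg$seed)
    } else {
      chunk <- sim_config(eta = cfg$eta, steps = min(cfg$steps, 20000L),
                          record_stride = cfg$record_stride,
                          conv_tol = cfg$conv_tol)
      total <- 0L
      times <- numeric(0)
      leg_qq <- list()
      repeat {
        traj <- simulate_gd(state, corrs[[j]], chunk)
        keep <- if (total == 0L) seq_along(traj$times) else -1L
        times <- c(times, traj$times[keep] + total)
        leg_qq <- c(leg_qq, traj$qq[keep])
        total <- total + chunk$steps
        last <- traj$qq[[length(traj$qq)]]
        state <- traj$final_state
        leg_loss <- loss_from_function(network_function(last), corrs[[j]])
        if (leg_loss - minima[j] <= cfg$conv_tol) break
        if (total >= cfg$steps) {
          stop(sprintf(
            "leg %d did not converge within the %d-step budget (loss above minimum %.3g)",
            j, cfg$steps, leg_loss - minima[j]
          ), call. = FALSE)
        }
      }
      curves <- data.frame(time = times)
      for (i in seq_len(n_task)) {
        curves[[paste0("loss_T", i)]] <- vapply(
          leg_qq, function(qq) loss_from_function(network_function(qq), corrs[[i]]),
          numeric(1)
        )
      }
      final_qq <- leg_qq[[length(leg_qq)]]
    }
    loss_curves[[j]] <- curves
    wfun <- network_function(final_qq)
    final_losses[j, ] <- vapply(
      corrs, function(cc) loss_from_function(wfun, cc), numeric(1)
    )
  }

  structure(
    list(final_losses = final_losses, predicted = forgetting_matrix(corrs),
         loss_curves = loss_curves, assumptions = reports, engine = engine,
         minima = minima),
    class = "continual_result"
  )
}

#' @export
print.continual_result <- function(x, ...) {
  cat(sprintf("<continual_result> %s engine, %d tasks\n", x$engine,
              nrow(x$final_losses)))
  cat(sprintf("  max |final - predicted| = %.3g\n",
              max(abs(x$final_losses - x$predicted))))
  invisible(x)
}
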