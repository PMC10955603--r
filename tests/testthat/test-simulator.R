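test_that("origin is a fixed point and the loss is non-increasing", {
  b <- make_bundle(3, 3, seed = 1)
  zero <- network_state(matrix(0, 4, 3), matrix(0, 3, 4))
  traj <- simulate_gd(zero, b$corr, sim_config(eta = 1e-2, steps = 50,
                                               record_stride = 10))
  expect_true(all(vapply(traj$qq, function(q) all(q$m == 0), logical(1))))

  sim <- simulate_gd(b$init, b$corr, sim_config(eta = 5e-3, steps = 5000,
                                                record_stride = 100))
  expect_true(all(diff(sim$losses) <= 1e-12))
})

test_that("divergence at an unstable learning rate is caught", {
  b <- make_bundle(3, 3, seed = 2, scale = 2)
  expect_error(
    simulate_gd(b$init, b$corr, sim_config(eta = 2, steps = 500,
                                           record_stride = 10)),
    "diverged"
  )
})

test_that("balancedness drifts at the discretisation scale under linear GD", {
  b <- make_bundle(4, 4, seed = 21, scale = 0.3)
  eta <- 5e-4
  g0 <- b$corr$sigma_yx - b$init$W2 %*% b$init$W1
  grad_scale <- sqrt(sum(crossprod(b$init$W2, g0)^2) +
                       sum(tcrossprod(g0, b$init$W1)^2))
  res <- simulate_nonlinear(b$init, b$task,
                            sim_config(eta = eta, steps = 10000,
                                       record_stride = 1000))
  expect_lt(max(res$balancedness_gap), 10 * eta * grad_scale)
})

test_that("linear routing through the nonlinear simulator is identical", {
  b <- make_bundle(3, 4, seed = 7)
  cfg <- sim_config(eta = 2e-3, steps = 1500, record_stride = 300)
  sg <- simulate_gd(b$init, b$corr, cfg)
  sn <- simulate_nonlinear(b$init, b$task, cfg)
  expect_lt(max(abs(sg$losses - sn$losses)), 1e-12)
})

test_that("tanh and relu networks learn on a small task", {
  b <- make_bundle(3, 3, seed = 9, scale = 0.5)
  th <- simulate_nonlinear(b$init, b$task,
                           sim_config(eta = 5e-3, steps = 20000,
                                      record_stride = 2000,
                                      activation = "tanh"))
  expect_lt(min(th$losses), 0.9 * th$losses[1])
  expect_gt(max(th$balancedness_gap), 100 * balancedness_gap(b$init) + 1e-6)

  # all-positive targets and init: relu ends near the linear optimum
  p <- 3
  task <- linear_task(sqrt(p) * diag(p), matrix(runif(p * p, 0.5, 1), p))
  init <- network_state(matrix(runif(12, 0.1, 0.3), 4, p),
                        matrix(runif(12, 0.1, 0.3), p, 4))
  lin <- simulate_nonlinear(init, task, sim_config(eta = 5e-3, steps = 30000,
                                                   record_stride = 3000))
  rl <- simulate_nonlinear(init, task, sim_config(eta = 5e-3, steps = 30000,
                                                  record_stride = 3000,
                                                  activation = "relu"))
  expect_lte(tail(rl$losses, 1), tail(lin$losses, 1) + 1e-3)
})

test_that("continual runs: identical tasks forget nothing, engines agree with theory", {
  task <- make_random_whitened_task(3, 4, seed = 31)
  init <- compatible_balanced_init(compute_correlations(task), 5, scale = 0.1,
                                   seed = 32)
  res <- continual_run(list(task, task), init, sim_config(eta = 5e-3),
                       engine = "analytic")
  expect_lt(abs(res$final_losses[2, 1] - res$final_losses[1, 1]), 1e-6)

  tasks <- list(make_random_whitened_task(3, 4, seed = 33),
                make_random_whitened_task(3, 4, seed = 34))
  init2 <- compatible_balanced_init(compute_correlations(tasks[[1]]), 5,
                                    scale = 0.1, seed = 35)
  for (engine in c("analytic", "simulated")) {
    res <- continual_run(tasks, init2,
                         sim_config(eta = 5e-3, steps = 400000L, seed = 36),
                         engine = engine)
    expect_lt(max(abs(res$final_losses - res$predicted)), 1e-4)
    expect_length(res$assumptions, 2)
  }
})

test_that("a reversal leg stops the analytic continual engine with advice", {
  task <- make_random_whitened_task(3, 3, seed = 41)
  neg <- linear_task(task$X, -task$Y)
  init <- compatible_balanced_init(compute_correlations(task), 4, scale = 0.1,
                                   seed = 42)
  expect_error(
    continual_run(list(task, neg), init, sim_config(eta = 5e-3), "analytic"),
    "leg 2"
  )
})
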