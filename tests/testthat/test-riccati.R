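test_that("general solution is continuous at t = 0 and reaches the fixed point", {
  for (case in list(list(ni = 3, no = 3, scale = 0.3, seed = 1),
                    list(ni = 4, no = 2, scale = 1, seed = 2),
                    list(ni = 2, no = 5, scale = 3, seed = 3))) {
    b <- make_bundle(case$ni, case$no, scale = case$scale, seed = case$seed)
    t_end <- 50 / min(b$tsvd$d)
    traj <- exact_qqt(b$init, b$tsvd, c(1e-12, 1, t_end), tau = 1)
    expect_lt(max(abs(traj$qq[[1]]$m - qq_from_state(b$init)$m)), 1e-8)
    expect_lt(norm(traj$qq[[3]]$m - fixed_point(b$tsvd)$m, "F"), 1e-6)
  }
})

test_that("every analytic block is symmetric PSD and the loss non-increasing", {
  for (seed in 1:4) {
    b <- make_bundle(3 + seed %% 2, 4 - seed %% 2, scale = 0.5, seed = seed)
    grid <- default_time_grid(b$tsvd, 1, 60)
    traj <- exact_qqt(b$init, b$tsvd, grid, 1)
    for (qq in traj$qq) expect_symmetric_psd(qq$m)
    losses <- loss_trajectory(traj, b$corr)
    expect_true(all(diff(losses) <= 1e-10))
    # monotone approach to the fixed point past the slowest timescale
    fp <- fixed_point(b$tsvd)$m
    dist <- vapply(traj$qq, function(q) norm(q$m - fp, "F"), numeric(1))
    late <- grid > 2 / min(b$tsvd$d)
    expect_true(all(diff(dist[late]) <= 1e-10))
  }
})

test_that("reference matrix-exponential route agrees before its instability", {
  b <- make_bundle(3, 3, scale = 0.4, seed = 11)
  times <- seq(0.2, 5, length.out = 15)
  fk <- riccati_fukumizu(b$init, b$corr$sigma_yx, times, tau = 1)
  ex <- exact_qqt(b$init, b$tsvd, times, tau = 1)
  expect_lt(max_qq_dev(fk, ex), 1e-6)
  # t = 0 reduces to the initial statistics exactly
  fk0 <- riccati_fukumizu(b$init, b$corr$sigma_yx, 0, tau = 1)
  expect_lt(max(abs(fk0$qq[[1]]$m - qq_from_state(b$init)$m)), 1e-10)
  expect_error(riccati_fukumizu(b$init, diag(c(1, 0, 0)), 1), "singular")
  expect_error(riccati_fukumizu(b$init, matrix(1, 2, 3), 1), "square")
})

test_that("aligned closed form matches the general solution exactly", {
  b <- make_bundle(3, 3, seed = 13)
  A0 <- matrix(rnorm(9, sd = 0.6), 3, 3)
  ata0 <- crossprod(A0)
  grid <- default_time_grid(b$tsvd, 1, 50)

  ata <- aligned_dynamics(ata0, b$tsvd$d, c(0, grid), 1)
  expect_equal(ata[[1]], ata0, tolerance = 1e-10) # E = I collapses the bracket
  expect_lt(max(abs(ata[[length(ata)]] - diag(b$tsvd$d))), 1e-8) # -> Stilde
  offdiag <- vapply(ata, function(a) max(abs(a[upper.tri(a)])), numeric(1))
  expect_lt(offdiag[length(offdiag)], 1e-8) # cross-coupling dies

  lifted <- aligned_trajectory(ata0, b$tsvd, grid, 1)
  general <- exact_qqt(aligned_init(A0, b$tsvd), b$tsvd, grid, 1)
  expect_lt(max_qq_dev(lifted, general), 1e-8)

  expect_error(aligned_dynamics(matrix(c(1, 1, 1, 1), 2), c(1, 1), 1, 1),
               "singular")
})

test_that("cross-coupling peak time matches its closed form and a grid search", {
  # frozen value of the printed formula: (1/4) * log(0.8 / 0.0075)
  expect_equal(two_by_two_offdiag_peak(0.1, 0.1, 0.05, 1, tau = 1),
               0.25 * log(0.8 / 0.0075), tolerance = 1e-12)
  expect_equal(round(two_by_two_offdiag_peak(0.1, 0.1, 0.05, 1), 4), 1.1674)

  expect_true(is.na(two_by_two_offdiag_peak(0.1, 0.2, 0, 1))) # decoupled
  expect_true(is.na(two_by_two_offdiag_peak(0.6, 0.7, 0.3, 1))) # large init
  expect_error(two_by_two_offdiag_peak(0.1, 0.1, 0.05, 1, 2), "equal task")
  expect_error(two_by_two_offdiag_peak(0.1, 0.1, 0.2, 1), "positive")

  set.seed(101)
  for (i in 1:10) {
    a1 <- runif(1, 0.01, 0.05); a2 <- runif(1, 0.01, 0.05)
    b0 <- runif(1, 0.2, 0.9) * sqrt(a1 * a2)
    tp <- two_by_two_offdiag_peak(a1, a2, b0, 1)
    times <- seq(tp / 4, 4 * tp, length.out = 1500)
    ata <- aligned_dynamics(matrix(c(a1, b0, b0, a2), 2), c(1, 1), times, 1)
    b_abs <- vapply(ata, function(a) abs(a[1, 2]), numeric(1))
    expect_lt(abs(times[which.max(b_abs)] - tp), diff(times)[1] + 1e-12)
  }
})

test_that("sigmoid mode: limits and coherent-regime agreement", {
  expect_equal(sigmoid_mode(0.03, 0.01, 2, 0), 0.03) # t = 0
  expect_equal(sigmoid_mode(0.01, 0, 1.5, 1e4), 1.5, tolerance = 1e-8) # a2 = 0 limit
  expect_equal(sigmoid_mode(0.01, -0.01, 1, 1e6), 0) # guarded zero denominator

  # coherent (rank-one) small init: the formula is the exact dominant mode
  a1 <- 0.01; a2 <- 0.006; b0 <- sqrt(a1 * a2 * (1 - 1e-5))
  times <- seq(0, 5, length.out = 120)
  ata <- aligned_dynamics(matrix(c(a1, b0, b0, a2), 2), c(1, 1), times, 1)
  expect_lt(max(abs(vapply(ata, function(a) a[1, 1], numeric(1)) -
                      sigmoid_mode(a1, a2, 1, times))), 1e-3)
})

test_that("shallow closed form solves the single-layer flow", {
  b <- make_bundle(3, 4, seed = 19)
  w0 <- matrix(rnorm(12, sd = 0.5), 4, 3)
  ws <- shallow_dynamics(w0, b$corr$sigma_yx, c(0, 30), tau = 1)
  expect_equal(ws[[1]], w0)
  expect_lt(max(abs(ws[[2]] - b$corr$sigma_yx)), 1e-8)

  # independent oracle: literal single-layer gradient descent
  eta <- 1e-3
  w <- w0
  for (k in 1:4000) w <- w + eta * (b$corr$sigma_yx - w %*% b$corr$sigma_xx)
  expect_lt(max(abs(shallow_dynamics(w0, b$corr$sigma_yx, 4000, tau = 1 / eta)[[1]] - w)),
            1e-4)
})

test_that("factor_qqt inverts qq_from_state up to the hidden gauge", {
  b <- make_bundle(3, 3, seed = 23)
  fp <- fixed_point(b$tsvd)
  st <- factor_qqt(fp, 5, seed = 7)
  expect_lt(max(abs(st$W2 %*% st$W1 -
                      b$tsvd$u %*% (b$tsvd$d * t(b$tsvd$v)))), 1e-8)
  expect_lt(balancedness_gap(st), 1e-8)
  expect_lt(max(abs(qq_from_state(st)$m - fp$m)), 1e-8)
  expect_error(factor_qqt(fp, 1), "rank")
  bad <- qq_block(diag(6) - 2 * diag(6), 3, 3) # negative definite
  expect_error(factor_qqt(bad, 4), "positive semidefinite")
})

test_that("singular alignment raises the documented separatrix error", {
  b <- make_bundle(3, 3, seed = 29)
  rev <- balanced_init_from_product(-b$corr$sigma_yx, 4, seed = 1)
  expect_error(exact_qqt(rev, b$tsvd, 1, 1), "separatrix")
})
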