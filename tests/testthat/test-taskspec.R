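test_that("correlations are exact sample averages", {
  task <- linear_task(sqrt(2) * diag(2), sqrt(2) * diag(c(1, 2)))
  corr <- compute_correlations(task)
  expect_equal(corr$sigma_xx, diag(2))
  expect_equal(corr$sigma_yx, diag(c(1, 2)))
  expect_equal(corr$mean_sq_target, 5)

  zero_y <- compute_correlations(linear_task(sqrt(2) * diag(2), matrix(0, 2, 2)))
  expect_equal(zero_y$sigma_yx, matrix(0, 2, 2))
  expect_equal(zero_y$mean_sq_target, 0)

  e1 <- matrix(c(1, 0, 0), 3, 1)
  single <- compute_correlations(linear_task(e1, e1))
  expect_equal(single$sigma_xx, tcrossprod(e1))
  expect_equal(single$sigma_yx, tcrossprod(e1))
})

test_that("correlations are invariant to sample permutations", {
  set.seed(7)
  X <- matrix(rnorm(12), 3, 4)
  Y <- matrix(rnorm(8), 2, 4)
  perm <- c(3, 1, 4, 2)
  a <- compute_correlations(linear_task(X, Y))
  b <- compute_correlations(linear_task(X[, perm], Y[, perm]))
  expect_equal(a$sigma_xx, b$sigma_xx)
  expect_equal(a$sigma_yx, b$sigma_yx)
  expect_equal(a$mean_sq_target, b$mean_sq_target)
})

test_that("dimension mismatch between X and Y is an input error", {
  expect_error(linear_task(diag(2), matrix(0, 2, 3)), "same number of columns")
})

test_that("compact SVD truncates, reconstructs, and builds exact projectors", {
  sv <- compact_svd(diag(c(3, 0)))
  expect_equal(sv$rank, 1L)
  expect_equal(sv$d, 3)

  sv3 <- compact_svd(diag(3))
  expect_equal(sv3$d, rep(1, 3))
  expect_equal(sv3$pu_perp, matrix(0, 3, 3))
  expect_equal(sv3$pv_perp, matrix(0, 3, 3))

  set.seed(11)
  m <- matrix(rnorm(6), 3, 2) %*% matrix(rnorm(10), 2, 5) # 3x5, rank 2
  sv2 <- compact_svd(m)
  expect_equal(sv2$rank, 2L)
  expect_lt(max(abs(sv2$u %*% (sv2$d * t(sv2$v)) - m)), 1e-10)
  expect_equal(sum(diag(sv2$pv_perp)), 3) # 5 - 2 kernel directions
  # projectors annihilate the retained vectors and are idempotent
  expect_lt(max(abs(sv2$pu_perp %*% sv2$u)), 1e-12)
  expect_lt(max(abs(sv2$pv_perp %*% sv2$v)), 1e-12)
  expect_lt(max(abs(sv2$pv_perp %*% sv2$pv_perp - sv2$pv_perp)), 1e-12)

  expect_error(compact_svd(matrix(0, 2, 2)), "rank-0")
})

test_that("hierarchy task is whitened, full rank, with nested similarity", {
  for (depth in 1:4) {
    task <- make_hierarchy_task(depth)
    p <- 2^depth
    expect_equal(c(task$ni, task$no, task$p), rep(p, 3))
    corr <- compute_correlations(task)
    expect_lt(norm(corr$sigma_xx - diag(p), "F"), 1e-12)
    expect_equal(task_svd(corr)$rank, p)
  }

  # two-leaf case: symmetric items
  t1 <- task_svd(make_hierarchy_task(1))
  rsm1 <- t1$v %*% (t1$d * t(t1$v))
  expect_equal(rsm1[1, 1], rsm1[2, 2])
  expect_equal(rsm1[1, 2], rsm1[2, 1])

  # depth 3: sibling leaves more similar than any cross-subtree pair
  t3 <- task_svd(make_hierarchy_task(3))
  rsm3 <- t3$v %*% (t3$d * t(t3$v))
  expect_gt(rsm3[1, 2], rsm3[1, 3]) # sibling vs cousin
  expect_gt(rsm3[1, 3], rsm3[1, 5]) # cousin vs opposite half
})

test_that("random whitened tasks realise requested spectra deterministically", {
  task <- make_random_whitened_task(4, 4, seed = 5)
  corr <- compute_correlations(task)
  expect_lt(norm(corr$sigma_xx - diag(4), "F"), 1e-12)

  spec <- make_random_whitened_task(2, 2, seed = 9, singular_values = c(2, 1))
  expect_equal(task_svd(spec)$d, c(2, 1))

  a <- make_random_whitened_task(3, 5, seed = 42)
  b <- make_random_whitened_task(3, 5, seed = 42)
  expect_identical(a$X, b$X)
  expect_identical(a$Y, b$Y)

  expect_error(make_random_whitened_task(2, 2, singular_values = c(3, 2, 1)),
               "at most")
  expect_error(make_random_whitened_task(3, 3, singular_values = c(2, 1)),
               "full-rank")
})

test_that("assumption report carries numeric evidence and never raises", {
  b <- make_bundle(3, 3, seed = 31)
  rep_ok <- validate_assumptions(b$task, b$init)
  expect_true(rep_ok$equal_dims$pass)
  expect_true(rep_ok$whitened$pass)
  expect_true(rep_ok$balanced$pass)
  expect_true(rep_ok$full_rank$pass)
  expect_true(rep_ok$b_nonsingular$pass)
  expect_true(rep_ok$fukumizu_ok)
  expect_true(rep_ok$general_ok)

  # exactly sign-reversed init: B singular, everything else fine
  rev <- balanced_init_from_product(-b$corr$sigma_yx, 4, seed = 1)
  rep_rev <- validate_assumptions(b$task, rev)
  expect_false(rep_rev$b_nonsingular$pass)
  expect_lt(rep_rev$b_nonsingular$min_sv_B, 1e-10)
  expect_true(rep_rev$balanced$pass)

  # one-hot inputs without the sqrt(P) scaling: Sigma_xx = I/P
  p <- 4
  raw <- linear_task(diag(p), diag(p))
  rep_raw <- validate_assumptions(raw, random_balanced_init(p, p, p, seed = 2))
  expect_false(rep_raw$whitened$pass)
  expect_equal(rep_raw$whitened$deviation, norm(diag(p) / p - diag(p), "F"))
})
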