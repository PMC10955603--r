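test_that("balancedness gap: closed forms and unitary invariance", {
  expect_equal(balancedness_gap(network_state(diag(3), 2 * diag(3))),
               3 * sqrt(3)) # |I - 4I|_F
  st <- random_balanced_init(3, 4, 5, seed = 1)
  o <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  rotated <- network_state(o %*% st$W1, st$W2 %*% t(o))
  expect_equal(balancedness_gap(rotated), balancedness_gap(st), tolerance = 1e-10)
})

test_that("random balanced inits are exactly balanced, full rank, seeded", {
  for (seed in 1:5) {
    st <- random_balanced_init(4, 3, 6, scale = 0.7, seed = seed)
    expect_lt(balancedness_gap(st), 1e-10)
    expect_equal(compact_svd(st$W2 %*% st$W1)$rank, 3L)
  }
  expect_identical(random_balanced_init(3, 3, 4, seed = 8)$W1,
                   random_balanced_init(3, 3, 4, seed = 8)$W1)
  expect_error(random_balanced_init(4, 4, 2), "bottleneck")
})

test_that("function norm scales linearly with the init scale", {
  norms <- vapply(1:100, function(seed) {
    s1 <- random_balanced_init(4, 4, 5, scale = 1, seed = seed)
    s2 <- random_balanced_init(4, 4, 5, scale = 2, seed = seed)
    norm(s2$W2 %*% s2$W1, "F") / norm(s1$W2 %*% s1$W1, "F")
  }, numeric(1))
  expect_true(all(abs(norms - 2) < 0.4)) # x2 in expectation, 20% slack
})

test_that("product init reproduces a prescribed function", {
  m <- diag(c(2, 1))
  st <- balanced_init_from_product(m, 2, seed = 3)
  expect_lt(max(abs(st$W2 %*% st$W1 - m)), 1e-10)
  expect_lt(balancedness_gap(st), 1e-10)
  # W1'W1 carries the function's right-singular structure V S V'
  sv <- compact_svd(m)
  expect_equal(crossprod(st$W1), sv$v %*% (sv$d * t(sv$v)), tolerance = 1e-10)
  expect_error(balanced_init_from_product(diag(3), 2), "rank")

  b <- make_bundle(3, 3, seed = 17)
  conv <- balanced_init_from_product(b$corr$sigma_yx, 5, seed = 4)
  expect_lt(max(abs(conv$W2 %*% conv$W1 - b$corr$sigma_yx)), 1e-10)
})

test_that("aligned init shares the task's singular pairing", {
  b <- make_bundle(3, 3, seed = 23)
  A0 <- matrix(rnorm(12, sd = 0.5), 4, 3)
  st <- aligned_init(A0, b$tsvd)
  expect_lt(balancedness_gap(st), 1e-10)
  expect_equal(st$W2 %*% st$W1,
               b$tsvd$u %*% crossprod(A0) %*% t(b$tsvd$v), tolerance = 1e-10)

  # A0'A0 diagonal (descending) => decoupled: B = 2I, C = 0
  Ad <- diag(c(0.9, 0.5, 0.2))
  std <- aligned_init(Ad, b$tsvd)
  bc <- build_bc(compact_svd(std$W2 %*% std$W1), b$tsvd)
  expect_lt(max(abs(bc$B - 2 * diag(3))), 1e-8)
  expect_lt(max(abs(bc$C)), 1e-8)

  expect_error(aligned_init(matrix(0.1, 4, 3), compact_svd(diag(c(2, 1, 0)))),
               "full-rank")
})

test_that("alignment matrices satisfy their defining identities", {
  b <- make_bundle(4, 3, seed = 29)
  isvd <- compact_svd(b$init$W2 %*% b$init$W1)
  bc <- build_bc(isvd, b$tsvd)
  expect_lt(max(abs(bc$B + bc$C - 2 * crossprod(isvd$u, b$tsvd$u))), 1e-12)
  expect_lt(max(abs(bc$B - bc$C - 2 * crossprod(isvd$v, b$tsvd$v))), 1e-12)

  # exact sign reversal: B = 0
  rev <- balanced_init_from_product(-b$corr$sigma_yx, 5, seed = 2)
  bc_rev <- build_bc(compact_svd(rev$W2 %*% rev$W1), b$tsvd)
  expect_lt(bc_rev$min_sv_B, 1e-10)
  expect_true(bc_rev$b_singular)

  expect_error(build_bc(compact_svd(diag(c(1, 1))), compact_svd(diag(c(1, 1, 1)))),
               "rank")
})

test_that("orientation-mismatched square inits have exactly singular B", {
  b <- make_bundle(3, 3, seed = 37)
  st <- random_balanced_init(3, 3, 4, scale = 0.5, seed = 101)
  f <- st$W2 %*% st$W1
  if (sign(det(f)) == sign(det(b$corr$sigma_yx))) {
    # flip one mode to force the orientation mismatch
    sv <- compact_svd(f)
    f <- f - 2 * sv$d[3] * sv$u[, 3] %*% t(sv$v[, 3])
    st <- balanced_init_from_product(f, 4, seed = 5)
  }
  bc <- build_bc(compact_svd(st$W2 %*% st$W1), b$tsvd)
  expect_lt(bc$min_sv_B, 1e-12)
  # and the conditioned sampler avoids it by construction
  ok <- compatible_balanced_init(b$tsvd, 4, scale = 0.5, seed = 101)
  bc_ok <- build_bc(compact_svd(ok$W2 %*% ok$W1), b$tsvd)
  expect_gt(bc_ok$min_sv_B, 0.1)
})
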