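# Fixtures are generated in code; every helper is deterministic given `seed`.

# A whitened task with its correlations, SVD, and a compatible balanced init.
make_bundle <- function(ni = 3, no = 3, nh = max(ni, no) + 1, scale = 0.3,
                        seed = 1, singular_values = NULL) {
  task <- make_random_whitened_task(ni, no, seed = seed,
                                    singular_values = singular_values)
  corr <- compute_correlations(task)
  tsvd <- task_svd(corr)
  init <- compatible_balanced_init(tsvd, nh, scale = scale, seed = seed + 1000)
  list(task = task, corr = corr, tsvd = tsvd, init = init)
}

max_qq_dev <- function(traj_a, traj_b) {
  max(vapply(seq_along(traj_a$qq),
             function(k) max(abs(traj_a$qq[[k]]$m - traj_b$qq[[k]]$m)),
             numeric(1)))
}

expect_symmetric_psd <- function(m, tol = 1e-8) {
  expect_lt(max(abs(m - t(m))), tol * max(1, max(abs(m))))
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -tol * max(1, max(abs(ev))))
}
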