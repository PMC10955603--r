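# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Random matrix with orthonormal columns (n x k, k <= n), Haar up to QR signs.
rand_orthonormal <- function(n, k) {
  stopifnot(k <= n)
  qr.Q(qr(matrix(stats::rnorm(n * k), n, k)))[, seq_len(k), drop = FALSE]
}

fnorm <- function(m) sqrt(sum(m^2))

# Scale column j of M by e[j]  (M %*% diag(e) without forming diag(e)).
colscale <- function(m, e) m * rep(e, each = nrow(m))

symmetrize <- function(m) (m + t(m)) / 2

is_square_matrix <- function(m) is.matrix(m) && nrow(m) == ncol(m)

check_finite_matrix <- function(m, name) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  }
  if (!all(is.finite(m))) {
    stop(sprintf("'%s' contains non-finite entries", name), call. = FALSE)
  }
  invisible(m)
}
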