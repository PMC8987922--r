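# Independent reference implementations used to check the spectral shortcuts.
# All work by dense matrix algebra or explicit refitting and never call the
# package's fast paths.

# all n! permutations of 1:n (tiny n only)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# dense ridge hat matrix by direct p x p inversion
dense_hat <- function(x, lambda) {
  p <- ncol(x)
  x %*% solve(crossprod(x) + diag(lambda, p)) %*% t(x)
}

# dense GCV from the full smoother (intercept + ridge); y is centered so the
# intercept block contributes only its degree of freedom
dense_gcv <- function(x, y, lambda) {
  n <- nrow(x)
  h <- dense_hat(x, lambda)
  r <- y - drop(h %*% y)
  mean((r / (1 - (1 + sum(diag(h))) / n))^2)
}

# dense LOOCV from the full smoother leverages 1/n + [H]_ii
dense_loocv <- function(x, y, lambda) {
  n <- nrow(x)
  h <- dense_hat(x, lambda)
  r <- y - drop(h %*% y)
  mean((r / (1 - 1 / n - diag(h)))^2)
}

# score statistic as a dense quadratic form (no clipping; valid whenever all
# raw weights are non-negative)
dense_score <- function(x, y, lambda) {
  drop(t(y) %*% dense_hat(x, lambda) %*% y)
}

# standardized design + decomposition for a seeded Gaussian matrix
toy_decomp <- function(n, p, seed) {
  set.seed(seed)
  std <- standardize_design(matrix(rnorm(n * p), n, p))
  list(std = std, decomp = design_svd(std))
}
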