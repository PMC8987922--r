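#' Center and scale a design matrix
#'
#' Columns are centered to mean zero and, optionally, scaled to unit standard
#' deviation (denominator `n - 1`). Constant columns are centered and left
#' unscaled with a warning; dropping them is left to the caller. Centering and
#' scaling put all features on a common footing so that a single ridge penalty
#' acts comparably on every coefficient.
#'
#' @param x numeric matrix, subjects in rows (at least 2 rows, no missing
#'   values).
#' @param scale logical; scale non-constant columns to unit standard deviation?
#' @return An object of class `"standardized_design"`: a list with elements
#'   `x` (the standardized matrix), `n`, `p`, `column_means`, `column_sds`
#'   (the sds actually divided by; 1 for constant or unscaled columns), and
#'   `scaled`.
#' @examples
#' std <- standardize_design(matrix(rnorm(24), 6, 4))
#' colMeans(std$x)  # all ~0
#' @export
standardize_design <- function(x, scale = TRUE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("design matrix must be numeric")
  if (nrow(x) < 2L) stop("design matrix must have at least 2 rows")
  if (anyNA(x)) stop("design matrix contains missing values")
  n <- nrow(x)
  p <- ncol(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  sds <- rep(1, p)
  if (scale) {
    s <- sqrt(colSums(xc^2) / (n - 1))
    constant <- s < .Machine$double.eps * 100
    if (any(constant)) {
      warning(sum(constant), " constant column(s) centered but not scaled")
    }
    s[constant] <- 1
    xc <- sweep(xc, 2L, s, "/")
    sds <- s
  }
  structure(
    list(x = xc, n = n, p = p, column_means = mu, column_sds = sds,
         scaled = scale),
    class = "standardized_design"
  )
}

.design_matrix <- function(design) {
  if (inherits(design, "standardized_design")) design$x else as.matrix(design)
}

#' Spectral decomposition of a standardized design
#'
#' Computes the left singular vectors and singular values of the design. When
#' `p > n` the decomposition is obtained from the n-by-n Gram matrix XX' by a
#' symmetric eigendecomposition, which is all downstream computations need and
#' keeps the cost at O(n^2 p). The rank cutoff is applied on the eigenvalue
#' scale — `d_j^2 <= max(d)^2 * 1e-12 * max(n, p)` is treated as zero — since
#' the Gram-route eigenvalues are accurate to machine precision times the
#' spectral norm, whereas their square roots are not.
#'
#' @param design a `"standardized_design"` or a plain (already centered)
#'   numeric matrix.
#' @return An object of class `"design_svd"`: list with `u` (n-by-r,
#'   orthonormal columns), `d` (non-increasing positive singular values),
#'   `r` (rank), `n`, `p`.
#' @export
design_svd <- function(design) {
  x <- .design_matrix(design)
  n <- nrow(x)
  p <- ncol(x)
  if (all(x == 0)) stop("design is identically zero; no spectral decomposition")
  if (p > n) {
    eg <- eigen(tcrossprod(x), symmetric = TRUE)
    d <- sqrt(pmax(eg$values, 0))
    u <- eg$vectors
  } else {
    sv <- svd(x, nu = min(n, p), nv = 0)
    d <- sv$d
    u <- sv$u
  }
  keep <- d^2 > max(d)^2 * 1e-12 * max(n, p)
  structure(
    list(u = u[, keep, drop = FALSE], d = d[keep], r = sum(keep), n = n, p = p),
    class = "design_svd"
  )
}

#' @export
print.design_svd <- function(x, ...) {
  cat("Spectral decomposition: n =", x$n, ", p =", x$p, ", rank =", x$r, "\n")
  cat("singular values in [", format(min(x$d), digits = 4), ",",
      format(max(x$d), digits = 4), "]\n")
  invisible(x)
}

.eps_singular <- function(d) 1e-8 * max(d)^2

#' Ridge score-test weights
#'
#' The weight on the j-th spectral component of the ridge score statistic is
#' `d_j^2 / (d_j^2 + lambda)`. At `lambda = 0` the Moore-Penrose convention of
#' the fixed-effects score test applies: weight 1 wherever `d_j > 0`, else 0.
#' For admissible negative penalties weights may exceed 1 (up-weighting
#' low-variance directions); any weight that would be negative is clipped to 0
#' when `clip = TRUE` so that the statistic remains a non-negative mixture of
#' chi-squared components.
#'
#' @param d non-negative singular values.
#' @param lambda ridge penalty (may be negative).
#' @param clip logical; clip negative weights to zero (default `TRUE`).
#' @return numeric vector of weights, same length as `d`.
#' @examples
#' ridge_weights(c(2, 1), 0)    # c(1, 1)
#' ridge_weights(c(2, 1), -2)   # c(2, 0): raw (2, -1), clipped
#' @export
ridge_weights <- function(d, lambda, clip = TRUE) {
  if (any(d < 0)) stop("singular values must be non-negative")
  if (lambda == 0) {
    return(as.numeric(d > 0))
  }
  d2 <- d^2
  if (any(abs(d2 + lambda) < .eps_singular(d))) {
    stop("penalty is within the exclusion radius of -d_j^2 for some j ",
         "(singular penalty)")
  }
  w <- d2 / (d2 + lambda)
  w[d == 0] <- 0
  if (clip) w <- pmax(w, 0)
  w
}

#' Ridge regression score statistic
#'
#' Computes `T(lambda) = sum_j w_j(lambda) z_j^2` with `z = U'y`, the spectral
#' form of the ridge score statistic `tr(H_lambda y y')` = `y' H_lambda y`
#' (the two coincide exactly when no weight clipping occurs).
#'
#' @param decomp a [design_svd()] decomposition.
#' @param y centered response vector of length `n`.
#' @param lambda ridge penalty.
#' @param clip clip negative weights to zero (see [ridge_weights()]).
#' @return Object of class `"ridge_score"`: list with `lambda`, `weights`,
#'   `z`, `statistic`.
#' @export
score_statistic <- function(decomp, y, lambda, clip = TRUE) {
  stopifnot(inherits(decomp, "design_svd"))
  y <- as.numeric(y)
  if (length(y) != decomp$n) stop("length(y) must equal n")
  z <- drop(crossprod(decomp$u, y))
  w <- ridge_weights(decomp$d, lambda, clip = clip)
  structure(
    list(lambda = lambda, weights = w, z = z, statistic = sum(w * z^2)),
    class = "ridge_score"
  )
}

#' @export
print.ridge_score <- function(x, ...) {
  cat("Ridge score statistic T(lambda =", format(x$lambda), ") =",
      format(x$statistic), "\n")
  invisible(x)
}

#' Fixed-effects score statistic
#'
#' The global-test score statistic `y'X(X'X)^- X'y` under the fixed-effects
#' model, i.e. the ridge statistic at `lambda = 0` with the Moore-Penrose
#' pseudoinverse convention: `sum_{d_j > 0} z_j^2`.
#'
#' @inheritParams score_statistic
#' @return non-negative scalar.
#' @export
fixed_effects_statistic <- function(decomp, y) {
  score_statistic(decomp, y, 0)$statistic
}

#' Random-effects (variance-component) score statistic
#'
#' The score statistic for testing a zero variance component,
#' `sum_j d_j^2 z_j^2 = ||X'y||^2 = tr(XX' yy')`; the `lambda -> Inf` limit of
#' the ridge family after rescaling by `lambda`.
#'
#' @inheritParams score_statistic
#' @return non-negative scalar.
#' @export
random_effects_statistic <- function(decomp, y) {
  stopifnot(inherits(decomp, "design_svd"))
  y <- as.numeric(y)
  if (length(y) != decomp$n) stop("length(y) must equal n")
  z <- drop(crossprod(decomp$u, y))
  sum(decomp$d^2 * z^2)
}

#' Ridge hat (Gram) matrix
#'
#' `H_lambda = X (X'X + lambda I_p)^{-1} X'`. When `p > n` the n-by-n identity
#' `X'(XX' + lambda I_n)^{-1} = (X'X + lambda I_p)^{-1} X'` is used so only an
#' n-by-n system is solved. The trace of the result equals
#' `sum_j d_j^2 / (d_j^2 + lambda)`, the effective degrees of freedom.
#'
#' @param design a `"standardized_design"` or centered numeric matrix.
#' @param lambda ridge penalty; must keep the penalized system invertible.
#' @return symmetric n-by-n matrix.
#' @export
hat_matrix <- function(design, lambda) {
  x <- .design_matrix(design)
  n <- nrow(x)
  p <- ncol(x)
  h <- tryCatch(
    if (p > n) {
      g <- tcrossprod(x)
      g %*% solve(g + diag(lambda, n))
    } else {
      x %*% solve(crossprod(x) + diag(lambda, p), t(x))
    },
    error = function(e) stop("singular penalized system at lambda = ", lambda,
                             ": ", conditionMessage(e))
  )
  (h + t(h)) / 2
}
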