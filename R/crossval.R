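# Spectral evaluation of GCV / LOOCV over the penalty grid, for one response
# or a whole matrix of (permuted) responses at once.
#
# With X = U D V' and raw weights w_j = d_j^2/(d_j^2 + lambda) (never clipped
# here: cross-validation scores genuine ridge predictions, clipping belongs to
# the test statistic), the fitted values are yhat = U diag(w) U'y, so
#   ||y - yhat||^2 = sum_j (1 - w_j)^2 z_j^2 + (||y||^2 - ||z||^2)
# with z = U'y; the second term is the part of y orthogonal to the column
# space. The full fitting procedure removes the mean before penalized fitting,
# so the effective smoother is S = J/n + H_lambda (an unpenalized intercept
# plus the ridge on centered columns, orthogonal pieces); its degrees of
# freedom are 1 + sum_j w_j and its leverages 1/n + sum_j U_ij^2 w_j. Without
# the intercept's degree of freedom a centered design (rank n - 1) would make
# near-interpolation look free: the residual vanishes as lambda -> 0 while the
# denominator stays bounded away from zero.
.cv_matrix <- function(decomp, Y, grid, method = c("gcv", "loocv")) {
  method <- match.arg(method)
  u <- decomp$u
  d2 <- decomp$d^2
  n <- decomp$n
  Y <- as.matrix(Y)
  Z <- crossprod(u, Y)
  Z2 <- Z^2
  vals <- matrix(Inf, grid$M, ncol(Y))

  if (method == "gcv") {
    perp <- pmax(colSums(Y^2) - colSums(Z2), 0)
    idx <- which(grid$valid)
    W <- outer(grid$values[idx], d2, function(l, dd) dd / (dd + l))
    tr <- 1 + rowSums(W)
    ok <- abs(1 - tr / n) >= 1e-10
    if (any(ok)) {
      A <- (1 - W[ok, , drop = FALSE])^2
      rss <- A %*% Z2 + rep(perp, each = sum(ok))
      vals[idx[ok], ] <- rss / (n * (1 - tr[ok] / n)^2)
    }
  } else {
    u2 <- u^2
    for (m in which(grid$valid)) {
      w <- d2 / (d2 + grid$values[m])
      h <- 1 / n + drop(u2 %*% w)
      if (any(abs(1 - h) < 1e-10)) next
      resid <- (Y - u %*% (w * Z)) / (1 - h)
      vals[m, ] <- colMeans(resid^2)
    }
  }
  list(values = vals, Z2 = Z2)
}

# Smallest-lambda tie-break: which.min returns the first minimum and the grid
# is strictly increasing.
.select_index <- function(values) {
  if (!any(is.finite(values))) {
    stop("no admissible penalty: all cross-validation values are infinite")
  }
  which.min(values)
}

.cv_curve <- function(decomp, y, grid, method) {
  vals <- drop(.cv_matrix(decomp, y, grid, method)$values)
  idx <- .select_index(vals)
  structure(
    list(method = toupper(method), grid = grid, values = vals,
         lambda_hat = grid$values[idx], index_hat = idx),
    class = "cv_curve"
  )
}

#' Generalized cross-validation curve over the penalty grid
#'
#' Evaluates `gcv(lambda) = mean_i ((y_i - yhat_i) / (1 - tr(S_lambda)/n))^2`
#' on every valid grid value via the spectral shortcut (no refitting), and
#' selects the minimizer. The smoother `S_lambda` is the full fitting
#' procedure — mean removal plus the ridge on the centered design — so its
#' trace is `1 + sum_j d_j^2/(d_j^2 + lambda)`. Grid values that are singular
#' or make the denominator vanish carry an `Inf` sentinel.
#'
#' @param decomp a [design_svd()] decomposition.
#' @param y centered response vector of length `n`.
#' @param grid a [lambda_grid()].
#' @return Object of class `"cv_curve"`: list with `method`, `grid`, `values`
#'   (length `M`, `Inf` where invalid), `lambda_hat`, `index_hat`. Ties are
#'   broken toward the smallest penalty.
#' @export
gcv_curve <- function(decomp, y, grid) .cv_curve(decomp, y, grid, "gcv")

#' Leave-one-out cross-validation curve over the penalty grid
#'
#' Evaluates `loocv(lambda) = mean_i ((y_i - yhat_i) / (1 - [S_lambda]_ii))^2`
#' using the smoother leverages `[S_lambda]_ii = 1/n + sum_j U_ij^2 w_j`
#' (intercept plus ridge) from the spectral decomposition — exactly
#' equivalent to n explicit leave-one-out refits of the intercept-plus-ridge
#' model, but without performing them.
#'
#' @inheritParams gcv_curve
#' @return Object of class `"cv_curve"`; see [gcv_curve()].
#' @export
loocv_curve <- function(decomp, y, grid) .cv_curve(decomp, y, grid, "loocv")

#' Penalty selected by a cross-validation curve
#'
#' @param curve a `"cv_curve"` from [gcv_curve()] or [loocv_curve()].
#' @return the grid value minimizing the curve (ties toward the smallest
#'   penalty).
#' @export
select_lambda <- function(curve) {
  stopifnot(inherits(curve, "cv_curve"))
  curve$grid$values[.select_index(curve$values)]
}

#' @export
print.cv_curve <- function(x, ...) {
  cat(x$method, "curve over", x$grid$M, "penalties;",
      sum(is.finite(x$values)), "finite\n")
  cat("selected lambda_hat =", format(x$lambda_hat), "(min =",
      format(min(x$values)), ")\n")
  invisible(x)
}

#' @export
plot.cv_curve <- function(x, ...) {
  ok <- is.finite(x$values)
  graphics::plot(x$grid$values[ok], x$values[ok], type = "l",
                 xlab = "ridge penalty", ylab = tolower(x$method), ...)
  graphics::abline(v = x$lambda_hat, lty = 2)
  invisible(x)
}

#' Leave-one-out cross-validation by explicit refitting
#'
#' Direct implementation of the LOOCV definition: for each observation i the
#' intercept-plus-ridge model is refit on the remaining n - 1 rows (fold-wise
#' centering, then the penalized slope solve) and used to predict y_i. O(n)
#' linear solves; intended as a reference for the spectral shortcut and for
#' small problems.
#'
#' @param design a `"standardized_design"` or centered numeric matrix.
#' @param y centered response vector.
#' @param lambda ridge penalty (may be negative if admissible for every fold).
#' @return mean squared leave-one-out prediction error.
#' @export
loocv_bruteforce <- function(design, y, lambda) {
  x <- .design_matrix(design)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 3L) stop("need at least 3 observations")
  y <- as.numeric(y)
  if (length(y) != n) stop("length(y) must equal nrow(design)")
  err <- numeric(n)
  for (i in seq_len(n)) {
    mu <- colMeans(x[-i, , drop = FALSE])
    xi <- sweep(x[-i, , drop = FALSE], 2L, mu, "-")
    ybar <- mean(y[-i])
    yi <- y[-i] - ybar
    beta <- tryCatch(
      if (p >= n - 1L) {
        crossprod(xi, solve(tcrossprod(xi) + diag(lambda, n - 1L), yi))
      } else {
        solve(crossprod(xi) + diag(lambda, p), crossprod(xi, yi))
      },
      error = function(e) stop("singular per-fold system at fold ", i, ": ",
                               conditionMessage(e))
    )
    pred <- ybar + drop((x[i, ] - mu) %*% beta)
    err[i] <- (y[i] - pred)^2
  }
  mean(err)
}
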