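#' @export
print.adamant <- function(x, ...) {
  cat("Adaptive Mantel test (",
      if (x$method == "cv") "permutation" else "Gamma-approximated",
      " null, ", toupper(x$cv), "-tuned ridge penalty)\n", sep = "")
  cat("n =", x$n, "subjects, p =", x$p, "features, B =", x$B,
      "permutations\n")
  cat("selected penalty (observed data):", format(x$lambda_hat[1]), "\n")
  cat("score statistic T =", format(x$statistic), "\n")
  cat("p-value =", format(x$p.value), "\n")
  invisible(x)
}

#' @export
summary.adamant <- function(object, ...) {
  lh <- object$lambda_hat
  structure(
    list(fit = object,
         lambda_summary = summary(lh),
         boundary_frac = mean(abs(lh - object$grid$lambda_max) <
                                .Machine$double.eps^0.5),
         negative_frac = mean(lh < 0),
         inner_p_observed = object$inner_p[1]),
    class = "summary.adamant"
  )
}

#' @export
print.summary.adamant <- function(x, ...) {
  print(x$fit)
  cat("\nSelected penalties over the", x$fit$B + 1, "datasets:\n")
  print(x$lambda_summary)
  cat("at the grid maximum:", format(100 * x$boundary_frac, digits = 3),
      "% | negative:", format(100 * x$negative_frac, digits = 3), "%\n")
  cat("observed inner p-value:", format(x$inner_p_observed), "\n")
  invisible(x)
}

#' Ridge coefficients at the selected penalty
#'
#' Minimum-norm ridge solution `beta = X'(XX' + lambda I)^{-1} y` at the
#' penalty selected for the observed data, on the standardized scale of the
#' design.
#'
#' @param object an `"adamant"` fit.
#' @param ... unused.
#' @return numeric vector of length `p`.
#' @export
coef.adamant <- function(object, ...) {
  dcp <- object$decomp
  z <- drop(crossprod(dcp$u, object$y))
  denom <- dcp$d^2 + object$lambda_hat[1]
  beta <- drop(crossprod(object$std$x, dcp$u %*% (z / denom)))
  names(beta) <- colnames(object$std$x)
  beta
}

#' @export
fitted.adamant <- function(object, ...) {
  dcp <- object$decomp
  z <- drop(crossprod(dcp$u, object$y))
  w <- dcp$d^2 / (dcp$d^2 + object$lambda_hat[1])
  drop(dcp$u %*% (w * z))
}

#' @export
residuals.adamant <- function(object, ...) {
  object$y - fitted(object)
}

#' Predict from an adaptive Mantel fit
#'
#' Applies the stored standardization to `newdata` and multiplies by the
#' ridge coefficients at the selected penalty. Predictions are of the
#' centered response.
#'
#' @param object an `"adamant"` fit.
#' @param newdata numeric matrix with `p` columns.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.adamant <- function(object, newdata, ...) {
  if (missing(newdata)) return(fitted(object))
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) stop("newdata must have p = ", object$p,
                                      " columns")
  xs <- sweep(newdata, 2L, object$std$column_means, "-")
  xs <- sweep(xs, 2L, object$std$column_sds, "/")
  drop(xs %*% coef(object))
}

#' Plot an adaptive Mantel fit
#'
#' @param x an `"adamant"` fit.
#' @param which `"lambda"` for a histogram of the penalties selected across
#'   the observed and permuted responses, or `"cv"` for the observed-data
#'   cross-validation curve.
#' @param ... passed to the underlying plotting function.
#' @export
plot.adamant <- function(x, which = c("lambda", "cv"), ...) {
  which <- match.arg(which)
  if (which == "lambda") {
    graphics::hist(x$lambda_hat, xlab = "selected ridge penalty",
                   main = "Penalties selected across permutations", ...)
    graphics::abline(v = x$lambda_hat[1], col = 2, lwd = 2)
  } else {
    plot(x$curve, ...)
  }
  invisible(x)
}
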