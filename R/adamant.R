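#' Generate permuted copies of a response vector
#'
#' Draws `B` uniform random permutations of `y` (with replacement over the
#' symmetric group; distinctness is not enforced, the standard choice for
#' B far below n!). Index 0 — the original ordering — is by convention not
#' included in the output.
#'
#' @param y response vector.
#' @param B number of permutations.
#' @param seed optional integer seed for reproducibility.
#' @return an `n x B` matrix whose columns are permuted copies of `y`.
#' @export
permute_responses <- function(y, B, seed = NULL) {
  if (B < 1L) stop("B must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  matrix(vapply(seq_len(B), function(b) y[sample.int(n)], numeric(n)), n, B)
}

#' Fixed-penalty ridge Mantel permutation test
#'
#' The classical Mantel permutation test between the ridge-penalized linear
#' kernel of `x` and the outer product of `y`, at a single fixed penalty:
#' large values of `T(lambda) = y' H_lambda y` indicate association, and the
#' p-value is the fraction of datasets (original included) whose statistic is
#' at least the observed one, so `p >= 1/(B+1)`.
#'
#' @param x numeric design matrix (subjects in rows).
#' @param y numeric response vector.
#' @param lambda ridge penalty (admissible for the design spectrum).
#' @param B number of permutations.
#' @param seed optional integer seed.
#' @param scale scale the design columns (see [standardize_design()]).
#' @param clip clip negative score weights to zero.
#' @return Object of class `"mantel_ridge"`: list with `statistic` (observed
#'   T), `perm_statistics` (length `B`), `p.value`, `lambda`, `B`, `n`, `p`,
#'   `seed`.
#' @export
mantel_fixed <- function(x, y, lambda, B = 1000L, seed = NULL, scale = TRUE,
                         clip = TRUE) {
  std <- standardize_design(x, scale = scale)
  y <- as.numeric(y)
  if (length(y) != std$n) stop("length(y) must equal nrow(x)")
  yc <- y - mean(y)
  decomp <- design_svd(std)
  if (!is.null(seed)) set.seed(seed)
  Y <- unname(cbind(yc, permute_responses(yc, B)))
  Z2 <- crossprod(decomp$u, Y)^2
  w <- ridge_weights(decomp$d, lambda, clip = clip)
  stats <- drop(w %*% Z2)
  structure(
    list(statistic = stats[1], perm_statistics = stats[-1],
         p.value = mean(stats[1] <= stats), lambda = lambda, B = as.integer(B),
         n = std$n, p = std$p, seed = seed),
    class = "mantel_ridge"
  )
}

#' @export
print.mantel_ridge <- function(x, ...) {
  cat("Ridge Mantel permutation test (fixed penalty)\n")
  cat("lambda =", format(x$lambda), ", B =", x$B, "permutations\n")
  cat("T =", format(x$statistic), ", p-value =", format(x$p.value), "\n")
  invisible(x)
}

#' Fit a Gamma null by the method of moments
#'
#' Matches the Gamma shape and rate to the sample mean and variance
#' (denominator `n - 1`): `shape = mean^2/var`, `rate = mean/var`. Used to
#' smooth the permutation null of the score statistic, which is asymptotically
#' a mixture of chi-squared variables — a family the Gamma contains.
#'
#' @param sample positive numeric vector, length >= 2, non-degenerate.
#' @return Object of class `"gamma_null"`: list with `shape`, `rate`,
#'   `n_sample`.
#' @examples
#' fit <- gamma_mom_fit(rgamma(1000, shape = 3, rate = 2))
#' fit$shape / fit$rate  # equals the sample mean
#' @export
gamma_mom_fit <- function(sample) {
  sample <- as.numeric(sample)
  if (length(sample) < 2L) stop("need at least 2 values to fit a Gamma")
  m <- mean(sample)
  v <- stats::var(sample)
  if (!is.finite(v) || v <= 0 || m <= 0) {
    stop("degenerate sample (zero variance or non-positive mean); ",
         "Gamma method-of-moments fit is undefined")
  }
  structure(list(shape = m^2 / v, rate = m / v, n_sample = length(sample)),
            class = "gamma_null")
}

#' @export
print.gamma_null <- function(x, ...) {
  cat("Gamma null (method of moments): shape =", format(x$shape),
      ", rate =", format(x$rate), ", fitted on", x$n_sample, "values\n")
  invisible(x)
}

# Count-based inner p-values for one row of the cross-table: for every dataset
# b sharing the same selected penalty, the fraction of datasets c whose
# statistic is >= that of b (ties count toward 1, i.e. against rejection).
.upper_tail_fractions <- function(stats_row) {
  nB1 <- length(stats_row)
  (nB1 - rank(stats_row, ties.method = "min") + 1) / nB1
}

#' Adaptive Mantel test with cross-validated ridge penalty
#'
#' Tests for association between a high-dimensional design `x` and a
#' univariate response `y` with the ridge-penalized Mantel statistic, tuning
#' the penalty separately for the observed response and for each of `B`
#' permuted responses by GCV or LOOCV over a singular-value-thresholded grid
#' that may extend to negative penalties.
#'
#' For every dataset `b = 0, ..., B` (0 = observed) the selected penalty
#' `lambda_hat_b` defines a score statistic for every dataset `c`, giving a
#' `(B+1) x (B+1)` cross-table `T_cross[b, c] = T_c(lambda_hat_b)`. With
#' `method = "cv"` the inner p-value of dataset `b` is the fraction of
#' datasets whose statistic under `lambda_hat_b` is at least its own; with
#' `method = "gacv"` it is the upper-tail probability of a Gamma distribution
#' fitted by the method of moments to the `B` permutation statistics under
#' `lambda_hat_b`. Either way the reported p-value is the fraction of inner
#' p-values no greater than the observed one, so the test is a valid
#' permutation test whatever the tuning does.
#'
#' The design is decomposed once; all permutations share the spectrum, and
#' statistics are evaluated only once per distinct selected penalty, so the
#' whole procedure costs O(n^2 p + n^2 B).
#'
#' @param x numeric design matrix, subjects in rows.
#' @param y numeric response vector, length `nrow(x)`.
#' @param method `"cv"` (empirical inner p-values) or `"gacv"` (Gamma
#'   approximation).
#' @param cv tuning criterion, `"gcv"` or `"loocv"`.
#' @param tau singular-value threshold: `"none"`, `"q1"`, `"q2"`, or a
#'   numeric quantile probability in (0, 1).
#' @param M number of grid values.
#' @param B number of permutations.
#' @param lambda_max upper end of the penalty interval.
#' @param grid_scale,safe_lower_bound,lambda_min_rule passed to
#'   [lambda_grid()].
#' @param clip_weights clip negative score weights to zero (applied to the
#'   test statistic in all code paths; cross-validation always uses raw
#'   weights).
#' @param exclude_self with `method = "gacv"`, exclude each permutation from
#'   its own Gamma fitting sample (default `FALSE`: the B permutation
#'   statistics are used for every dataset).
#' @param scale scale the design columns.
#' @param keep_cross retain the full `(B+1) x (B+1)` statistic cross-table in
#'   the result.
#' @param seed optional integer seed governing the permutations.
#' @return Object of class `"adamant"`. Main elements: `p.value`;
#'   `statistic` (observed score statistic at its selected penalty);
#'   `lambda_hat` (length `B+1`, element 1 = observed data); `inner_p`
#'   (length `B+1`); `curve` (the observed-data `"cv_curve"`); `grid`;
#'   `method`, `cv`, `B`, `n`, `p`, `seed`; `T_cross` when `keep_cross`.
#' @examples
#' set.seed(1)
#' x <- make_design(40, 80, "compound_symmetric")
#' y <- make_response(x, "null", sigma = 1)
#' fit <- adamant(x, y, B = 99, M = 25, seed = 7)
#' fit$p.value
#' @export
adamant <- function(x, y, method = c("cv", "gacv"), cv = c("gcv", "loocv"),
                    tau = "none", M = 250L, B = 1000L, lambda_max = 1000,
                    grid_scale = c("linear", "log-positive"),
                    safe_lower_bound = FALSE,
                    lambda_min_rule = c("root", "ratio"),
                    clip_weights = TRUE, exclude_self = FALSE, scale = TRUE,
                    keep_cross = FALSE, seed = NULL) {
  method <- match.arg(method)
  cv <- match.arg(cv)
  cl <- match.call()
  B <- as.integer(B)
  if (B < 1L) stop("B must be at least 1")

  std <- standardize_design(x, scale = scale)
  y <- as.numeric(y)
  if (length(y) != std$n) {
    stop("dimension mismatch: length(y) = ", length(y), " but nrow(x) = ",
         std$n)
  }
  yc <- y - mean(y)
  decomp <- design_svd(std)
  grid <- lambda_grid(decomp, tau = tau, M = M, lambda_max = lambda_max,
                      grid_scale = grid_scale,
                      safe_lower_bound = safe_lower_bound,
                      lambda_min_rule = lambda_min_rule)

  if (!is.null(seed)) set.seed(seed)
  Y <- unname(cbind(yc, permute_responses(yc, B)))
  nB1 <- B + 1L

  cvres <- .cv_matrix(decomp, Y, grid, cv)
  if (any(!apply(is.finite(cvres$values), 2, any))) {
    stop("cross-validation failed: some dataset has no finite criterion ",
         "value on the grid")
  }
  sel <- apply(cvres$values, 2, which.min)
  lambda_hat <- grid$values[sel]

  # one weight vector per distinct selected penalty; statistics for all
  # datasets follow as a single matrix product against the squared projections
  ud <- sort(unique(sel))
  map <- match(sel, ud)
  Wc <- t(vapply(ud, function(k) {
    ridge_weights(decomp$d, grid$values[k], clip = clip_weights)
  }, numeric(decomp$r)))
  tmat <- Wc %*% cvres$Z2                       # distinct x (B+1)
  tdiag <- tmat[cbind(map, seq_len(nB1))]       # T_b(lambda_hat_b)

  inner_p <- numeric(nB1)
  if (method == "cv") {
    for (k in seq_along(ud)) {
      rows <- which(map == k)
      inner_p[rows] <- .upper_tail_fractions(tmat[k, ])[rows]
    }
  } else {
    fell_back <- FALSE
    for (k in seq_along(ud)) {
      rows <- which(map == k)
      null_sample <- tmat[k, -1]                # permutations c = 1..B
      fit <- tryCatch(gamma_mom_fit(null_sample), error = function(e) NULL)
      if (is.null(fit)) {
        fell_back <- TRUE
        inner_p[rows] <- .upper_tail_fractions(tmat[k, ])[rows]
        next
      }
      if (exclude_self) {
        for (b in rows) {
          fb <- if (b > 1L) {
            tryCatch(gamma_mom_fit(null_sample[-(b - 1L)]),
                     error = function(e) NULL)
          } else fit
          inner_p[b] <- if (is.null(fb)) {
            fell_back <- TRUE
            .upper_tail_fractions(tmat[k, ])[b]
          } else {
            stats::pgamma(tdiag[b], shape = fb$shape, rate = fb$rate,
                          lower.tail = FALSE)
          }
        }
      } else {
        inner_p[rows] <- stats::pgamma(tdiag[rows], shape = fit$shape,
                                       rate = fit$rate, lower.tail = FALSE)
      }
    }
    if (fell_back) {
      warning("degenerate permutation statistics for some selected penalty; ",
              "fell back to empirical inner p-values there")
    }
  }

  p_value <- mean(inner_p <= inner_p[1])

  curve <- structure(
    list(method = toupper(cv), grid = grid, values = cvres$values[, 1],
         lambda_hat = lambda_hat[1], index_hat = sel[1]),
    class = "cv_curve"
  )

  res <- list(
    p.value = p_value, statistic = tdiag[1], inner_p = inner_p,
    lambda_hat = lambda_hat, curve = curve, grid = grid,
    method = method, cv = cv, B = B, n = std$n, p = std$p, seed = seed,
    clip_weights = clip_weights, exclude_self = exclude_self,
    std = std, decomp = decomp, y = yc, call = cl
  )
  if (keep_cross) res$T_cross <- tmat[map, , drop = FALSE]
  class(res) <- "adamant"
  res
}
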