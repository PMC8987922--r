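# Deterministic substream seeds: one master seed keys every (replication,
# stream) pair so replications are independent and reproducible regardless of
# evaluation order. Constants are arbitrary distinct primes; all arithmetic
# stays below 2^31.
.substream_seed <- function(master, index, stream = 1L) {
  m <- 2147483629
  as.integer((((master %% m) * 48271) %% m + index * 1299709 +
                stream * 15485863) %% m)
}

#' Simulate a Gaussian design matrix
#'
#' Rows are i.i.d. p-variate normal with mean zero and either a
#' compound-symmetric covariance (unit variances, common correlation `rho`)
#' or a heteroskedastic diagonal covariance with variances `log(j + 1)` for
#' column j. The compound-symmetric draw uses the exact O(np) square-root
#' construction `X = a E + b rowSums(E)` (`a = sqrt(1 - rho)`,
#' `b = (sqrt(1 + (p-1) rho) - a)/p`), never forming the p-by-p covariance.
#'
#' @param n,p dimensions.
#' @param covariance `"compound_symmetric"` or `"heteroskedastic"`.
#' @param rho common correlation for the compound-symmetric structure; must
#'   lie in `(-1/(p-1), 1)`.
#' @param seed optional integer seed.
#' @return an `n x p` numeric matrix.
#' @export
make_design <- function(n, p,
                        covariance = c("compound_symmetric",
                                       "heteroskedastic"),
                        rho = 0.025, seed = NULL) {
  covariance <- match.arg(covariance)
  if (!is.null(seed)) set.seed(seed)
  e <- matrix(stats::rnorm(n * p), n, p)
  if (covariance == "compound_symmetric") {
    if (rho <= -1 / (p - 1) || rho >= 1) {
      stop("rho must lie in (-1/(p-1), 1)")
    }
    a <- sqrt(1 - rho)
    b <- (sqrt(1 + (p - 1) * rho) - a) / p
    a * e + b * rowSums(e)
  } else {
    sweep(e, 2L, sqrt(log(seq_len(p) + 1)), "*")
  }
}

#' Simulate a response vector
#'
#' Generates `y` under the null (`y = eps`), the fixed-effects alternative
#' (`y = X (xi 1_p) + eps`), or the random-effects alternative
#' (`y = X b + eps`, `b_j ~ N(0, sigma_b^2)`), with `eps ~ N(0, sigma^2)`.
#' The error vector is drawn before the coefficients, so the fixed-effects
#' model at `xi = 0` reproduces the null draw bit for bit under the same
#' seed.
#'
#' @param x design matrix (raw scale).
#' @param response `"null"`, `"fixed_effects"`, or `"random_effects"`.
#' @param xi fixed-effects coefficient value (each of the p coefficients).
#' @param sigma_b random-effects standard deviation.
#' @param sigma error standard deviation.
#' @param seed optional integer seed.
#' @return numeric vector of length `nrow(x)`.
#' @export
make_response <- function(x, response = c("null", "fixed_effects",
                                          "random_effects"),
                          xi = 3, sigma_b = 0.5, sigma = 1, seed = NULL) {
  response <- match.arg(response)
  if (sigma <= 0) stop("sigma must be positive")
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(x)
  n <- nrow(x)
  eps <- stats::rnorm(n, 0, sigma)
  switch(response,
         null = eps,
         fixed_effects = drop(x %*% rep(xi, ncol(x))) + eps,
         random_effects = drop(x %*% stats::rnorm(ncol(x), 0, sigma_b)) + eps)
}

#' Describe a Monte-Carlo experiment
#'
#' Bundles and validates every parameter of a rejection-rate experiment: the
#' design and response models, the test configuration, and the master seed.
#' Defaults follow the reference simulation design (n = 350, alpha = 0.05,
#' lambda_max = 1000, rho = 0.025, xi = 3, sigma_b = 0.50).
#'
#' @param n,p design dimensions.
#' @param covariance,rho see [make_design()].
#' @param response,xi,sigma_b,sigma see [make_response()].
#' @param S number of Monte-Carlo replications.
#' @param B,M,tau,lambda_max,cv,method test parameters, see [adamant()].
#' @param alpha nominal significance level.
#' @param seed master seed; every replication derives its own substreams.
#' @return Object of class `"simulation_config"` (a validated list).
#' @export
simulation_config <- function(n = 350L, p = 1000L,
                              covariance = c("compound_symmetric",
                                             "heteroskedastic"),
                              rho = 0.025,
                              response = c("null", "fixed_effects",
                                           "random_effects"),
                              xi = 3, sigma_b = 0.5, sigma = 1,
                              S = 500L, B = 1000L, M = 250L, tau = "none",
                              alpha = 0.05, lambda_max = 1000,
                              cv = c("gcv", "loocv"),
                              method = c("cv", "gacv"), seed = 1L) {
  covariance <- match.arg(covariance)
  response <- match.arg(response)
  cv <- match.arg(cv)
  method <- match.arg(method)
  if (sigma <= 0) stop("sigma must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (S < 1L || B < 1L || M < 1L) stop("S, B and M must be positive")
  if (covariance == "compound_symmetric" &&
      (rho <= -1 / (p - 1) || rho >= 1)) {
    stop("rho must lie in (-1/(p-1), 1)")
  }
  structure(
    list(n = as.integer(n), p = as.integer(p), covariance = covariance,
         rho = rho, response = response, xi = xi, sigma_b = sigma_b,
         sigma = sigma, S = as.integer(S), B = as.integer(B),
         M = as.integer(M), tau = tau, alpha = alpha,
         lambda_max = lambda_max, cv = cv, method = method,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation: n =", x$n, ", p =", x$p, ",", x$covariance,
      "design,", x$response, "response, sigma =", x$sigma, "\n")
  cat("test:", toupper(x$method), "/", toupper(x$cv), ", tau =",
      as.character(x$tau), ", B =", x$B, ", M =", x$M, ", S =", x$S,
      "replications, seed =", x$seed, "\n")
  invisible(x)
}

#' Monte-Carlo rejection-rate experiment
#'
#' Runs `S` independent replications of (design, response, adaptive Mantel
#' test) under a [simulation_config()] and returns the empirical rejection
#' rate at level `alpha` — the Type-I error under the null, the power under
#' an alternative — together with its Monte-Carlo standard error and the
#' distribution of selected penalties. Replications that fail (e.g. a
#' degenerate draw) are redrawn under a shifted substream, at most twice,
#' and counted.
#'
#' @param config a [simulation_config()].
#' @param progress print a dot every 10 replications.
#' @return Object of class `"rejection_summary"`: list with `rate`, `S`,
#'   `S_effective`, `mc_se`, `alpha`, `p_values` (length `S`, `NA` for failed
#'   replications), `lambda_hat_mean` (pooled over all datasets of all
#'   replications), `lambda_hat_rep_mean` (per-replication means),
#'   `lambda_hat_all` (pooled vector), `failures`, `config`.
#' @export
rejection_rate_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  S <- config$S
  p_values <- rep(NA_real_, S)
  rep_mean <- rep(NA_real_, S)
  pooled <- vector("list", S)
  failures <- 0L
  for (s in seq_len(S)) {
    fit <- NULL
    for (attempt in 0:2) {
      data_seed <- .substream_seed(config$seed, s, 1L + 10L * attempt)
      test_seed <- .substream_seed(config$seed, s, 2L + 10L * attempt)
      fit <- tryCatch({
        x <- make_design(config$n, config$p, config$covariance,
                         rho = config$rho, seed = data_seed)
        y <- make_response(x, config$response, xi = config$xi,
                           sigma_b = config$sigma_b, sigma = config$sigma)
        adamant(x, y, method = config$method, cv = config$cv,
                tau = config$tau, M = config$M, B = config$B,
                lambda_max = config$lambda_max, seed = test_seed)
      }, error = function(e) {
        warning("replication ", s, " failed (", conditionMessage(e),
                "); redrawing", call. = FALSE)
        NULL
      })
      if (!is.null(fit)) break
      failures <- failures + 1L
    }
    if (!is.null(fit)) {
      p_values[s] <- fit$p.value
      rep_mean[s] <- mean(fit$lambda_hat)
      pooled[[s]] <- fit$lambda_hat
    }
    if (progress && s %% 10L == 0L) cat(".")
  }
  if (progress) cat("\n")
  ok <- !is.na(p_values)
  s_eff <- sum(ok)
  if (s_eff == 0L) stop("every replication failed")
  rate <- mean(p_values[ok] <= config$alpha)
  pooled <- unlist(pooled)
  structure(
    list(rate = rate, S = S, S_effective = s_eff,
         mc_se = sqrt(rate * (1 - rate) / s_eff), alpha = config$alpha,
         p_values = p_values, lambda_hat_mean = mean(pooled),
         lambda_hat_rep_mean = rep_mean, lambda_hat_all = pooled,
         failures = failures, config = config),
    class = "rejection_summary"
  )
}

#' @export
print.rejection_summary <- function(x, ...) {
  print(x$config)
  cat("rejection rate at alpha =", x$alpha, ":", format(x$rate),
      "(MC se", format(x$mc_se, digits = 3), ") over", x$S_effective,
      "replications\n")
  cat("mean selected penalty (pooled):", format(x$lambda_hat_mean), "\n")
  if (x$failures > 0L) cat(x$failures, "replication failure(s) redrawn\n")
  invisible(x)
}

#' Noise-added empirical power across penalties
#'
#' Starting from a base response, each replication adds fresh Gaussian noise
#' (`y_s = y_base + eps_s`) and computes the fixed-penalty Mantel p-value at
#' every penalty in `lambda` (or, if `lambda` is `NULL`, the full adaptive
#' test with criterion `cv`). The empirical power at each penalty is the
#' fraction of replications rejecting at `alpha`; the mean of -log10(p) is
#' returned alongside as a graded summary.
#'
#' @param x design matrix.
#' @param y_base base response vector.
#' @param lambda numeric vector of penalties, or `NULL` to tune by
#'   cross-validation each replication.
#' @param cv criterion used when `lambda` is `NULL`.
#' @param S number of noise replications.
#' @param alpha significance level.
#' @param noise_sigma standard deviation of the added noise.
#' @param B permutations per test.
#' @param seed master seed.
#' @param ... further arguments to [adamant()] when tuning.
#' @return data frame with columns `lambda` (NA when tuned), `power`,
#'   `mean_neglog10_p`.
#' @export
noise_added_power <- function(x, y_base, lambda = NULL, cv = "gcv", S = 100L,
                              alpha = 0.05, noise_sigma = 1, B = 200L,
                              seed = 1L, ...) {
  y_base <- as.numeric(y_base)
  n <- length(y_base)
  if (nrow(as.matrix(x)) != n) stop("length(y_base) must equal nrow(x)")
  if (is.null(lambda)) {
    pv <- vapply(seq_len(S), function(s) {
      set.seed(.substream_seed(seed, s, 1L))
      ys <- y_base + stats::rnorm(n, 0, noise_sigma)
      adamant(x, ys, cv = cv, B = B,
              seed = .substream_seed(seed, s, 2L), ...)$p.value
    }, numeric(1))
    return(data.frame(lambda = NA_real_, power = mean(pv <= alpha),
                      mean_neglog10_p = mean(-log10(pv))))
  }
  # fixed penalties share the decomposition across replications and penalties
  std <- standardize_design(x)
  decomp <- design_svd(std)
  W <- t(vapply(lambda, function(l) ridge_weights(decomp$d, l),
                numeric(decomp$r)))
  pv <- matrix(NA_real_, S, length(lambda))
  for (s in seq_len(S)) {
    set.seed(.substream_seed(seed, s, 1L))
    ys <- y_base + stats::rnorm(n, 0, noise_sigma)
    ys <- ys - mean(ys)
    set.seed(.substream_seed(seed, s, 2L))
    Y <- unname(cbind(ys, permute_responses(ys, B)))
    tmat <- W %*% crossprod(decomp$u, Y)^2
    pv[s, ] <- rowMeans(tmat >= tmat[, 1])
  }
  data.frame(lambda = lambda, power = colMeans(pv <= alpha),
             mean_neglog10_p = colMeans(-log10(pv)))
}
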