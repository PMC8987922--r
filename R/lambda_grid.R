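#' Threshold small singular values
#'
#' Sets singular values strictly below `tau` to zero, keeping the rest. The
#' thresholded spectrum defines the most negative admissible ridge penalty:
#' allowing a fraction of near-zero singular values to be ignored widens the
#' negative part of the penalty interval.
#'
#' @param d non-negative singular values.
#' @param tau threshold, `tau >= 0`.
#' @return vector of the same length with entries below `tau` zeroed.
#' @examples
#' adjusted_singular_values(c(5, 3, 1), 3)  # c(5, 3, 0)
#' @export
adjusted_singular_values <- function(d, tau) {
  if (tau < 0) stop("tau must be non-negative")
  ifelse(d >= tau, d, 0)
}

#' Smallest positive adjusted singular value
#'
#' @param d_adjusted output of [adjusted_singular_values()].
#' @return smallest strictly positive entry.
#' @export
ell_min <- function(d_adjusted) {
  pos <- d_adjusted[d_adjusted > 0]
  if (length(pos) == 0L) {
    stop("no positive adjusted singular values; threshold removed the whole ",
         "spectrum")
  }
  min(pos)
}

#' Quantile of the singular values used as threshold
#'
#' First quartile (`"q1"`), median (`"q2"`), or an arbitrary probability in
#' (0, 1); computed with linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param d singular values (non-empty).
#' @param which `"q1"`, `"q2"`, or a numeric probability in (0, 1).
#' @return scalar threshold.
#' @examples
#' quantile_threshold(c(4, 2), "q2")  # 3
#' @export
quantile_threshold <- function(d, which) {
  if (length(d) == 0L) stop("empty singular value vector")
  prob <- if (is.numeric(which)) {
    if (which <= 0 || which >= 1) stop("quantile probability must be in (0, 1)")
    which
  } else {
    switch(tolower(as.character(which)),
           q1 = 0.25, q2 = 0.5,
           stop("unknown quantile label: ", which))
  }
  unname(stats::quantile(d, probs = prob, type = 7))
}

#' Lower end of the admissible penalty interval
#'
#' `lambda_min = -(sqrt(p/n) - 1)^2 * ell_min` (the default `"root"` rule), or
#' `-(p/n - 1)^2 * ell_min` under the `"ratio"` rule; zero when `p = n`. The
#' negative lower bound is what admits negative ridge penalties in
#' high-dimensional designs.
#'
#' @param ell_min smallest positive (thresholded) singular value.
#' @param n,p design dimensions.
#' @param rule `"root"` (default) or `"ratio"`.
#' @return scalar, `<= 0`.
#' @export
lambda_min <- function(ell_min, n, p, rule = c("root", "ratio")) {
  rule <- match.arg(rule)
  if (n < 1 || p < 1) stop("n and p must be positive")
  fac <- if (rule == "root") (sqrt(p / n) - 1)^2 else (p / n - 1)^2
  -fac * ell_min
}

#' Candidate grid of ridge penalties
#'
#' Builds the `M`-point search grid on the half-open interval
#' `(lambda_min, lambda_max]`, where `lambda_min` comes from singular-value
#' thresholding (see [lambda_min()]). Grid points landing within the exclusion
#' radius of any `-d_j^2` (where the penalized system is singular), or on
#' exactly 0 when the fitted smoother interpolates (`r >= n - 1`: the rank
#' plus the intercept exhaust the sample, making the cross-validation
#' criteria 0/0), are flagged invalid and skipped by the search.
#'
#' @param decomp a [design_svd()] decomposition.
#' @param tau `"none"`, `"q1"`, `"q2"`, or a numeric quantile probability in
#'   (0, 1) for the singular-value threshold.
#' @param M number of candidate values (>= 2).
#' @param lambda_max upper end of the interval (default 1000).
#' @param grid_scale `"linear"` (default) for equally spaced values, or
#'   `"log-positive"` to log-space the positive part of the grid.
#' @param safe_lower_bound if `TRUE`, replace `lambda_min` by
#'   `-d_(1)^2 + eps` with `d_(1)` the smallest positive singular value and
#'   `eps` the machine tolerance, guaranteeing all raw weights stay positive.
#' @param lambda_min_rule passed to [lambda_min()].
#' @return Object of class `"lambda_grid"`: list with `tau`, `tau_quantile`,
#'   `ell_min`, `lambda_min`, `lambda_max`, `values` (strictly increasing,
#'   length `M`), `valid` (logical mask), `M`, `eps_singular`, and the
#'   decomposition dimensions `n`, `p`, `r`.
#' @export
lambda_grid <- function(decomp, tau = "none", M = 250L, lambda_max = 1000,
                        grid_scale = c("linear", "log-positive"),
                        safe_lower_bound = FALSE,
                        lambda_min_rule = c("root", "ratio")) {
  stopifnot(inherits(decomp, "design_svd"))
  grid_scale <- match.arg(grid_scale)
  M <- as.integer(M)
  if (M < 2L) stop("M must be at least 2")
  d <- decomp$d

  if (is.numeric(tau)) {
    tau_val <- quantile_threshold(d, tau)
    tau_label <- paste0("custom(", format(tau), ")")
  } else if (identical(tolower(as.character(tau)), "none")) {
    tau_val <- 0
    tau_label <- "none"
  } else {
    tau_val <- quantile_threshold(d, tau)
    tau_label <- toupper(as.character(tau))
  }

  lmin <- if (safe_lower_bound) {
    -min(d[d > 0])^2 + .Machine$double.eps
  } else {
    lambda_min(ell_min(adjusted_singular_values(d, tau_val)),
               decomp$n, decomp$p, rule = lambda_min_rule)
  }
  if (lambda_max <= lmin) stop("lambda_max must exceed lambda_min = ",
                               format(lmin))

  values <- if (grid_scale == "linear") {
    lmin + seq_len(M) * (lambda_max - lmin) / M
  } else {
    .log_positive_grid(lmin, lambda_max, M)
  }
  values[M] <- lambda_max  # the closed upper endpoint, exactly

  eps <- .eps_singular(d)
  d2 <- d^2
  valid <- vapply(values, function(v) {
    if (min(abs(d2 + v)) < eps) return(FALSE)
    if (decomp$r >= decomp$n - 1L && abs(v) < eps) return(FALSE)
    TRUE
  }, logical(1))
  if (!any(valid)) stop("all grid values are invalid (singular penalties)")

  structure(
    list(tau = tau_val, tau_quantile = tau_label, ell_min = ell_min(
           adjusted_singular_values(d, tau_val)),
         lambda_min = lmin, lambda_max = lambda_max, values = values,
         valid = valid, M = M, eps_singular = eps,
         n = decomp$n, p = decomp$p, r = decomp$r),
    class = "lambda_grid"
  )
}

# Log-spaced positive part; any negative-to-zero stretch keeps linear spacing
# with a proportional share of the M points.
.log_positive_grid <- function(lmin, lmax, M) {
  if (lmax <= 0) stop("log-positive grid requires lambda_max > 0")
  m_neg <- if (lmin < 0) max(1L, round(M * (0 - lmin) / (lmax - lmin))) else 0L
  m_neg <- min(m_neg, M - 1L)
  m_pos <- M - m_neg
  neg <- if (m_neg > 0L) lmin + seq_len(m_neg) * (0 - lmin) / m_neg else numeric(0)
  lo <- lmax * 1e-6
  pos <- exp(seq(log(lo), log(lmax), length.out = m_pos))
  c(neg, pos)
}

#' @export
print.lambda_grid <- function(x, ...) {
  cat("Ridge penalty grid: M =", x$M, "on (",
      format(x$lambda_min, digits = 6), ",", format(x$lambda_max), "]\n")
  cat("threshold tau =", format(x$tau, digits = 6), "(", x$tau_quantile,
      "), ell_min =", format(x$ell_min, digits = 6), "\n")
  if (!all(x$valid)) cat(sum(!x$valid), "value(s) masked as singular\n")
  invisible(x)
}
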