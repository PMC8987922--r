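test_that("permutations are seeded, reproducible and uniform", {
  y <- c(2.5, -1, 0, 4)
  p1 <- permute_responses(y, 25, seed = 99)
  p2 <- permute_responses(y, 25, seed = 99)
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(4L, 25L))
  expect_equal(apply(p1, 2, sort), matrix(sort(y), 4, 25))
  expect_equal(permute_responses(5, 10, seed = 1), matrix(5, 1, 10))
  expect_error(permute_responses(y, 0), "at least 1")

  # each of the 4! orderings appears with frequency 1/24 (3 SE multinomial)
  pm <- permute_responses(1:4, 6000, seed = 7)
  keys <- apply(pm, 2, paste, collapse = "")
  freq <- as.numeric(table(keys)) / 6000
  expect_length(freq, 24)
  se <- sqrt((1 / 24) * (23 / 24) / 6000)
  expect_true(all(abs(freq - 1 / 24) < 3 * se))
})

test_that("fixed-penalty Mantel p-value matches exhaustive enumeration", {
  set.seed(101)
  x <- matrix(rnorm(4 * 6), 4, 6)
  y <- rnorm(4)
  lam <- 2
  std <- standardize_design(x)
  dcp <- design_svd(std)
  yc <- y - mean(y)
  t_obs <- score_statistic(dcp, yc, lam)$statistic
  perms <- all_perms(4)
  t_all <- apply(perms, 1, function(pp) {
    score_statistic(dcp, yc[pp], lam)$statistic
  })
  p_exact <- mean(t_obs <= t_all)  # includes the identity permutation

  fit <- mantel_fixed(x, y, lam, B = 10000, seed = 5)
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(fit$p.value - p_exact), 3 * se + 2 / 10001)
  expect_gte(fit$p.value, 1 / 10001)
})

test_that("degenerate responses give p = 1", {
  set.seed(102)
  x <- matrix(rnorm(10 * 8), 10, 8)
  y <- rep(3, 10)
  fit <- mantel_fixed(x, y, 1, B = 50, seed = 1)
  expect_equal(fit$p.value, 1)
  expect_equal(fit$statistic, 0)
  fit2 <- adamant(x, y, B = 50, M = 20, seed = 1)
  expect_equal(fit2$p.value, 1)
  expect_true(all(fit2$inner_p == 1))
})

test_that("adamant is deterministic given a seed and reports valid lattices", {
  set.seed(103)
  x <- matrix(rnorm(20 * 35), 20, 35)
  y <- rnorm(20)
  f1 <- adamant(x, y, B = 60, M = 25, seed = 11)
  f2 <- adamant(x, y, B = 60, M = 25, seed = 11)
  expect_identical(f1$p.value, f2$p.value)
  expect_identical(f1$lambda_hat, f2$lambda_hat)
  expect_identical(f1$inner_p, f2$inner_p)
  # CV inner p-values and the outer p-value live on the 1/(B+1) lattice
  lattice <- f1$inner_p * 61
  expect_equal(lattice, round(lattice), tolerance = 1e-9)
  expect_equal(f1$p.value * 61, round(f1$p.value * 61), tolerance = 1e-9)
  expect_gte(f1$p.value, 1 / 61)
  # inner p of the observed data equals the fixed-penalty test at lambda_hat
  mf <- mantel_fixed(x, y, f1$lambda_hat[1], B = 60, seed = 11)
  expect_equal(f1$inner_p[1], mf$p.value)
})

test_that("cross-table matches naive dense evaluation (n=12, p=20, B=30)", {
  set.seed(104)
  x <- matrix(rnorm(12 * 20), 12, 20)
  y <- rnorm(12)
  B <- 30
  fit <- adamant(x, y, B = B, M = 15, lambda_max = 100, seed = 21,
                 keep_cross = TRUE)

  # independent naive path: dense eigendecomposition per dataset, explicit
  # GCV minimization, explicit statistic for every (b, c) pair
  std <- standardize_design(x)
  yc <- y - mean(y)
  set.seed(21)
  Y <- cbind(yc, permute_responses(yc, B))
  eg <- eigen(tcrossprod(std$x), symmetric = TRUE)
  keep <- sqrt(pmax(eg$values, 0)) >
    max(sqrt(pmax(eg$values, 0))) * 1e-12 * 20
  d2 <- eg$values[keep]
  u <- eg$vectors[, keep, drop = FALSE]
  g <- fit$grid
  naive_sel <- integer(B + 1)
  for (b in seq_len(B + 1)) {
    crit <- rep(Inf, g$M)
    for (m in which(g$valid)) {
      h <- u %*% ((d2 / (d2 + g$values[m])) * t(u))
      r <- Y[, b] - drop(h %*% Y[, b])
      den <- 1 - (1 + sum(diag(h))) / 12  # intercept df included
      if (abs(den) < 1e-10) next
      crit[m] <- mean((r / den)^2)
    }
    naive_sel[b] <- which.min(crit)
  }
  expect_equal(g$values[naive_sel], fit$lambda_hat, tolerance = 1e-10)
  naive_cross <- matrix(NA_real_, B + 1, B + 1)
  for (b in seq_len(B + 1)) {
    w <- pmax(d2 / (d2 + g$values[naive_sel[b]]), 0)
    for (cc in seq_len(B + 1)) {
      z <- drop(crossprod(u, Y[, cc]))
      naive_cross[b, cc] <- sum(w * z^2)
    }
  }
  expect_equal(unname(fit$T_cross), naive_cross, tolerance = 1e-8)
})

test_that("Gamma method-of-moments fit matches sample moments exactly", {
  s <- c(1, 2, 3)  # mean 2, var 1
  fit <- gamma_mom_fit(s)
  expect_equal(fit$shape / fit$rate, mean(s), tolerance = 1e-10)
  expect_equal(fit$shape / fit$rate^2, var(s), tolerance = 1e-10)
  fit2 <- gamma_mom_fit(c(0.5, 2, 3.5))  # mean 2, var 2.25
  expect_equal(fit2$shape, 4 / 2.25, tolerance = 1e-12)
  expect_equal(fit2$rate, 2 / 2.25, tolerance = 1e-12)
  expect_error(gamma_mom_fit(rep(2, 10)), "degenerate")
  expect_error(gamma_mom_fit(1), "at least 2")
})

test_that("Gamma parameters are recovered from synthetic draws", {
  set.seed(105)
  draws <- rgamma(1e5, shape = 3, rate = 2)
  fit <- gamma_mom_fit(draws)
  boot <- replicate(200, {
    i <- sample.int(1e5, replace = TRUE)
    gamma_mom_fit(draws[i])$shape
  })
  expect_lt(abs(fit$shape - 3), 3 * sd(boot))
  expect_equal(fit$shape / fit$rate, mean(draws), tolerance = 1e-10)
  expect_equal(fit$shape / fit$rate^2, var(draws), tolerance = 1e-10)
  # upper-tail probability at the sample maximum is below 1
  expect_lt(pgamma(max(draws), fit$shape, fit$rate, lower.tail = FALSE), 1)
})

test_that("Gamma-approximated test agrees with its permutation scaffold", {
  set.seed(106)
  x <- matrix(rnorm(25 * 40), 25, 40)
  y <- rnorm(25)
  fg <- adamant(x, y, method = "gacv", B = 80, M = 20, seed = 31)
  fc <- adamant(x, y, method = "cv", B = 80, M = 20, seed = 31)
  # same permutations, same tuning: identical selected penalties
  expect_identical(fg$lambda_hat, fc$lambda_hat)
  # the outer p-value is a lattice quantity for both methods
  expect_equal(fg$p.value * 81, round(fg$p.value * 81), tolerance = 1e-9)
  expect_gte(fg$p.value, 1 / 81)
  expect_true(all(fg$inner_p >= 0 & fg$inner_p <= 1))
  # exclude_self changes at most the Gamma samples, not the machinery
  fe <- adamant(x, y, method = "gacv", B = 80, M = 20, seed = 31,
                exclude_self = TRUE)
  expect_identical(fe$lambda_hat, fg$lambda_hat)
})

test_that("a strong fixed-effects signal is detected, a null is not", {
  x <- make_design(60, 150, "compound_symmetric", seed = 41)
  y_alt <- make_response(x, "fixed_effects", xi = 3, sigma = 1, seed = 42)
  f_alt <- adamant(x, y_alt, B = 199, M = 40, seed = 43)
  expect_lte(f_alt$p.value, 0.01)
  y_null <- make_response(x, "null", sigma = 1, seed = 44)
  f_null <- adamant(x, y_null, B = 199, M = 40, seed = 45)
  expect_gt(f_null$p.value, 0.05)
})

test_that("fixed-penalty permutation p-values are calibrated under the null", {
  set.seed(107)
  rejections <- vapply(1:400, function(s) {
    x <- matrix(rnorm(25 * 35), 25, 35)
    y <- rnorm(25)
    mantel_fixed(x, y, lambda = 5, B = 79)$p.value <= 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("the Gamma variant is at least as powerful as the empirical one", {
  # matched weak-signal settings; dominance asserted up to Monte-Carlo noise
  S <- 60
  p_cv <- numeric(S)
  p_ga <- numeric(S)
  for (s in seq_len(S)) {
    x <- make_design(40, 80, "compound_symmetric", seed = 5000 + s)
    y <- make_response(x, "fixed_effects", xi = 0.05, sigma = 1,
                       seed = 6000 + s)
    p_cv[s] <- adamant(x, y, method = "cv", B = 99, M = 25,
                       seed = 7000 + s)$p.value
    p_ga[s] <- adamant(x, y, method = "gacv", B = 99, M = 25,
                       seed = 7000 + s)$p.value
  }
  pow_cv <- mean(p_cv <= 0.05)
  pow_ga <- mean(p_ga <= 0.05)
  mc_se <- sqrt(pmax(pow_cv, 0.05) * (1 - pmax(pow_cv, 0.05)) / S)
  expect_gte(pow_ga, pow_cv - 2 * mc_se)
})
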