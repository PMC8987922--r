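---
title: "Adaptive Mantel testing with ridge-penalized kernels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive Mantel testing with ridge-penalized kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(adamant)
```

## The testing problem

In imaging genetics and similar screening problems one asks whether a
high-dimensional block of features `X` (n subjects by p SNP dosages,
methylation probes, expression values, ...) is associated *as a set* with a
univariate quantitative response `y` (an EEG coherence summary, a clinical
measurement). Feature-by-feature testing is underpowered when effects are
small and spread out; kernel association tests instead compare
subject-by-subject similarity in `X` with similarity in `y`.

The Mantel statistic for the ridge-penalized linear kernel is

```
T(lambda) = tr(H_lambda y y') = y' H_lambda y,
H_lambda  = X (X'X + lambda I_p)^{-1} X',
```

which in the spectral coordinates of the standardized design
`X = U D V'` becomes a weighted sum of squared response projections,

```
T(lambda) = sum_j w_j(lambda) z_j^2,   w_j = d_j^2 / (d_j^2 + lambda),
z = U' y.
```

The penalty indexes a family of score tests: at `lambda = 0` (with the
pseudoinverse convention for zero singular values) `T` is the fixed-effects
score statistic `sum z_j^2`, equally weighting every design direction; as
`lambda -> Inf`, `lambda * T(lambda)` converges to the variance-component
statistic `sum d_j^2 z_j^2`, which up-weights high-variance directions. A
*negative* admissible penalty (`lambda > -d_r^2`) gives weights above 1 on
low-variance directions — useful when the signal hides there, a regime that
genuinely occurs in high-dimensional data where the cross-validated optimum
of ridge prediction error can be negative.

## Choosing the penalty, and paying for the choice

The selected penalty should be data-driven, but re-using the data for
selection and testing inflates the Type-I error unless the selection is
repeated under the null. The adaptive Mantel test does exactly that:

1. Standardize `X` (centering and scaling columns) and center `y`; decompose
   `X` once (`design_svd()`; for p > n the n-by-n Gram route keeps the cost
   at O(n^2 p)).
2. Build the candidate grid: `M` values on `(lambda_min, lambda_max]`
   (`lambda_grid()`). The lower end comes from singular-value thresholding:
   with threshold `tau` (none, Q1 or the median of the singular values),
   `ell_min` is the smallest surviving singular value and
   `lambda_min = -(sqrt(p/n) - 1)^2 * ell_min`, negative whenever `p != n`.
3. For the observed response and each of `B` permuted responses, select
   `lambda_hat_b` by minimizing GCV or LOOCV over the grid, then evaluate the
   statistic cross-table `T_cross[b, c] = T_c(lambda_hat_b)`.
4. Convert to inner p-values `P_b` — empirically (the fraction of datasets
   whose statistic under `lambda_hat_b` is at least dataset b's own;
   `method = "cv"`), or from a Gamma null fitted by the method of moments to
   the `B` permutation statistics under `lambda_hat_b` (`method = "gacv"`,
   a smooth stand-in for the asymptotic mixture-of-chi-squared null).
5. The reported p-value is the fraction of `P_b <= P_0`. Because the
   *entire* procedure, selection included, is recomputed for every
   permutation, the test is exact up to Monte-Carlo error whatever the
   tuning does; the Gamma variant buys power by grading the inner p-values
   more finely than the 1/(B+1) lattice.

All statistics for all B+1 datasets under one penalty come from a single
weight-vector-by-squared-projection product, and weights are computed once
per *distinct* selected penalty, so a full test at n = 350, p = 1000,
B = 1000 takes a few hundred milliseconds.

## Cross-validation details

GCV and LOOCV are computed spectrally, with no refitting:

```
gcv(lambda)   = mean_i ( (y_i - yhat_i) / (1 - tr(S_lambda)/n) )^2
loocv(lambda) = mean_i ( (y_i - yhat_i) / (1 - [S_lambda]_ii) )^2
```

Two numerical choices deserve explanation.

**The smoother includes the intercept.** The fitting procedure removes the
mean of `y` and the column means of `X` before the penalized fit, so the
smoother actually applied to the raw response is `S = J/n + H_lambda`
(an unpenalized intercept plus the ridge on centered columns; the two pieces
are orthogonal). Its degrees of freedom are `1 + sum_j w_j` and its
leverages `1/n + sum_j U_ij^2 w_j`, and those are what the denominators
use. This accounting matters: a centered design has rank `n - 1` and the
centered response lies entirely in its column space, so without the
intercept's degree of freedom the residual vanishes as `lambda -> 0+` while
the denominator stays bounded away from zero, and the criterion would
spuriously favor near-interpolation. With it, `lambda = 0` on a
rank-(n-1) centered design is a genuine 0/0 interpolation point — the grid
masks it — and under a pure-noise response the criterion correctly pushes
the penalty to the top of the grid (the best null predictor is 0). The
LOOCV shortcut remains *exact*: it equals n explicit leave-one-out refits of
the intercept-plus-ridge model, which the test suite verifies to 1e-8,
including at admissible negative penalties.

**Raw weights for prediction, clipped weights for testing.** Cross-validation
scores genuine ridge predictions, so it uses `w_j = d_j^2/(d_j^2 + lambda)`
unclipped. The test statistic must remain a non-negative mixture of
chi-squared components, so weights that would be negative (possible only for
inadmissibly negative penalties) are clipped to zero
(`w~_j = max(w_j, 0)`), in both the permutation and the Gamma code paths;
`clip_weights = FALSE` switches this off.

Other numerical choices: rank is cut off on the eigenvalue scale
(`d_j^2 <= max(d)^2 * 1e-12 * max(n, p)`), because the Gram-route
eigenvalues are accurate to machine precision times the spectral norm while
their square roots are not; grid values within `1e-8 * d_1^2` of any
`-d_j^2` are masked as singular; invalid grid entries carry an `Inf`
sentinel rather than being dropped, so curves keep length `M` for plotting
and audit; CV ties break toward the smallest penalty; the grid is linearly
spaced by default (`grid_scale = "log-positive"` log-spaces the positive
part); the upper endpoint `lambda_max` (default 1000) must be supplied
because the admissible interval is half-open to the right.

## Defaults and tunable parameters

| parameter | default | meaning |
|---|---|---|
| `tau` | `"none"` | singular-value threshold (quantile) defining `lambda_min`; `"q1"`/`"q2"` allow more negative penalties |
| `M` | 250 | grid resolution |
| `B` | 1000 | permutations; p-values live on the 1/(B+1) lattice |
| `lambda_max` | 1000 | top of the penalty interval |
| `method` | `"cv"` | `"gacv"` fits the Gamma null for finer inner p-values |
| `cv` | `"gcv"` | `"loocv"` is equivalent in practice and costlier (O(n^2) per grid value per dataset) |
| `exclude_self` | `FALSE` | with `"gacv"`, whether permutation b is excluded from its own Gamma sample; the B-sample version is used for every dataset (O(1/B) self-inclusion bias at most) |

The `lambda_min` formula uses the square-root form
`-(sqrt(p/n) - 1)^2 * ell_min` (`lambda_min_rule = "ratio"` gives
`-(p/n - 1)^2 * ell_min`); `ell_min` is computed on singular values, not
eigenvalues. Quantiles use linear interpolation between order statistics.
`safe_lower_bound = TRUE` instead uses `-d_(1)^2 + eps` (smallest positive
singular value, machine epsilon), the bound that keeps every raw weight
positive.

## What the simulation machinery emulates

`make_design()` draws i.i.d. Gaussian rows with either a compound-symmetric
covariance (unit variances, common correlation `rho = 0.025` by default,
drawn by the exact O(np) square-root construction valid on the whole range
`rho` in `(-1/(p-1), 1)`) or a heteroskedastic diagonal covariance with
variances `log(j + 1)`. `make_response()` generates the null (`y = eps`),
the dense fixed-effects alternative (`beta = xi 1_p`, `xi = 3`), or the
random-effects alternative (`b_j ~ N(0, sigma_b^2)`, `sigma_b = 0.50`);
the error vector is drawn before the coefficients so the `xi = 0` model is
bit-identical to the null under the same seed. These are the reference
study conditions (n = 350, p in {500, 1000}, alpha = 0.05).

`rejection_rate_experiment()` runs S independent replications, standardizes
`X` inside each (the reference design is population-standardized, but real
data are not, so the pipeline is exercised uniformly), and reports the
rejection rate with its Monte-Carlo standard error plus the pooled
distribution of selected penalties. Each replication derives independent
data and permutation substreams from the master seed (distinct-prime keyed),
so results are reproducible and order-independent; failed replications are
redrawn under a shifted substream, at most twice, and counted.
`noise_added_power()` implements the fixed-penalty power heat-map recipe:
`y_s = y_base + eps_s` with fresh noise per replication, power per penalty
as the rejection fraction.

What the generator does *not* emulate about real data: discreteness and
allele-frequency spectra of genotype codes, linkage-disequilibrium block
structure, population stratification, heavy-tailed or heteroskedastic
responses, and missingness (the PLINK reader's mean imputation is exercised
only on synthetic files). Passing the Monte-Carlo checks therefore
demonstrates calibration and power under Gaussian designs with the stated
covariances, not robustness to those real-data features.

## Reference problem sizes

The package's reference checks (`scripts/acceptance.R`, and the acceptance
test file) run the study conditions at desk scale: S = 200 replications,
B = 300 permutations, M = 100 grid values, n = 350 — sizes chosen so the
whole battery completes in minutes on one core while keeping the
Monte-Carlo standard error of a rejection rate near 0.015. Power entries in
the mid-range are additionally sensitive to the grid construction (spacing,
`lambda_max`, threshold), which is why the package pins those choices as
explicit arguments with the defaults above.

## Known limitations and open points

- Under the null with thresholding (`tau = "q1"`/`"q2"`), the reference
  study reports *negative* average selected penalties, whereas this
  implementation selects the grid maximum: with a pure-noise response the
  predictive risk is minimized at infinite penalty, and the criterion value
  at the negative end of the interval is demonstrably larger than at the
  top, regardless of the threshold (which only widens the interval
  downward). We could not construct a defensible criterion variant that
  prefers the negative edge under the null, and chose the risk-consistent
  behavior; the thresholded-null penalty histograms should be interpreted
  accordingly. Power and Type-I error are unaffected in kind: the
  permutation construction is valid for any tuning rule.
- Permuting a centered response preserves its centering exactly, so
  responses are not re-standardized per permutation; this is moot for exact
  permutations.
- Multivariate responses (matrix `Y`, Kronecker-structured effects) and
  kernels other than the linear ridge kernel are out of scope; so are
  k-fold CV variants and data-driven selection of `lambda_max`.
- The Gamma method-of-moments null assumes the permutation statistics at a
  fixed penalty have positive variance; degenerate samples (e.g. constant
  responses) fall back to the empirical inner p-value with a warning.

## A worked example

```{r example}
x <- make_design(120, 300, "compound_symmetric", seed = 7)
y <- make_response(x, "fixed_effects", xi = 0.4, sigma = 1, seed = 8)
fit <- adamant(x, y, method = "gacv", cv = "gcv", tau = "q1",
               M = 100, B = 499, seed = 9)
fit
summary(fit)
```

The summary reports where the selected penalties sit: under an alternative
the observed response typically selects a smaller (or negative) penalty
than most permuted responses, which is itself diagnostic of signal
concentrated in specific variance directions.

```{r plot, fig.width = 6, fig.height = 4}
plot(fit, "cv")
```
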