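---
title: "Left-censored imputation by Gibbs sampling: model, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Left-censored imputation by Gibbs sampling: model, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(censimp)
```

## The problem

Targeted metabolomics assays quantify a panel of compounds in every
sample, but a compound whose true abundance falls below the platform's
limit of quantification (LOQ) yields no value.  This missingness is
*missing not at random* (MNAR): the probability that a cell is missing
depends on the value itself, and the missing values are systematically
the *smallest* values of their variable.  Imputers designed for
missing-at-random data (kNN, SVD, random forest) ignore this and pull
imputed values toward the variable mean, overstating the low tail and
distorting every downstream statistic.

## The model

Let $X$ be an $n \times p$ abundance matrix and let variable $j$ contain
missing cells.  Write $y = X_j$, split into the missing part $y_m$
(length $m$) and observed part $y_f$ (length $f$), and let
$X' = X_{-j}$ be the remaining variables.  Each missing variable gets
truncation bounds $[lo, hi]$: $hi$ is the natural censoring point — by
default the observed minimum of the variable, optionally a quantile of
the observed values or a known LOQ — and $lo$ is $-\infty$ for centred
or log-scale data (or $0$ for raw positive abundances).

Imputation is a Gibbs sampler with an embedded prediction model:

1. **Initialize** the missing cells (QRILC by default, so the starting
   values already respect the censoring bound).
2. **Predict**: fit an elastic net $y' \sim X'$ on all $n$ rows.
3. **Estimate**: take the fitted values $\hat y$ and the root mean
   square deviation of the missing part,
   $\sigma = \sqrt{\tfrac1m \sum_{i=1}^{m} (\hat y_{mi} - y'_{mi})^2}$.
4. **Sample**: redraw each missing element from the truncated normal
   $N(\hat y_{mi}, \sigma^2 \mid [lo, hi])$ and write it back into
   $y'$.

Steps 2–4 repeat `iters_each` times per variable; the sweep over all
missing variables (ordered from fewest to most missing cells, so the
best-observed variables stabilize first) repeats `iters_all` times.
The final draw is the imputed value — no posterior averaging — matching
the algorithm's definition of the returned matrix.  The chain for any
cell can be recorded (`trace_cells`) to inspect convergence: $\hat y$
and $\tilde y$ settle after a few cycles and $\sigma$ drops to a steady
small value, while the visible upper ceiling on $\tilde y$ shows the
truncation at work.

The prediction model sees *all* other variables, including other
currently-imputed missing variables; this is what lets information
propagate across the matrix over the outer sweeps.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `iters_each` | 100 | Gibbs cycles per missing variable per sweep |
| `iters_all` | 20 | sweeps over the whole matrix |
| `lambda` | 0.01 | elastic-net penalty weight |
| `alpha` | 0.5 | L1/L2 mix (0.5 = equal blend) |
| `initialization` | `"qrilc"` | starting fill for missing cells |
| `lo_policy` | `"neg_inf"` | lower bound (use `"zero"` for raw positive data) |
| `hi_policy` | `"min_observed"` | upper bound (censoring-point proxy) |
| `workers` | 1 | parallel variable updates per sweep |

The defaults run $100 \times 20 = 2000$ Gibbs cycles per missing
variable.  Halving both (`iters_each = 50`, `iters_all = 10`) changes
per-variable NRMSE by well under 10% in the package's own benchmark
(asserted in the test suite), so the reduced setting is a
reasonable preset for large matrices.

**Elastic-net penalty scale.**  `lambda` is glmnet's $\lambda$: the
penalty weight on the $\tfrac1{2n}$-averaged squared-error objective,
with predictors (and, internally, the response) standardized and an
unpenalized intercept.  Written out, the ridge ($\alpha = 0$) solution
solves $(X_s^\top X_s/n + (\lambda/\hat\sigma_y) I)\,\beta_s =
X_s^\top y_c / n$ on the standardized scale, where $\hat\sigma_y$ is
the $1/n$-denominator SD of $y$ — this mapping is frozen in a
closed-form oracle test.  Exposing glmnet's own scale (rather than a
total-RSS scale differing by a factor $2n$) keeps `lambda = 0.01`
meaning what practitioners of this method expect.  `lambda = 0`
short-circuits to ordinary least squares.

## Comparator imputers

* **HM** — half-minimum substitution: every missing cell becomes half
  the observed minimum of its variable.  Deterministic, fast, and
  distribution-destroying; the baseline everything should beat.
* **QRILC** — per variable, the mean and SD of the underlying complete
  normal are estimated by regressing the sorted observed values on
  standard-normal quantiles of censoring-adjusted plotting positions
  ($p_r = \pi + (1-\pi)\,r/(f+1)$ for censored fraction $\pi$), then
  every missing cell is drawn from that normal truncated above at the
  observed minimum.  Keeps the distribution but ignores all other
  variables.
* **kNN-TN** — variables are standardized by truncated-normal
  maximum-likelihood estimates of their mean/SD (Newton–Raphson on
  $(\mu, \log\sigma)$, gradient tolerance $10^{-8}$), then each missing
  cell is the $|r|$-weighted average of its row's values in the $k$
  most-correlated variables ($k = 10$ by default; neighbours are
  variables, not samples, and weights are $|r|$ with ties broken by
  variable index).  No truncation is applied to the result — the method
  can and does impute values above the censoring point, which is
  exactly the failure mode the Gibbs approach avoids; one acceptance
  check demonstrates it on a censored fixture.

Two degenerate cases deserve note.  First, on a heavily censored small
sample the left-truncated normal likelihood can increase without bound
as $\mu \to -\infty$ (no interior MLE exists; we verified this by grid
search on a failing fixture).  `truncnorm_mle()` reports an error in
that case and kNN-TN falls back to observed-sample moments for that
variable, with a warning.  Second, if the Gibbs $\sigma$ collapses to
exactly zero (perfect fit, e.g. duplicated columns), the fitted values
are clamped into the bounds instead of sampled.

## The synthetic benchmark

`simulate_two_group_dataset()` emulates a two-condition metabolomics
study: for each group a $p$-vector of variable means is drawn i.i.d.
$N(0, 0.5^2)$, then 80 observations per group are drawn from a
multivariate normal with those means and a shared covariance,
factorized by its (symmetric-matrix) SVD; the default 76-variable
covariance is a random correlation matrix with condition number at most
100, standing in for a real panel's covariance, which can be supplied
instead.  `generate_mnar_mask()` censors `round(proportion * p)`
variables chosen uniformly without replacement, each strictly below its
own empirical quantile drawn from $U(0.3, 0.6)$ (the harsher of the two
sweep presets; real-data-style sweeps use $U(0.1, 0.5)$).  Rounding of
the variable count uses R's round-half-even; quantiles are type 7.

What this emulates well: correlated variables, group structure, and
left-censoring at variable-specific detection limits.  What it does
not: skewed or heteroscedastic abundance distributions, batch effects,
and missingness mixing MNAR with MCAR.  Passing benchmarks here shows
the machinery works under the model's own assumptions, not that the
same margins will hold on any real dataset.

## Evaluation metrics

Per missing variable, NRMSE
$= \sqrt{\operatorname{mean}((t - x)^2)/\operatorname{var}(t)}$ is
computed on the masked cells only (the only cells on which methods can
differ); SD-normalization is isolated in `nrmse()` so an alternative
normalization is a one-line swap.  Methods are ranked per variable and
ranks summed (SOR; ties get average ranks, so the per-variable total is
conserved at $m(m+1)/2$).  Sample-layout distortion is the Procrustes
residual sum of squares between the ordination of the original and the
imputed matrix — PCA scores (unsupervised) and two-class PLS X-scores
(supervised), 2 components by default, reference fixed and target
translated/rotated/scaled (vegan's convention with scaling enabled).
Label-aware checks compare two-sample t-tests per missing variable:
Pearson correlation of natural-log p-values (the log base cancels in
the correlation), and the true positive rate
$|S \cap S'|/|S|$ at cutoffs 0.05 and 0.01, where $S$ ($S'$) are the
variables significant on the original (imputed) data.  Welch's t-test
is the default; `pooled = TRUE` gives the classic equal-variance test.

## Numerical choices

* Truncated-normal sampling is inverse-CDF on a log-scale mixture of
  normal tail probabilities, reflected into the numerically favourable
  tail; draws are a deterministic function of the uniform stream, so
  fixed seeds give bit-identical results across platforms, with no
  rejection loops.
* All randomness derives from one integer seed.  Each (sweep, variable)
  update seeds its own substream, so with `workers > 1` (updates
  against a frozen start-of-sweep snapshot, committed together) the
  result is identical for any worker count.  Serial mode
  (`workers = 1`) lets each variable see the others' latest values —
  the classical Gibbs scan — and is therefore a slightly different, also
  deterministic, estimate.
* The elastic net is refit at every Gibbs cycle, as the procedure is
  defined; nothing is cached across cycles.
* Matrices are imputed as given: no internal log-transform or scaling.
  Transform first if your data are raw abundances and you want the
  normal model to be plausible.

## Problem sizes used in the test suite

The packaged benchmarks run the simulator at its native 160 × 76 shape
with 30% of variables censored, reduced iterations (50 × 10) for the
ten-replicate method-ordering comparison, and one replicate at full
2000 cycles for the iteration-robustness check; unit tests use smaller
fixtures (tens of rows, ~10 variables) chosen to exercise every code
path rather than to estimate performance.

## Known limitations

* A single completed matrix is returned; there is no multiple-imputation
  pooling of between-draw uncertainty.
* The truncated-normal model assumes approximate normality per variable
  on the analysis scale.
* kNN-TN equivalence with its published implementation is at the level
  of the method contract (estimation, standardization, weighting), not
  byte-for-byte output.
* Variables with fewer than 3 observed values cannot be imputed by the
  model-based methods (kNN-TN needs 10 for its MLE step).
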