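# censimp

Imputation of left-censored missing values in quantified metabolomics
and proteomics matrices.

## The problem

When a metabolite's true abundance falls below the platform's limit of
quantification, the cell comes back empty.  Such values are *missing
not at random*: they are systematically the smallest values of their
variable, so mean-seeking imputers (kNN, SVD, random forest) overstate
them, shrink variances, and distort downstream tests.

## The method

For an n × p matrix **X** with missing variable *j*, write y = X_j with
missing part y_m and observed part y_f, and X′ = X_{−j}.  Each missing
variable gets truncation bounds [lo, hi], with hi the censoring-point
proxy (observed minimum by default, or a quantile, or a known LOQ) and
lo = −∞ (centred/log data) or 0 (raw abundances).  After initializing
(QRILC), a Gibbs sampler iterates:

1. fit an elastic net y′ ~ X′
   (β̂ = argmin ‖y − Xβ‖² + λ[(1−α)/2 ‖β‖₂² + α‖β‖₁], glmnet
   parameterization, λ = 0.01, α = 0.5);
2. take fitted values ŷ and σ = √(Σᵢ (ŷ_mi − y′_mi)² / m), the RMSD of
   the missing part;
3. redraw each missing element from the truncated normal
   N(ŷ_mi, σ² | [lo, hi]).

Each missing variable runs `iters_each = 100` such cycles per sweep and
the matrix is swept `iters_all = 20` times (2000 cycles per variable),
variables ordered from least to most missing.  Imputed values exploit
the full correlation structure *and* respect the censoring bound —
unlike half-minimum substitution (HM), QRILC (ignores other variables),
or truncated-normal kNN (kNN-TN; no bound on its output), all of which
are included as comparators.

## Worked example

```r
library(censimp)

sim <- simulate_two_group_dataset(n_per_group = 40, p = 20, seed = 7)
cen <- generate_mnar_mask(sim$data, mnar_spec(0.3, 0.3, 0.6), seed = 8)
cen$censored
#> <data_matrix> 80 observations x 20 variables, 213 missing cells (13.3%)

res <- impute_gsimp(cen$censored,
                    config = run_config(iters_each = 50, iters_all = 10,
                                        seed = 9))
res
#> <imputation_result> method=gsimp, 80 x 20 matrix, 500 Gibbs cycles per missing variable, seed=9

report <- evaluate_methods(sim$data, cen$censored, labels = sim$labels,
                           config = run_config(iters_each = 50,
                                               iters_all = 10, seed = 9))
report
#> <evaluation_report> 6 missing variables, 4 methods
#> sum of NRMSE ranks (lower = better):
#>  gsimp  qrilc     hm knn-tn
#>      7     13     20     20
#> median NRMSE per method:
#>  gsimp  qrilc     hm knn-tn
#> 1.1971 1.3426 1.6968 2.0100
#> log p-value correlation:
#>  gsimp  qrilc     hm knn-tn
#> 0.9866 0.9966 0.9621 0.7972
```

Six of the twenty variables were censored below variable-specific
detection limits.  The Gibbs imputer attains the lowest sum of NRMSE
ranks (7; the minimum possible with 6 variables is 6) and the lowest
median NRMSE, i.e. its imputed values sit closest to the true censored
values; the p-value correlations show how well each method preserves
the two-group t-test results.

A command-line wrapper covering `impute`, `simulate`, and `evaluate`
is installed at `inst/scripts/censimp`:

```sh
Rscript inst/scripts/censimp impute --in censored.csv --out imputed.csv \
    --method gsimp --seed 1 --report run.json
```

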