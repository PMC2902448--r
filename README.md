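# sspca — super-sparse principal component analysis

PCA of an expression matrix (samples × genes) returns loading vectors
with essentially no zero entries, which is both hard to interpret and,
when genes vastly outnumber samples, statistically noisy. `sspca`
estimates **sparse** principal components for exactly this regime. It
is aimed at analysts of bulk or single-cell transcriptomic matrices
(and any other wide numeric data) who want components supported on a
small, explicit set of variables.

## The method

For centered data `X` (n × p) with sample covariance `S = X'X/n`, the
leading loading `v` is estimated by a NIPALS power iteration whose
regression step is penalized:

    minimize over v:  Σ_j { ||X_j − v_j z||² + p_λ(|v_j|) },

solved by iteratively reweighted least squares with diagonal weights
`p′_λ(|v_j|)/|v_j|`. The flagship penalty comes from a random-effect
(h-likelihood) model, `v|u ~ N(0, uθ)` with `u ~ Gamma(mean 1,
variance w)`: profiling out `u` gives the weight `λ/û(|v|)` with

    û = ½ { (1 − w/2) + √((w/2 − 1)² + 2wv²/θ) },   λ = φ/θ.

At `w = 0` this is ridge, at `w = 2` LASSO-like; for `w > 2` (default
30) the penalty is **unbounded at the origin**, so small coefficients
are driven exactly to zero — far sparser than LASSO or elastic-net
fits. For the super-sparse variant (SSPCA) the singular values of `X`
are first shrunk under a condition-number constraint on the covariance
spectrum — `1/l*_i = clamp(1/l_i, t*, κ_max t*)` with `t*` maximizing
the constrained Gaussian likelihood — and the loading is estimated
from the reconstruction `X* = U D* V'`. `θ` is estimated by a moment
rule, `λ` and `κ_max` by 5-fold cross-validation; the number of
components comes from a row-wise permutation test, and explained
variance is reported as QR-adjusted variance because sparse scores are
correlated.

LASSO, SCAD, elastic-net and ridge penalties are available through the
same interface as comparison baselines.

## Worked example

```r
library(sspca)
set.seed(7)
dat <- sim_generate(sim_scenario(n = 60, p = 40, beta_sq = 2))
X <- center_columns(dat$X)

# how many components? permutation test, values shuffled within rows
perm <- permutation_component_count(X, P = 1000, alpha = 0.001, seed = 7)
perm
#> Permutation test (P = 1000 , alpha = 0.001 ): 1 significant component(s)
#>         d  p_value
#> 1 21.3905 0.000999
#> 2  4.2900 1.000000
#> ...

# super-sparse fit with the HL penalty; lambda = NA -> 5-fold CV
fit <- sspca_fit(X, k = perm$k0,
                 spec = penalty_spec("HL", lambda = NA, w = 30),
                 shrink = TRUE, tuning = tuning_config(K = 5, seed = 7))
fit
#> SSPCA-HL fit: 60 samples x 40 variables, 1 component(s)
#>         d nonzero lambda adj_var_pct cum_adj_var_pct
#> 1 21.3213       4  2.116       66.19           66.19
#> kappa_max = 5.19691

which(abs(fit$loadings[, 1]) >= 5e-5)
#> [1] 1 2 3 4
loading_distance(dat$v1_true, fit$loadings[, 1])
#> [1] 0.0214
```

The generator plants a single factor on variables 1–4; the permutation
test finds exactly one significant component, and the fitted loading
is supported on exactly those four variables (36 of 40 coefficients
are zero at the 5e-5 reporting threshold), at sine-angle distance
0.021 from the true direction. Ordinary PCA on the same data gives 40
nonzero coefficients.

File-based workflows use the same machinery from the shell:

```sh
exec/sspca fit --input expr.tsv --method sspca --penalty hl \
    --k auto --permutations 1000 --alpha 0.001 --seed 1 --out results/
exec/sspca simulate --table all --reps 100 --seed 1 --out bench/
```

`fit` writes `loadings.tsv` (full precision plus a sparsity mask),
`scores.tsv`, `summary.tsv`, `permutation.tsv` and a JSON manifest
that suffices to reproduce the run.

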