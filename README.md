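# groupslab

Group-adaptive spike-and-slab regression and classification via
variational Bayes.

## What problem does this solve?

In high-dimensional regression the predictors are rarely exchangeable: a
clinical model may combine drug-response assays, gene expression and
methylation; a multi-tissue model pools features per tissue. Standard
penalized regression applies one symmetric penalty to all features and
ignores any side information about them. `groupslab` uses an **external
covariate** — the assay type, tissue, a per-feature quality metric, any
value attached to each feature — to partition the $p$ features into $G$
groups, and learns **per-group penalization** from the data.

Each coefficient gets a spike-and-slab prior, $\beta_j = s_j b_j$ with

$$ b_j \sim \mathrm{N}\!\big(0, \gamma_{g(j)}^{-1}\big), \qquad
   s_j \sim \mathrm{Ber}\big(\pi_{g(j)}\big), $$

so group $k$ has its own **slab precision** $\gamma_k$ (shrinkage strength)
and **mixing proportion** $\pi_k$ (sparsity level), both under conjugate
hyper-priors and both estimated by coordinate-ascent variational inference
together with the coefficients. The result: groups that carry signal are
penalized less, noise groups are shrunk hard and emptied out, and the fitted
$\hat\gamma_k$, $\hat\pi_k$ are interpretable measures of each group's
importance. Gaussian and binary (logistic, via the Jaakkola–Jordan bound)
responses are supported, plus a dense variant with a full multivariate
coefficient posterior for correlated designs.

Intended users: statisticians and computational biologists fitting
penalized regression on grouped/multi-omics features who want data-driven,
covariate-aware penalties rather than one global penalty or ad-hoc
per-block scaling.

## Worked example

Simulate the six-group benchmark (three pairs of groups with slab
precisions 0.01, 1 and 100 — i.e. high-, mid- and low-amplitude effects —
and within-pair sparsity 0.2 / 0.3), fit the sparse engine, and score
against the ground truth:

```r
library(groupslab)

sim <- simulate_data(default_scenario(nu = 0.2, n = 500, p = 300, seed = 1))
fit <- fit_linear(sim$dataset, sim$partition)
fit
#> <gs_fit> family: gaussian, variant: sparse
#>   300 coefficients, 6 groups
#>   gamma_hat: 0.00974, 0.0334, 1.16, 1.6, 57.1, 66.9
#>   pi_hat:    0.289, 0.29, 0.217, 0.318, 0.259, 0.202
#>   45 sweeps, converged: TRUE
```

The estimated slab precisions `gamma_hat` recover the three amplitude
levels (truth 0.01/0.01, 1/1, 100/100) and `pi_hat` the sparsity around
0.2–0.3; small-effect groups (truth $\gamma = 100$) are the hardest and
land within a modest factor of the truth. Out-of-sample:

```r
test <- make_test_set(sim, n_test = 1000)
m <- recovery_metrics(fit, sim, test$X, test$y)
round(c(m$rmse_y, m$rmse_beta, m$sign_agreement), 4)
#> 0.3470 0.0084 0.9530
```

Test-set RMSE 0.347 against a noise standard deviation of
$1/\sqrt{\tau} \approx 0.316$ (the intercept-only model scores ≈ 44 on
these data), coefficient RMSE 0.0084, and 95% of the truly active features
recovered with the correct sign. `fit$inclusion_prob` gives per-feature
posterior inclusion probabilities for selection.

Real data enter either as in-memory objects:

```r
data <- gs_dataset(X, y, family = "gaussian")      # samples x features
part <- build_partition(assay_type)                # one value per feature
fit  <- fit_linear(data, part)                     # or fit_logistic(...)
yhat <- predict(fit, X_new)
```

or through files and the command-line wrapper (TSV/CSV matrices with a
sample-id column, a two-column feature annotation):

```sh
Rscript inst/cli/groupslab.R fit \
  --matrix X.tsv --response y.tsv --annotation groups.tsv \
  --family gaussian --variant sparse --out fit
```

`run_cv()` provides seeded (stratified) cross-validation and
`run_experiment()` a parameter-sweep harness with recovery metrics.

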