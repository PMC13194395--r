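# hnet: individualized dose-response curves via hypernetworks

Estimating the causal effect of a **continuous** treatment (a drug dosage, an
exposure level, a policy intensity) from observational data means learning,
for each unit with covariates `x`, the whole counterfactual dose-response
curve

> θ_x(t) = E[ Y | do(T = t), X = x ],

not a single treated-vs-control contrast. Under the standard identification
assumptions (positivity, conditional unconfoundedness, consistency) this
reduces to a regression problem — but a naive regression of `y` on `(x, t)`
tends to bury the treatment inside the covariate representation: under
confounding, `x` co-predicts whatever `t` contributes, and the fitted curves
come out flat or arbitrary even when factual error looks fine.

`hnet` implements a hypernetwork estimator that makes the dose structurally
unavoidable. An encoder maps covariates to a representation
`z = f_phi(x)`; a hypernetwork maps `z` to the *entire weight vector*
`omega = g_psi(z)` of a small fixed-architecture target network
`h_omega : t -> y`; the prediction is

> ŷ = h_{g_psi(f_phi(x))}(t),

trained end-to-end by outcome mean squared error. Each unit gets its own
generated dose-response network; the dose is the only input that network
sees. The package ships with:

- the neural S-learner ablation (`fit_slearner()`): identical encoder,
  optimizer and scaling, with the weight-generating pathway replaced by
  plain `(z, t)` concatenation;
- counterfactual evaluation metrics `mise()` / `amse()` against a
  ground-truth oracle on a dose grid;
- seeded generators for the confounded synthetic benchmark family
  (`generate_nie2021()`, `generate_linear_dgp()`);
- a replicate benchmark harness (`run_benchmark()`) with a persistent
  per-replicate ledger and mean ± SE aggregation;
- JSON model archives (`save_model()` / `load_model()`) and a thin CLI
  (`inst/cli/hnet.R`).

Everything — including the neural networks, backpropagation through the
generated weights, and the AdamW-style optimizer — is implemented in
vectorized base R; there are no heavyweight dependencies.

## Worked example

```r
library(hnet)

# one instance of the confounded synthetic benchmark: 6 uniform covariates,
# logistic-squashed confounded dose, smooth nonlinear outcome + noise
inst <- generate_nie2021(dgp_spec(n_train = 500, n_test = 200, seed = 42))
inst$train
#> <observational_dataset> N = 500, p = 6 covariates, tau = 1 treatment dim, with ground-truth oracle

model <- fit_hnet(inst$train, hnet_config(t_support = c(0, 1)), seed = 1)
model
#> <hnet_model> p = 6, tau = 1, 6357 trainable parameters
#>   trained 800 epochs (best at 800), monitored MSE 0.3782 (scaled outcome)

# counterfactual accuracy against the noiseless ground truth
evaluate_model(model, inst$test, dose_grid(n_points = 65))
#> <metric_report> MISE = 0.05485, AMSE = 0.002758 (n_test = 200, grid G = 65)

# an individual curve vs the truth at doses 0, .25, .5, .75, 1
x <- inst$test$X[1, ]
round(predict_curve(model, x, dose_grid(n_points = 5)), 3)
#> [1] -0.215  0.053  0.753  0.045 -1.308
round(inst$oracle(seq(0, 1, 0.25), matrix(x, 1)), 3)
#> [1] -0.263  0.000  0.513  0.000 -1.263

# effect of moving this unit from dose 0.2 to dose 0.8
round(contrast(model, x, 0.8, 0.2), 3)
#> [1] -0.156
```

The fit takes a few seconds on one CPU. MISE is the average integrated
squared error of the individual curves (here ≈ 0.05 against an outcome
noise variance of 0.25); AMSE is the same for the population-average curve.
The printed "monitored MSE 0.3782" is the scaled training loss, sitting just
above the scaled noise floor (≈ 0.32 for this instance) — the signature of a
fit that is regularized rather than memorizing.

## The benchmark

`run_benchmark()` reproduces the replicate protocol of the synthetic
benchmark: R independent instances (500 train / 200 test), both models fit
per instance with matched seeds, MISE/AMSE per replicate, mean ± SE across
replicates:

```r
res <- run_benchmark(dgp_spec(), models = c("hnet", "slearn_nn"),
                     R = 20, base_seed = 1)
res
#> <benchmark_result> nie2021, R = 20 replicates (failed: 0), base seed 1
#> | Model | MISE | AMSE |
#> |---|---|---|
#> | HNet | 0.083 ± 0.006 | 0.012 ± 0.002 |
#> | SLearn NN | 0.787 ± 0.023 | 0.415 ± 0.012 |
```

The hypernetwork model beats the ablation on every matched replicate — the
concatenation model's curves flatten under the shared training protocol,
which is exactly the treatment-relevance failure the architecture exists to
prevent. See the methods vignette
(`vignettes/hypernetwork-dose-response.Rmd`) for the model, the default
hyperparameters and the reasoning behind them, and what the benchmark does
and does not certify.

## Command line

```sh
Rscript inst/cli/hnet.R simulate  --dgp nie2021 --n-train 500 --n-test 200 --seed 7 --out data/
Rscript inst/cli/hnet.R train     --data data/train.csv --map data/train.csv.json --seed 7 --out model.json
Rscript inst/cli/hnet.R evaluate  --model model.json --test data/test.csv --map data/test.csv.json --grid 65
Rscript inst/cli/hnet.R benchmark --replicates 20 --seed 7 --out results/
```
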