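# deepweibull

Parametric survival analysis for time-to-onset studies with
high-dimensional genetic predictors — for biostatisticians and genetic
epidemiologists who want the interpretability of a Weibull accelerated
failure time (AFT) model together with the flexibility of a small neural
network, plus game-theoretic attributions of what the fitted model
actually learned.

## The model

Onset times follow a Weibull law with a shared shape and a per-subject
scale,

    S(t | x_i) = exp( -(t / λ_i)^k ),      log λ_i = g(x_i),

where `k > 1` corresponds to a hazard rising with age. The package fits
two forms of `g` by right-censored maximum likelihood:

* `fit_linear_aft()` — the classical linear predictor
  `g(x) = β₀ + xᵀβ` (BFGS on the exact likelihood, analytic gradients);
* `fit_ffn_aft()` — a feedforward network with two SoftPlus hidden
  layers and a linear output node, trained jointly with `k` by
  full-batch Adam with hand-derived backpropagation. Its point is
  epistasis: interactions such as XOR between two carrier indicators,
  which no linear model can represent, are learned without enumerating
  product terms.

Around the models:

* SNP and APOE genotype encoders (`encode_snp_indicators()`,
  `encode_apoe()`), strict coordinate-based VCF extraction
  (`extract_variants_vcf()`), cohort CSV I/O;
* event-stratified k-fold cross-validation with Harrell's C-index and
  the IPCW integrated Brier score (`cross_validate()`);
* exact and permutation-sampling interventional Shapley values
  (`explain_model()`), importance rankings, beeswarm/dependence table
  exports;
* SHAP-ranked incremental feature selection
  (`run_feature_ladder()`);
* a synthetic SNP cohort generator with known ground truth
  (`simulate_cohort()`, `planted_epistasis_benchmark()`), used by the
  test-suite because real cohorts of this design are controlled-access;
* an end-to-end pipeline (`run_pipeline()`) and a thin CLI
  (`inst/cli/deepweibull-cli.R`) with `simulate`, `encode`, `fit`, `cv`,
  `explain`, `ladder`, `pipeline` subcommands.

## Worked example

Simulate a study-shaped cohort (956 subjects, 55 features: 25 variants ×
2 carrier indicators, 3 APOE indicators, MMSE, sex; ~50% events), fit
both models under the same stratified folds, and rank features by mean
absolute Shapley value:

```r
library(deepweibull)

sim   <- simulate_cohort(sim_config(n_subjects = 956, seed = 1))
folds <- stratified_kfold(sim$cohort, k = 5, seed = 1)

cross_validate(sim$cohort, "linear", folds = folds)
#> <cv_result> linear, 5 folds
#>  split  model mean_c_index  sd_c_index  mean_ibs      sd_ibs
#>   test linear    0.7153125 0.035269952 0.1648218 0.011115053
#>  train linear    0.7565539 0.006977387 0.1409099 0.002490195

cfg <- ffn_config(input_dim = 55, validation_split = 0.1, seed = 1)
cross_validate(sim$cohort, "ffn", folds = folds, config = cfg)
#> <cv_result> ffn, 5 folds
#>  split model mean_c_index sd_c_index  mean_ibs     sd_ibs
#>   test   ffn    0.7228345 0.04152307 0.1591024 0.01465615
#>  train   ffn    0.7699394 0.02816217 0.1342937 0.01609974

model <- fit_ffn_aft(sim$cohort, config = cfg)
attr  <- explain_model(model, sim$cohort[seq(1, 956, by = 6), ],
                       n_permutations = 40, seed = 1)
head(mean_abs_importance(attr), 5)
#>   rank   feature mean_abs_shap
#> 1    1      MMSE    0.37849024
#> 2    2   APOE_E4    0.29273444
#> 3    3 snp16_alt    0.11604868
#> 4    4 snp12_alt    0.07399378
#> 5    5 snp17_alt    0.06721537
```

Reading the numbers: the test C-index is the probability that the model
orders a random comparable pair of subjects correctly (0.5 = chance);
the integrated Brier score is the censoring-weighted squared error of
the predicted survival curves (lower is better). Here the neural model
edges out the linear baseline (0.723 vs 0.715) on a cohort whose
generating signal is mostly additive, and the attribution puts the two
genuinely dominant generated effects — the cognitive score and the
harmful APOE-E4 indicator — at the top; the small residual SHAP mass on
null SNPs is overfitting noise, visible as such because the generator's
truth channel (`sim$truth$coefficients`) is available.

On a cohort with a planted XOR interaction between two carrier
indicators (zero marginal effects), the same comparison separates the
models sharply — about 0.60 vs 0.51 test C-index — and the gap vanishes
when the interaction coefficient is set to zero; see
`planted_epistasis_benchmark()`.

## Documentation

`vignettes/neural-weibull-aft.Rmd` describes the model, the encoding
conventions, the evaluation and attribution methodology, what the
synthetic generator does and does not emulate, and the package's
numerical choices.
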