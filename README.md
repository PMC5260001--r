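# survmir

Survival-time estimation from miRNA expression cohorts with evolutionary
feature selection.

## The problem

Glioblastoma multiforme (GBM) carries a median survival of roughly a year,
and bulk miRNA expression profiles hold prognostic signal. Given a cohort of
deceased patients — an expression matrix (hundreds of miRNAs × hundreds of
samples) plus clinical survival in days — `survmir` asks which *small subset*
of miRNAs predicts survival time, and how accurately. Survival is treated as
a plain regression target in years.

## The method

The core estimator couples two pieces:

* a **ν-support-vector regressor** (radial kernel; the quadratic program is
  delegated to libsvm via `e1071`), scored by the Pearson correlation *r*
  between actual and predicted survival over *pooled* 10-fold
  cross-validated predictions, alongside the mean absolute error
  MAE = (1/N) Σ|ŷᵢ − yᵢ| (years) and the standard error of estimates
  SEE = √(Σ(ŷᵢ − yᵢ)²/(n − 2));
* an **inheritable bi-objective combinatorial genetic algorithm (IBCGA)**
  whose chromosome holds n binary feature genes (exactly r ones per stage)
  plus three 4-bit genes indexing C, γ and ν in 16-value grids. The
  algorithm sweeps stages r = r_start..r_end (defaults 10..50), runs a
  steady-state GA per stage with **orthogonal-array intelligent crossover**
  (children assembled from per-gene main effects estimated over a two-level
  orthogonal array), count-preserving swap mutation and elitism, then
  inherits each stage's population into the next with one extra feature gene
  switched on. The best stage solution becomes the final model.

Selected signatures are ranked by **main effect difference (MED)** — an
orthogonal experimental design over include/exclude levels of each selected
feature — and examined by single-feature effect and leave-one-out knock-out
analyses. Forward-stepwise multiple linear regression and an inner-CV-tuned
elastic net (glmnet) serve as baselines. A synthetic-cohort generator with
planted informative features makes every stage testable with known ground
truth.

See `vignettes/survival-estimation-methods.Rmd` for the full model account,
parameter meanings, and design choices.

## Worked example

```r
library(survmir)

## a synthetic cohort: 120 patients x 30 miRNAs, 4 informative
sim   <- simulate_cohort(synthetic_spec(n_samples = 120, n_features = 30,
                                        informative_features = 4,
                                        noise_sd = 0.8, seed = 11))
res   <- run_ibcga(sim$cohort,
                   ibcga_params(r_start = 2, r_end = 6, N_pop = 10,
                                G_max = 6, P_m = 0.45, seed = 11),
                   crossover_cv_folds = 3)
res
#> IBCGA sweep: stages r = 2 .. 6
#> overall best: r = 5, pooled r = 0.9016, MAE = 0.791 years

selected_features(res$overall_best, sim$cohort)
#> [1] "mir-sim-0001" "mir-sim-0002" "mir-sim-0003" "mir-sim-0012" "mir-sim-0022"
sim$truth$informative_ids
#> [1] "mir-sim-0001" "mir-sim-0002" "mir-sim-0003" "mir-sim-0004"

hp <- decode_hyperparams(res$overall_best$chromosome)
med_analysis(selected_features(res$overall_best, sim$cohort),
             sim$cohort, hp, res$folds)
#>     feature_id         med rank
#> 1 mir-sim-0001  0.34320141    1
#> 2 mir-sim-0002  0.29414161    2
#> 3 mir-sim-0012  0.02262810    3
#> 4 mir-sim-0022 -0.01231368    4
#> 5 mir-sim-0003 -0.07912765    5
```

The best model predicts held-out survival with a pooled cross-validated
correlation of 0.90 and a mean absolute error of 0.79 years. Its five
selected miRNAs contain three of the four planted ones (effect magnitudes
1.5, 1.17, 0.83; the weakest planted effect, 0.5, is not separable from
noise at this cohort size), and the MED ranking puts the two strongest
planted features clearly on top — the near-zero and negative MED scores
below them are the design's way of saying those features contribute nothing
once the strong ones are present.

A file-based pipeline is available through `cmd_simulate()`, `cmd_select()`
and `cmd_analyze()` (or the `inst/cli/survmir` script) driven by a JSON/YAML
config; it writes the stage solutions, selected-feature list, fitted model,
metric reports, ranking tables and a predicted-vs-real scatter plot.

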