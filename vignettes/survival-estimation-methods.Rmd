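---
title: "Estimating survival time from miRNA expression: model, search and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating survival time from miRNA expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survmir)
```

## The problem

Glioblastoma multiforme (GBM) has a median survival of roughly a year, and
miRNA expression profiles carry prognostic signal. `survmir` treats survival
time (in years, deceased patients only) as a plain regression target and asks
two coupled questions: *which small subset of miRNAs* predicts survival, and
*how well*. Both are answered at once by wrapping a ν-support-vector
regressor (ν-SVR) inside an inheritable bi-objective combinatorial genetic
algorithm (IBCGA) that sweeps the number of selected features.

## The regression model

The base learner is a radial-kernel ν-SVR. For training pairs
$(x_i, y_i)$ the solver minimises the usual regularised ε-insensitive loss,
with ν simultaneously upper-bounding the fraction of margin errors and
lower-bounding the fraction of support vectors. We delegate the quadratic
program to libsvm (via `e1071`); the package owns everything around it:
feature selection, hyperparameter encoding, cross-validation and scoring.

Model quality is scored on *pooled* 10-fold cross-validated predictions: all
out-of-fold predictions are collected into one vector and scored once. The
three reported quantities are the Pearson correlation $r$ between actual and
predicted survival, the mean absolute error (MAE, years — a months-scale
column is emitted alongside), and the standard error of estimates
$\mathrm{SEE} = \sqrt{\sum_i (\hat y_i - y_i)^2 / (n - 2)}$. Pooling (rather
than averaging per-fold metrics) matches the single all-patients scatter this
kind of analysis reports; per-fold aggregation can be recovered from the
returned prediction vectors if wanted. The correlation is the GA's fitness
function. A degenerate pooling — zero variance in either vector — is assigned
fitness −1 with a warning rather than an error, so invalid candidates are
dominated instead of crashing the search.

## Chromosome encoding and the hyperparameter grid

A chromosome holds $n$ binary feature genes $f_i$ (exactly $r$ ones inside a
stage) plus three 4-bit genes indexing C, γ and ν in 16-value grids:

* C = $2^{-10}, \dots, 2^{5}$
* γ = $2^{-15}, \dots, 2^{0}$
* ν = $1/16, 2/16, \dots, 1$

Sixteen values per parameter make the 4-bit encoding exact. The γ and ν
grids are the standard libsvm-style search ranges. For C we deliberately use
$2^{-10..5}$ rather than extending to $2^{10}$: features are z-scored per
training fold (expression platforms differ in scale and SVR is
scale-sensitive; standardisation is on by default and configurable) and the
response spans only ~0.4–11 years, so C beyond $2^5$ adds no usable model
capacity — while libsvm's working-set solver needs 50–100× more iterations
at C ≥ $2^8$ on weak-signal feature subsets. The grid is fully configurable
(`hyperparam_grid()`) for anyone wanting other ranges.

## The IBCGA search

The search sweeps stages $r = r_\text{start}..r_\text{end}$; each stage runs
a generational GA whose population all carry exactly $r$ selected features,
and the final population of stage $r$ is *inherited* into stage $r+1$ by
switching one extra random feature gene on per individual. Defaults follow
the published configuration: r 10..50, population 50, crossover probability
0.8, mutation probability 0.05, 60 generations per stage, 2-way tournaments.
We read the generation budget as *per stage* (the termination test is inside
the per-$r$ loop); with stages 10..50 this yields exactly 41 stage solutions
$X_r$ and the overall best becomes the final model.

Crossover is the orthogonal-array (OA) "intelligent" operator. For two
parents, the factors are the gene positions where they differ — each
differing feature gene is one two-level factor, and each differing 4-bit
hyperparameter gene is one factor as a block. A Sylvester-type two-level OA
over those factors generates one candidate per row (level 1 = parent 1's
gene, level 2 = parent 2's), each candidate is repaired to exactly $r$ ones
by random flips *restricted to the differing positions* (minimal
disruption), and all candidates are evaluated. Per-factor main effects (mean
fitness at level 1 minus level 2) assemble child 1 from each factor's better
level; child 2 is the best evaluated row. Beyond 31 factors the surplus
differing positions are randomly grouped so the array never exceeds 32 rows;
the cap is configurable. Candidate scoring uses the same pooled-CV fitness
by default; `crossover_cv_folds` substitutes a coarser fold split for the
candidate screening only, trading child quality for speed on large cohorts.

Mutation must not break the stage constraint $\sum_i f_i = r$, so the
"traditional" bit-flip operator is realised as a single gene *swap*: a
selected gene trades places with an unselected one, keeping the mutant close
to its parent so that a newly introduced good gene is judged in a context
selection can reward. Hyperparameter genes flip each bit independently with
a deliberately low probability (1/16, under one flipped bit per mutant): in
our measurements a mutant whose C or γ index is heavily perturbed dies in
selection even when its feature swap was beneficial, which silently shuts
down the feature-exploration channel. The best individual is exempt from
mutation.

Within a stage the scheme is steady-state rather than wholesale-generational:
the population persists between generations; the tournament pool only
chooses crossover parents; the children displace the currently worst
individuals; and mutation perturbs randomly chosen non-elite slots in place.
Wholesale resampling through tournaments collapses a population of 20 onto a
single genotype within about four generations, after which crossover of
identical parents is (by definition) a no-op and all exploration stops. The
steady-state scheme keeps near-median explorers alive long enough for the
orthogonal-array crossover to screen the genes they carry — on planted-truth
cohorts this roughly doubles the number of planted features recovered under
a reduced search budget. For the same reason, crossover pairs are arranged
distinct-first.

Each stage ends with a memetic refinement of its elite: the three
hyperparameter genes are optimised by coordinate descent over the grid
(each gene swept through its 16 values in turn, cycling until no
improvement) with the feature set fixed. This reports every stage solution $X_r$ at comparable
hyperparameter quality, so the sweep's fitness profile across $r$ reflects
feature sets rather than hyperparameter luck, and the refined elite re-enters
the population where it sharpens the selection signal of later stages. It can
be disabled (`refine_elite = FALSE`).

A practical note on exploration budgets: mutation is the only operator that
introduces genes absent from the population (crossover recombines, and
inheritance adds one random gene per individual per stage), and the expected
number of mutation events per stage is $P_m N_{pop} G_{max}$ — 150 under the
published defaults. When running with a deliberately reduced population and
generation budget, keep that *absolute* event rate roughly constant by
raising $P_m$ (e.g. $P_m = 0.45$ at $N_{pop} = 20$, $G_{max} = 15$);
leaving $P_m$ at its default while shrinking the population starves the
search of new genes on feature spaces of realistic size.

Determinism: one master seed fans out to named sub-seeds (fold assignment,
GA stream, simulation) via a fixed hash (`derive_seed`), and the fold
assignment is drawn once per run and shared by every fitness evaluation —
fitness comparisons between chromosomes are therefore paired, which keeps
elitism well-defined. Ties (equal fitness, equal main effects) always prefer
the lexicographically smaller gene vector, so reruns are byte-identical.

## Feature ranking and diagnostics

* **MED** (`med_analysis`): a two-level OA with one factor per selected
  feature (level 1 = keep, level 2 = drop) scores every row's feature subset
  at fixed hyperparameters; a feature's main effect difference is the mean
  fitness gap between its two levels. This is the standard two-level
  main-effect estimator; rows encoding the empty subset take the −1
  degenerate fitness. Hyperparameters are *not* re-tuned per subset — the
  ranking is of features within the chosen model, and re-tuning would
  confound the contrast (a flag re-enables it implicitly by passing other
  `hp`).
* **Individual effects** (`individual_effect_analysis`): one single-feature
  ν-SVR per selected miRNA, re-tuned over a coarse 4×4×4 sub-grid by the
  same pooled-CV criterion, reporting $r$ and MAE in months.
* **Knock-out** (`knockout_analysis`): the fitness drop when one feature is
  removed from the full selected set. The field's "knock-out" phrase is
  ambiguous between this and the single-feature reading, so both analyses
  are provided and neither is endorsed; note that knock-out deltas of
  collinear features are near zero while their individual effects are not —
  comparing the two tables is itself informative.
* **Baselines**: forward-stepwise multiple linear regression (admission
  criterion: pooled-CV $r$ gain ≥ 0.005, matching the evaluation currency of
  the main method rather than in-sample F-tests) and an elastic net with the
  mixing parameter tuned over a grid and the penalty by inner CV. The
  elastic net defaults to the `lambda.1se` rule — the stronger
  regularisation reproduces the small-support, lower-correlation behaviour
  this baseline shows on real cohorts; `lambda_rule = "min"` is available.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions every test runs under:
247 samples × 470 features at full scale, i.i.d. standard-normal expression
(no distributional claim is made about real array values; scale-dependence
is neutralised by the per-fold z-scoring), a small planted set of
informative features with distinct sign-alternating effect sizes (default
magnitudes 1.5 down to 0.5), survival support 0.4–11 years, and additive
Gaussian noise with a 1-year standard deviation by default — roughly a 3:2
signal-to-noise ratio on the mapped scale, which we consider a realistic
middle ground between a trivially easy and an unlearnable cohort.

The latent score (linear combination of planted features, or a
Gaussian-bump-plus-weak-linear combination for `nonlinear_rbf`) is min-max
mapped onto the survival range *before* noise is added, then noise (in
years) is added and the result clipped back into the range. Mapping before
noise keeps `noise_sd` in its stated units; with `noise_sd = 0` nothing is
ever clipped, so a single planted linear feature correlates perfectly with
survival — a useful analytic anchor for tests. The `nonlinear_rbf` link
exists so that a kernel regressor has real curvature to exploit that linear
baselines cannot, letting tests check the expected method ordering
(ν-SVR ≥ stepwise MLR ≥ elastic net).

What the generator does *not* emulate: censoring (only deceased patients are
modelled), miRNA co-expression structure, batch effects, or platform noise
profiles. Passing tests therefore demonstrate algorithmic correctness and
recoverability under controlled conditions, not clinical performance on any
real cohort.

## Cohort assembly rules

Clinical records pass four filters, each removal attributed to the first
failing criterion: (i) received therapy, (ii) survival information present,
(iii) survival ≥ 30 days, (iv) duplicates merged. Duplicate entries with
*conflicting* survival are a hard error unless the keep-max merge policy is
enabled; day-to-year conversion uses 365.25 (configurable); missing
expression cells are refused unless per-feature mean imputation is enabled.
Whether "chemotherapy/radiotherapy" means either or both is delegated to
whoever prepares the clinical table: the package reads one boolean flag.

## Problem sizes used in the shipped checks

The package's own verification suite runs on simulated cohorts sized so the
full battery stays desk-scale: unit tests use cohorts of 30–200 samples and
6–30 features; the end-to-end checks use a 40×6 exhaustive-search
comparison (all C(6,2)·16³ chromosome configurations under a shared 5-fold
fitness), a full-scale 247×470 recovery study with a reduced search budget
(population 20, 15 generations, stages 5–15, P_m raised to 0.45 to keep the
absolute mutation-event rate near the published configuration), 120×20
cohorts for the method-ordering comparison, and 80–150-sample fixtures for
the ranking diagnostics. These sizes are the package's choice of a thorough-but-compact
evidence base; all of them regenerate from seeds at run time.

## Known limitations

* No censoring-aware metrics (C-index etc.) — survival is a plain
  regression target, as in the modelling tradition this follows.
* The GA's cost is dominated by SVR fits; at the full published budget
  (41 stages × 60 generations × population 50) a 247×470 cohort is an
  overnight run on one core. The reduced budgets used in the shipped checks
  recover planted signal reliably but are not the published configuration.
* MED scores depend on the fixed hyperparameters of the reference model;
  strongly redundant features depress each other's main effects (this is a
  property of the estimator, demonstrated in the tests, not a bug).
* The stepwise baseline's forward-only admission can stop at a local
  optimum; no backward elimination is attempted.
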