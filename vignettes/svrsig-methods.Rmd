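---
title: "Survival-signature discovery with nu-SVR and an inheritable bi-objective GA"
author: "svrsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival-signature discovery with nu-SVR and an inheritable bi-objective GA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svrsig)
```

## The estimation problem

Given bulk miRNA expression profiles of deceased cancer patients and
their observed survival times, we want (a) a regression model that
estimates survival time in years from expression, and (b) a *small*
subset of miRNAs — a signature — that carries the predictive
information. The two goals conflict: accuracy favours more features,
interpretability and clinical assay cost favour fewer. `svrsig` treats
this as a bi-objective problem and solves it with an inheritable
bi-objective combinatorial genetic algorithm (IBCGA) wrapped around
nu-support-vector regression (nu-SVR).

The expected input shape mirrors TCGA level-3 miRNA-seq cohorts:
a couple of hundred patients, a few hundred features of non-negative,
strongly right-skewed RPM-like values, with survival from the clinical
`days_to_death` field. Intake filters: only deceased patients with
both expression and clinical data are modelled; survival periods
under 30 days are excluded (exactly 30 is retained) to remove
perioperative deaths that no expression signal can explain; duplicate
clinical entries keep their first occurrence. Years are converted at
365.25 days/year (the astronomical convention; the clinical tables
only carry days).

## The regression model

For a feature subset S and hyperparameters $(\gamma, C, \nu)$, the
model is RBF-kernel nu-SVR:
$$ \hat y(x) = \sum_s \alpha_s \, e^{-\gamma \lVert x_S - x_{s,S} \rVert^2} - \rho, $$
fitted by libsvm (via `e1071`). In the nu parameterisation, $\nu \in
(0, 1]$ lower-bounds the support-vector fraction and upper-bounds the
margin-error fraction; the tube width $\varepsilon$ is an output of
the optimisation, not a tunable, which is why the chromosome encodes
only $(\gamma, C, \nu)$.

Features are standardized per training fold (mean/SD estimated on the
training split only and applied to the held-out split). Raw RPM
scales differ by orders of magnitude across miRNAs, which makes the
RBF distance degenerate, so standardization is on by default
(`standardize = FALSE` is available). A zero-variance training column
gets unit scale and therefore contributes nothing to the kernel
distance.

Two metrics score a model, both computed on the *pooled* out-of-fold
predictions of a seeded 10-fold cross-validation (pooling, rather than
averaging per-fold metrics, matches how predicted-versus-real scatter
plots are drawn and is stabler for small folds):

* CC — the Pearson correlation between real and estimated survival;
* MAE — $(1/N)\sum_i |x_i - z_i|$ in years. (A published statement of
  this estimator prints a squared deviation under the MAE name while
  reporting values in years; the exponent there is a typo, and the
  first-power form is implemented.)

## The search: IBCGA

A chromosome holds $d$ binary feature genes plus three 4-bit genes
indexing 16-level grids for $\gamma$, $C$ and $\nu$. The default
grids are the libsvm convention: $\gamma, C \in \{2^{-7}, \dots,
2^{8}\}$ and $\nu \in \{1/16, \dots, 16/16\}$.

At a fixed feature budget $r$, every individual has exactly $r$ set
feature genes, and the population evolves by

1. fitness evaluation — 10-CV CC (ties broken by lower MAE, then
   first-seen order, everywhere a comparison is made);
2. binary tournament selection into a mating pool;
3. orthogonal-array (OA) crossover on pool pairs (below);
4. mutation — per-bit flips on the parameter genes and a
   budget-preserving swap on the feature genes — with the phase-best
   individual exempt (elitism), so the best-so-far fitness at fixed
   $r$ never decreases.

When a budget phase ends, the best individual is recorded as the
solution $X_r$, then *inheritance* clears one uniformly chosen set bit
in every individual and the search continues at $r - 1$. Sweeping
$r$ from `r_start` down to `r_end` yields one solution per budget in a
single run, which is the bi-objective output; the overall best
$X_m$ is the signature. The phase stopping rule is a fixed generation
budget (`generations_per_r`, default 30) with early stop after
`stagnation_patience` (default 10) stagnant generations; both are
configurable because no canonical rule exists for this family of
algorithms. Crossover and mutation rates default to 0.8 and 0.05.

One fold partition, derived from the master seed, is shared by every
fitness evaluation in a run, so chromosomes are compared on identical
folds and fitness differences are attributable to the chromosome, not
to fold noise. A fitness cache keyed by the chromosome makes the many
near-duplicate OA evaluations cheap; it cannot change results, only
skip recomputation. Runs are fully deterministic given the seed.

### OA crossover

Where the two parents differ (feature genes and parameter genes
alike), the differing genes are grouped round-robin, after a seeded
shuffle, into at most `oa_max_factors` factors (default 7). A
two-level orthogonal array with $2^{\lceil \log_2(F+1) \rceil}$ runs —
built by the standard Hadamard parity construction — assigns each
factor en bloc to parent 1 or parent 2 per run. Every run's candidate
is repaired to the exact budget $r$ by random swap-repair *before*
evaluation, so every chromosome ever evaluated satisfies the budget
invariant. The main effect of each factor is the difference of mean
CC between its two levels over the array rows; `child1` composes each
factor from the parent with the better main effect, `child2` is the
best evaluated run candidate. The factor cap bounds the cost of one
crossover at $2^{\lceil \log_2(F+1)\rceil} + 1 \le 9$ evaluations.

### Multi-run aggregation

Because the GA is stochastic, `run_ibcga_replicates()` repeats the run
(default 10, matching the 10-fold reporting style) with consecutive
seeds and reports mean ± SD of CC, MAE and signature size, plus each
feature's selection frequency — features selected in most runs are the
robust core of the signature.

## MED ranking

To order the members of a chosen signature by importance, each feature
becomes a factor of a two-level orthogonal array (level 1 = included,
level 2 = excluded); each array row's subset is scored by the shared
10-CV CC, and the main effect difference
$\mathrm{MED}(f) = |\,\overline{CC}_{f\,\text{in}} -
\overline{CC}_{f\,\text{out}}\,|$ ranks the features. CC is used as
the response because it is the fitness the search optimized. Rows
with no included feature are skipped; a single-feature signature
reports its own CC as the score (the exclusion mean does not exist);
ties break alphabetically, and the signature is canonicalised to
alphabetical factor order so the fractional design — and hence the
scores — do not depend on input order. `full_factorial = TRUE`
evaluates all $2^s$ subsets (exact main effects, small signatures
only), and `method = "loo"` gives the leave-one-out sensitivity
variant $CC(\text{sig}) - CC(\text{sig} \setminus f)$.

## Baselines

`fit_lasso_cv()`, `fit_elasticnet_cv()` and `fit_mlr_cv()` implement
the standard linear competitors under the *identical* outer fold
partition (glmnet with seeded inner 5-fold CV for the penalty; the
elastic-net mixing weight from a small grid; OLS by QR). The
comparison table runs all four methods on shared folds. The MLR row
needs a feature subset; by default it reuses the LASSO-selected
subset — a reconstruction, since no canonical selection route exists
for plain MLR — and any explicit subset can be supplied instead.

## Validation on a living cohort

Living patients give only a lower bound on survival: their follow-up
time. The protocol predicts each living patient and counts the
estimate as consistent when it strictly exceeds the follow-up (ties
count as not-exceeding); the fraction of consistent patients is the
classification accuracy, and the MAE between estimate and follow-up is
reported over the remaining patients only. Summaries use the sample
(n−1) SD and months = years × 12 exactly. This is a weak but fully
censored-data-honest check: it can prove an estimate too short, never
too long.

## The synthetic generator

`simulate_cohort()` exists so every stage is testable without any
data download. It emulates: right-skewed non-negative expression
(per-feature lognormal by default, gamma optional); survival driven by
a small planted subset, linear in within-cohort z-scores — so effect
sizes are in years per SD and comparable across features — with an
optional fraction of squared (nonlinear) contributions, winsorized at
|z| = 3 and centred by the unit second moment so a single extreme
sample of a skewed feature cannot dominate the cohort, plus additive
Gaussian noise; and a living cohort whose follow-up is
$u \cdot \text{true survival}$, $u \sim U(0.2, 1.3)$, so follow-up
both under- and overshoots the truth and the validation protocol
exercises both outcomes. If any survival would fall at or below the
30-day intake filter the cohort is shifted up, preserving the linear
form up to its intercept, so no synthetic sample is silently dropped.

Defaults are fixed once to mirror the target cohort shape: 369
patients of whom a censor fraction of 160/369 is routed to the living
cohort (leaving 209 deceased), 415 features, 10 signal features with
effect magnitudes declining from 0.8 to 0.4 years/SD with alternating
sign, intercept 3 years, noise SD 0.5 years, nonlinear fraction 0.2.
What the generator does *not* emulate: negative-binomial sequencing
noise, batch structure, or correlated miRNA families — so passing
tests demonstrate algorithmic correctness and planted-signal
recovery, not clinical performance on real cohorts.

## Numerical and design choices

* Fold partition: seeded shuffle chopped into near-equal folds;
  every sample is predicted exactly once.
* Correlation degeneracies: both vectors constant is an error; one
  constant (a degenerate predictor) scores 0 rather than NA so the GA
  can keep going.
* Budget repair in crossover flips uniformly chosen bits; repair
  happens before evaluation so the budget invariant holds for every
  evaluated chromosome.
* Tie-breaks are total and deterministic (CC, then MAE, then
  first-seen), making whole runs bit-reproducible given the seed.
* Model handles serialize to versioned JSON (support vectors, dual
  coefficients, rho, scaling); the reloaded handle predicts from the
  kernel expansion directly and matches in-memory predictions to
  numerical precision.

## Problem sizes used in the shipped tests

The test-suite and the acceptance script run on scaled-down cohorts —
60–220 samples, 12–50 features, budgets swept over
$r \in [5, 20]$ with populations of 16–20 — chosen so a full suite
run completes comfortably on a laptop CPU while still giving the GA a
search space (binom(50, 10) ≈ 10^10 subsets) it cannot brute-force.
The acceptance script additionally runs the full default-shape cohort
(369 × 415) through the data-io path with a reduced GA schedule.

## Known limitations

* The GA cost is dominated by nu-SVR fits; at TCGA scale
  (~200 × 400+) a full default schedule (50 budgets × 50 individuals
  × 30 generations) is an overnight run on one core.
* MED on a fractional array aliases main effects with interactions;
  `full_factorial = TRUE` removes this for small signatures.
* The living-cohort accuracy depends on the censoring distribution;
  it is comparable between models on the same cohort, not across
  cohorts.
* No Kaplan–Meier estimation, log-rank testing or hazard ratios are
  provided; survival-curve analysis belongs to dedicated packages.
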