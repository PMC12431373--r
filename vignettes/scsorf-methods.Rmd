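---
title: "Swarm-optimized random forests for gallstone screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swarm-optimized random forests for gallstone screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`scsorf` implements a wrapper pipeline for clinical tabular classification:
a Sand Cat Swarm Optimization (SCSO) engine searches jointly over feature
subsets and random forest hyperparameters, fold-wise winners are
consolidated into one deployable configuration, and the fitted model is
interrogated with exact Shapley attribution and diverse counterfactual
search. The reference application is gallstone screening from a 38-feature
clinical table (demographics, bioimpedance, laboratory values) with a
binary target coded 0 = gallstones present, 1 = absent. This vignette
documents the models, the tunable parameters, the numerical choices, and
what the synthetic experiments do and do not establish.

## Data model and evaluation protocol

The canonical cohort has 319 records (161 disease-present, 158 absent) and
no missing values; the loader rejects any NA or non-numeric cell outright
rather than imputing. Evaluation uses **ten repeated shuffled 70/30
splits**. A partition-style 10-fold cross-validation of 319 rows cannot
produce 224 training and 95 test samples per fold, so although protocols
of this shape are often labelled "10-fold CV", the implementation is
explicitly repeated hold-out: each split draws `ceiling(0.7 * n)` training
rows (224 of 319) independently. Splits are stratified by label so each
split's class ratio matches the cohort within one sample; stratification
is a package choice (the protocol is otherwise silent), justified by the
near-balanced cohort and the stability of fold means, and it can be
switched off only by relabelling. Split generation is a pure function of
the row order and the seed.

## The sand cat swarm

SCSO is a population metaheuristic modelled on the low-frequency hearing
of hunting sand cats. A swarm of `pop_size` agents (default 50) moves
through a bounded box for `max_iter` iterations (default 100). The
swarm-wide *general sensitivity* decays linearly from `SM = 2` to 0,

```
isen(t) = SM - 2 * SM * t / (2 * tmax),
```

and controls two per-agent draws each iteration: a search radius
`r = isen * U(0,1)` and a phase parameter `R = 2 * isen * U(0,1) - isen`.
When `|R| > 1` the agent explores, moving relative to the best candidate
position (`new = r * best - U(0,1) * current`, fresh uniform per
dimension); when `|R| <= 1` it pounces, at a roulette-wheel angle `theta`
drawn uniformly over integer degrees 0–360:

```
loc_rnd = |U(0,1) * best - current|   (per dimension)
new     = best - r * loc_rnd * cos(theta)
```

Numerical choices worth stating:

* **Absolute value in `loc_rnd`.** Without it a signed radius makes the
  angled pounce overshoot unboundedly; the absolute-value form is the
  original algorithm's and is what we implement.
* **Randomness granularity.** `r` and `R` are drawn once per agent per
  iteration; the uniforms inside the two step formulas are drawn fresh per
  dimension for better space coverage.
* **Bounds.** Hard clamp after every update; every evaluated position is
  feasible.
* **Elitism and ties.** The recorded best is replaced only by a strictly
  better fitness, so the best-fitness history is non-decreasing and ties
  keep the first solution found. There is no separate candidate memory:
  the best-candidate and best positions both refer to the global
  best-so-far.
* **Known fitness ceiling.** `scso_control(target_fitness = ...)` stops
  the search once the recorded best reaches a known maximum. Because ties
  never replace the incumbent, no later evaluation can change the returned
  optimum or the (saturated) history, so the stop is exact, not an
  approximation. The classifier wrapper uses this with the F1 ceiling of 1.

On convergence precision: the pounce refines at rate
`r * |U(0,1) * best - current|`, which shrinks with the sensitivity
schedule but not multiplicatively towards an arbitrary optimum. On a 5-D
quadratic bowl with the default budget the swarm lands within 0.5 of the
optimum in most but not all seeded runs (median distance below 0.1), and
it comfortably dominates pure random search at an equal evaluation budget
— which is the property the package asserts. Benchmark reports of
near-zero error on sphere functions rely on the optimum sitting at the
origin, where the update's shrinkage is an artifact of the geometry.

## The wrapper problem

The search space concatenates four integer forest hyperparameters, a
feature-count dial, and one continuous saliency per feature:

| coordinate | range | meaning |
|---|---|---|
| phi1 | 100–300 | number of trees |
| phi2 | 3–10 | maximum tree depth |
| phi3 | 2–20 | minimum samples to split |
| phi4 | 1–10 | minimum samples per leaf |
| phi5 | 1–38 | number of selected features |
| saliency (×38) | [0, 1] | per-feature selection score |

Decoding rounds the five integers half-up then clamps, and selects the
`phi5` features with the largest saliencies, ties broken by the lowest
index. This encoding is a package design choice: the feature-count dial is
part of the published search space but the mechanism mapping a continuous
position to a discrete subset is not specified anywhere, and top-k
saliency makes the subset a deterministic, total function of the position.

The classifier is **delegated**, never re-implemented: a Gini-criterion
probability forest from `ranger`, with the four hyperparameters mapped to
`num.trees`, `max.depth`, `min.node.size` and `min.bucket`, a fixed seed
per fold, and single-threaded prediction for determinism.

**Fitness is the training-set F1 by default.** This is the only reading
consistent with the reference pipeline's observed behaviour (fitness
saturating at 1 within the first epochs) and with the absence of any inner
validation split in its procedure. It has a real consequence: once many
candidates reach F1 = 1 the fitness cannot discriminate among them, and
with first-best-kept ties the fold winner is effectively the first
saturating candidate encountered. Feature subsets selected under a
saturated fitness are therefore weakly constrained, which is precisely why
the consolidation stage unions them rather than intersecting. A
`holdout_f1` mode (inner stratified 80/20 split) is provided for users who
want fitness to keep discriminating after saturation.

## Consolidation

Across the ten splits the pipeline produces ten (subset, hyperparameter)
winners. The final configuration takes the **union** of the subsets —
keeping any feature deemed important in at least one fold — and the
**per-parameter statistical mode** of each hyperparameter, ties broken by
the smallest value so the result is deterministic and invariant to fold
order. On the published worked example this yields a 13-feature union with
modes (290, 10, 2, 1), which the test suite asserts verbatim.

## Metrics and diagnostics

Confusion-based metrics use an explicit, configurable positive label. The
package default is 1 ("absence"): the reference worked example's printed
precision/recall are reproduced from its confusion matrix only under that
convention (its prose narrates the same counts with the labels swapped).
Accuracy is `(tp + tn) / n` — the product form sometimes seen in print is
a typographical slip, identifiable because the printed 81.25% equals
78/96. Undefined 0/0 ratios are reported as 0 with a warning rather than
NaN so batch fold reports never fail. AUC is the Wilcoxon rank statistic
with midranks for ties, equal to brute-force concordant-pair counting.

Cramér's V drives the univariate association screen. Continuous features
must be discretized first; the package defaults to quartile (4-bin)
quantile binning, configurable, with the classic (bias-uncorrected)
formula. Published association values for continuous features depend
entirely on the unstated binning and are not reproduction targets.

The misclassification profiler tabulates per-feature means over cases
misclassified in a given clinical direction. Here the clinical convention
applies (disease-present = 0 is the positive class): a false negative is a
disease-present case predicted absent. The overfitting diagnostic refits
the forest over a range of maximum depths and reports the train-minus-test
accuracy gap; on synthetic data shallow forests show gaps of a few points
while unconstrained depths push training accuracy to 100% and the gap into
double digits.

## Interpretability

**Exact Shapley attribution.** Feature contributions are computed by full
subset enumeration with the factorial-weighted sum, using an
*interventional* value function: the value of a coalition is the mean
model probability over a background sample whose coalition columns are
overwritten with the explained instance's values. The conditioning choice
is the package's (the published description leaves `h_R` unspecified);
the background defaults to a seeded subsample of the training slice capped
at 100 rows. Enumeration is exponential and guarded at 16 features — the
13-feature consolidated model fits comfortably. Exactness buys the
efficiency identity `base + sum(phi) = prediction` to 1e-9 on every
explanation, and the test suite checks the enumeration against an
independent permutation-average oracle. Probabilities refer to class 1
("absence"), so a negative attribution pushes towards the disease-present
class; the predicted class is read out at the 0.5 threshold.

**Diverse counterfactuals.** Candidate sets of size `k` are scored by
mean hinge loss on the probability margin to the target class, plus
`lambda1` times the mean proximity cost, minus `lambda2` times a
determinantal-point-process diversity term — the log-determinant of the
similarity kernel `K_ij = 1 / (1 + dist(c_i, c_j))`. Proximity is L1
weighted by the inverse per-feature median absolute deviation of the
training data (zero MADs fall back to 1), giving a scale-free distance.
Defaults `lambda1 = 0.5`, `lambda2 = 1` follow the reference
counterfactual tooling's conventions; the determinant is floored at 1e-12
before the log so duplicate candidates degrade gracefully. The search
reuses the swarm over the `k × |actionable|` perturbation box; only
actionable features ever change (the natural clinical actionable set here
is CRP, Vitamin D and AAST), and candidates predicted in the target class
are flagged valid. Fewer than `k` valid candidates is reported via flags
and a diagnostic, not an error.

## The synthetic generator

Real screening data cannot ship with the package, so every stage is
exercised on a seeded generator emulating the schema: binary comorbidity
flags, small categorical codes, integer demographics, and continuous labs
with plausible clinical centres and spreads, all class-independent except
for a configurable set of signal features drawn class-conditionally. The
default signal triple uses the published class means of the three dominant
labs — CRP 0.46 (present) vs 3.27 (absent), Vitamin D 24.90 vs 17.83,
AAST 23.91 vs 19.41. CRP is modelled lognormal (non-negative,
right-skewed, matching its observed 0–13.9 range) with the arithmetic
mean fixed to the target and log-scale sd 0.75; Vitamin D and AAST are
normal with sd 8 and 7, clamped at zero. The spreads are package choices
made once: no class-conditional dispersions are published, and these give
realistic lab variability with moderate class overlap rather than trivial
separability.

What the generator does *not* emulate: inter-feature correlation (no
copulas), measurement noise structure, or site effects. Consequently,
passing the planted-recovery experiment shows that the pipeline's
selection and consolidation mechanics retain informative features under
realistic effect sizes — it does not certify performance on real cohorts,
where correlated features can share credit and the union may grow or
shrink accordingly.

## Problem sizes and reproducibility

The packaged experiments use the cohort-scale defaults: n = 319,
10 splits, population 20 with 30 iterations for the recovery harness
(20 seeds), population 50 with 100 iterations for single-fold
demonstrations, backgrounds capped at 100 rows, and 5-D benchmark bowls
over 20 seeds. Every stochastic component is seeded: the split plan, the
swarm, each forest fit, the background subsample and the generator, so an
end-to-end run is reproducible bit for bit apart from wall-clock timing
fields, which are isolated in the timing reports.

## Known limitations

* Training-set fitness cannot rank candidates past saturation; use
  `holdout_f1` when discrimination matters.
* Exact Shapley is exponential; 16 features is a hard guard, and larger
  models need sampling approximations the package deliberately omits.
* The DPP diversity term uses a fixed kernel; no learned plausibility
  model constrains counterfactual realism beyond the range box and MAD
  scaling.
* Cramér's V on continuous inputs is binning-dependent by construction.
* The swarm's terminal precision on smooth problems is limited by its
  update geometry (see above); it is a feature-selection workhorse, not a
  high-precision continuous optimizer.
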