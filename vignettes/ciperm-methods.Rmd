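---
title: "Modeling ex vivo placental barrier permeability with ciperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ex vivo placental barrier permeability with ciperm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciperm)
```

## The problem

The placental barrier moderates fetal exposure to drugs and environmental
chemicals. Ex vivo perfusion of term placentas measures how readily a
chemical crosses the barrier; the standard summary is the clearance index

$$\mathrm{CI} = \frac{\text{clearance of the chemical}}
                     {\text{clearance of antipyrine}},$$

a dimensionless, nonnegative ratio that normalizes away inter-placental
variability (antipyrine crosses by passive diffusion and serves as the
reference). Perfusion experiments are slow and tissue-limited, so a
quantitative structure–activity relationship (QSAR) model that predicts CI
from computable molecular descriptors is valuable for prioritization.

ciperm implements a complete, deliberately small-data-oriented QSAR
workflow for this setting: tables of one to a few thousand precomputed 1D/2D
descriptors (e.g. PaDEL output) over fewer than a hundred chemicals.
Everything downstream is designed around two constraints of that regime:
severe risk of overfitting, and the need for an applicability domain that
is honest about which predictions can be trusted.

## The pipeline

### 1. Uninformative-descriptor removal

Three filters run sequentially, each on the survivors of the previous one,
so every removed feature is attributed to the first criterion that fired:

1. **Extreme values** — the largest |x| exceeds 100 times the average |x|.
   With n ≤ ~100 rows a maximum can never be 100-fold larger than a mean
   that *includes* it (the maximum contributes more than 1/100 of such a
   mean), so the reference average excludes the candidate maximum
   (a leave-one-out mean). The all-inclusive reading is available via
   `filter_config(extreme_mean = "all")` for comparison.
2. **Scarcity** — the fraction of exactly-zero entries is at least 30%
   (inclusive boundary: exactly 30% is scarce). Zeros are compared exactly;
   descriptor values are computed quantities whose zeros are structural,
   not rounded.
3. **Low variation** — fewer than 12 distinct values (strict boundary:
   exactly 12 distinct values is retained).

### 2. z-score normalization

Each surviving descriptor is centered and scaled, $z = (x - \mu)/\sigma$,
with $\mu$ the arithmetic mean and $\sigma$ the population standard
deviation (divisor $n$), both estimated **on the training table only** and
applied unchanged to every later table. Applying anything else would leak
test information into preprocessing. Some published tables are scaled by
the population *variance* instead of the SD; `fit_normalizer(scale =
"variance")` reproduces that convention for parity experiments.

### 3. Models

Three regressors share one interface:

* `linear` — ordinary least squares with intercept. Stable on small n but
  can underfit.
* `forest` — a regression CART forest. Flexible but prone to overfitting
  small tables.
* `ensemble` — a voting regressor whose prediction is the equal-weight mean
  of the two components. The premise is that descriptors worth keeping
  should be informative for both a linear and a non-linear learner, which
  regularizes the wrapper selection below.

The forest is implemented inside the package (C++): `n_trees` bootstrap
trees, squared-error splits, **all** features considered at every split,
split ties broken by lowest feature index then lowest threshold, and an
internal seeded RNG, so any fit is bit-reproducible from its seed on any
platform. This matters because the selection wrapper compares LOOCV scores
across thousands of candidate sets; library forests are neither fast enough
at this fit size (a fit here costs well under a millisecond) nor
reproducible across versions and platforms at the tie-break level. The
defaults are 100 trees and a minimum node size of 5 — 100 trees because
importance estimates and LOOCV scores are unstable with fewer on 60-90
chemicals, node size 5 following the usual regression-forest convention.
The test suite cross-checks predictions and importance orderings against
an independent implementation (ranger).

Impurity importance is the forest's per-feature sum of split
variance-reductions, normalized to sum to one.

### 4. Sequential forward selection under LOOCV

The wrapper adds, at each step, the descriptor that maximizes the Pearson
correlation between observed CI and leave-one-out cross-validation
predictions of the current candidate set; ties go to the lower column index
of the input table, so a run is fully determined by the table, spec and
seed. The first feature is accepted unconditionally; afterwards a step must
improve LOOCV r by at least 0.01. The "1% improvement" rule is interpreted
as an **absolute** increment of 0.01 in r (with r around 0.85 the relative
reading differs negligibly; `relative = TRUE` provides it). Selection stops
at the first step that falls short, and that step is kept in the trace as
rejected, so the stopping decision is auditable.

Two pragmatic choices follow the pipeline's order of operations: LOOCV
folds reuse the globally normalized table rather than renormalizing per
fold (normalization happens once, before selection; `loocv(strict = TRUE)`
refits per fold for sensitivity analysis), and every candidate evaluation
reuses the spec's seed so forest-based scores are comparable across
candidates. A candidate whose fold fit fails — a collinear duplicate, for
instance — scores `-Inf` and is logged rather than aborting the run.
`max_features` defaults to `min(n - 2, 30)` as a runaway guard.

### 5. Applicability domain from training LOOCV errors

The domain is defined by *exclusion rules* learned from the training set
only:

1. each training chemical's absolute LOOCV error becomes the target of a
   regression tree (rpart) grown on the selected descriptors;
2. every leaf yields a candidate rule — the conjunction of its root-to-leaf
   threshold conditions, tagged with the leaf's mean absolute error;
3. candidates are ranked by that error, descending;
4. rules are appended one at a time and kept only if the Pearson r between
   observed CI and the *frozen* LOOCV predictions over the not-yet-excluded
   chemicals improves by at least 0.01; the first rejection stops the loop.
   The tree is grown once and the model is never refit during this loop.

A chemical is out of domain when it satisfies **all** conditions of **at
least one** accepted rule (conjunctive within a rule, disjunctive across
rules). Because membership depends on descriptor values alone, the domain
can be applied to tables that carry no measured CI at all — there is no
residual-based leak of test information, which is precisely the failure
mode of leverage/residual applicability domains this construction avoids.

Tree settings are necessarily a design choice: depth 3 and at least 5
chemicals per leaf favour few, interpretable, non-singleton rules on a
60-90 chemical table, and `cp = 0` leaves pruning decisions to the
rule-acceptance loop. All are configurable through `ad_tree_control()`.
rpart's own (deterministic) handling of exactly tied split gains is
accepted as-is. Rule thresholds live in normalized units; the JSON
serializer embeds the normalization parameters so thresholds can also be
displayed in raw descriptor units. Two degenerate cases are handled
explicitly: constant LOOCV errors yield an empty rule set (coverage 1) with
a note, and because tree leaves partition descriptor space some candidate
eventually covers every chemical still retained — such a candidate can
never demonstrate an improvement and therefore ends the loop as a
rejection, with a note in the model.

Boundary convention: conditions use `<=` and `>` (closed on the left). Tree
thresholds are midpoints between observed values, so the convention never
affects training chemicals, only hypothetical exact-boundary queries.

### Metrics

Performance is summarized as the sample Pearson correlation between
observed and predicted CI (for fitting, LOOCV, and independent test) plus
the mean absolute error; single external predictions are additionally
judged by the relative absolute error |obs − pred|/obs, reported as `NA`
when the observed value is zero. For external sets with reported
experimental variation, evaluation against the minimum CI within variation
(`ci_min`) complements the evaluation against the reported mean CI.

`rank_features()` reproduces the usual two-view feature ranking of an
ensemble: rank by |OLS coefficient| and by forest importance (both
descending), then rank the sum of the two ranks, ties sharing the smaller
rank.

## The synthetic study conditions

`synthetic_spec()` encodes the data regime the workflow targets, and its
defaults are the package's reference conditions: 66 chemicals; 5
informative standard-normal descriptors with linear coefficients
(1, 0.85, 0.7, 0.6, 0.5) plus one mild multiplicative interaction
(strength 0.3) between the first two — enough non-linearity to give the
forest something the linear model cannot capture; 95 pure-noise
descriptors; Gaussian noise with SD 0.2 on the response (clearly
detectable but non-trivial signal at n = 66); and 20 decoys engineered to
violate exactly one filter criterion each (10 scarce, 5 extreme, 5
low-variation), each also engineered *not* to trip an earlier filter, so
the expected removal report is known by construction. The CI is kept
nonnegative by shifting the intercept rather than truncating, which keeps
the generative model exactly linear. External tables (default 7 chemicals)
reuse the training table's generative coefficients and add a positive
experimental variation with `ci_min = max(ci - variation, 0)`.

What the generator deliberately does **not** emulate: the heavy mutual
correlation of real autocorrelation descriptors, heteroscedastic assay
noise, any relationship between a decoy's filter pathology and the
response, and the numeric range of experimental clearance indices (the
synthetic CI spans roughly 0–7 because five unit-scale effects add up,
whereas measured CI values rarely exceed ~1.5; correlations are
scale-free and absolute errors should be read relative to this span). Passing the synthetic suites therefore demonstrates that the
machinery is correct and recovers planted structure under the stated
conditions — not that any particular descriptor set predicts real placental
transfer.

## Numerical and reproducibility choices

* All randomness is seeded: the generator through R's RNG (restoring
  `.Random.seed` afterwards), the forest through its own splitmix64-based
  RNG, so results are identical across platforms and standard-library
  versions.
* Model files are JSON with numbers written at 17 significant digits,
  which round-trips IEEE doubles exactly; forests are refit
  deterministically from the stored training block and seed on load rather
  than serialized tree-by-tree, keeping artifacts small, readable and
  exactly reproducible (the loader verifies the stored OLS coefficients
  against the refit).
* Missing values are rejected at load time, never imputed.
* Constant features make z-scoring undefined and are reported as errors by
  name (the filters remove them in the normal flow).
* Singular designs are an error in `fit`; inside selection they only
  disqualify the candidate.

The test suite exercises the pipeline at the reference conditions
(66 × 120 tables, ensembles of 50 trees across 20 seeds for the end-to-end
recovery check; 50 seeded replicates for selection properties; 200
replicates for OLS coefficient recovery), sizes chosen to make the
statistical assertions stable without being wasteful.

## Known limitations

* The workflow consumes precomputed descriptor tables; it does not compute
  descriptors from structures.
* Greedy forward selection is not guaranteed to find the globally best
  subset, and with heavily correlated descriptors the chosen representative
  of a correlated block is somewhat arbitrary (the deterministic tie-break
  makes it at least reproducible).
* The applicability domain inherits CART's axis-aligned geometry; smooth
  or oblique unreliability regions will be approximated by boxes.
* With n under a hundred, LOOCV correlation has substantial variance;
  the 0.01 acceptance thresholds should be read as pragmatic conventions,
  not significance tests.
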