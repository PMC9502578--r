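# ciperm

Ensemble QSAR modeling of ex vivo placental barrier permeability.

The placental barrier moderates fetal exposure to drugs and environmental
chemicals. Ex vivo perfusion of term human placentas quantifies transfer as
the **clearance index**

```
CI = clearance of the chemical / clearance of antipyrine ,
```

a nonnegative, dimensionless ratio (antipyrine is the passive-diffusion
reference). Perfusion experiments are slow and tissue-limited; ciperm builds
quantitative structure–activity relationship (QSAR) models that predict CI
from precomputed 1D/2D molecular descriptors (e.g. PaDEL tables), for the
small-n, wide-table regime such datasets live in (tens of chemicals, up to
~1,500 descriptors).

The workflow, end to end:

1. **Descriptor filtering** — remove uninformative descriptors: extreme
   values (max |x| > 100 × the leave-one-out mean |x|), scarcity (≥ 30%
   exact zeros), low variation (< 12 distinct values).
2. **z-score normalization** — `z = (x − μ)/σ`, with μ and σ estimated on
   the training set only and applied unchanged to any later table.
3. **Sequential forward selection** — greedily add the descriptor that
   maximizes the Pearson correlation `r` between observed CI and
   leave-one-out cross-validation (LOOCV) predictions; stop when the best
   addition improves r by less than 0.01.
4. **Voting ensemble** — final predictor
   `ŷ = ½ ŷ_OLS + ½ ŷ_RF`, the equal-weight mean of an ordinary
   least-squares model and a regression random forest (seeded,
   deterministic, implemented in C++ inside the package).
5. **Applicability domain** — grow a regression tree on the training
   chemicals' absolute LOOCV errors, turn each leaf into a conjunctive
   threshold rule, rank rules by leaf mean error, and keep a rule only if
   excluding its chemicals improves the retained-set LOOCV r by ≥ 0.01.
   Chemicals matching an accepted rule are flagged out-of-domain; the
   domain uses descriptor values only, so no measured CI of a test set is
   ever consulted.

A synthetic-data module generates tables with the exact statistical
structure the pipeline assumes (planted informative features, noise
features, and decoys that each violate one filter criterion), so every
stage is testable without any external data.

## Worked example

```r
library(ciperm)

tab <- generate_descriptor_table(synthetic_spec(seed = 7))
tab
#> <descriptor_table> 66 chemicals x 120 features
#>   targets: ci

res <- run_train(tab, spec = model_spec("ensemble", n_trees = 50, seed = 7))
res$trace
#> <sfs_trace> 5 features accepted (final LOOCV r = 0.9716, threshold = 0.01)
#>   step feature   loocv_r improvement accepted
#> 1    1   INF01 0.4620184          NA     TRUE
#> 2    2   INF02 0.6936220 0.231603650     TRUE
#> 3    3   INF05 0.8224017 0.128779688     TRUE
#> 4    4   INF03 0.9100695 0.087667780     TRUE
#> 5    5   INF04 0.9716471 0.061577626     TRUE
#> 6    6  RND062 0.9733334 0.001686297    FALSE
```

The trace reads: the five planted informative descriptors (`INF01`–`INF05`)
are picked in order of effect size, each accepted step raising the LOOCV
correlation by at least 0.01; the sixth candidate (a noise feature) would
only add 0.0017 and is rejected, stopping the selection. The twenty decoy
descriptors never get this far — the filter report
(`res$filter_report`) shows 5 removed for extreme values, 10 for scarcity
and 5 for low variation, leaving exactly the 100 informative + noise
columns.

```r
res$model
#> <ci_model> kind = ensemble | 5 features | 66 training chemicals
#>   linear coefficients:
#> (Intercept)       INF01       INF02       INF05       INF03       INF04
#>   4.3780273   0.9778878   0.9176889   0.5819397   0.6881115   0.5624226

res$ad
#> <ad_model> 0 exclusion rule(s); training coverage 100.00% (66/66)

ext <- generate_external_table(synthetic_spec(seed = 7))   # 7 chemicals
run_evaluate(res$model, ext, "ci", ad = res$ad)$full
#> <evaluation> against = ci | n = 7
#>   pearson_r = 0.9778   mae = 0.3308
```

The OLS coefficients track the generator's true effect sizes
(1, 0.85, 0.7, 0.6, 0.5 — features are z-scored, so coefficients are per
SD); here the LOOCV errors are homogeneous enough that no exclusion rule
clears the 1% bar, so the applicability domain keeps all 66 training
chemicals. `rank_features(res$model)` combines the OLS and
forest-importance views into the overall ranking (rank of rank sums, ties
sharing the smaller rank).

A thin command-line wrapper with `simulate`, `split`, `train`, `predict`
and `evaluate` subcommands lives at `inst/cli/ciperm.R`:

```sh
Rscript inst/cli/ciperm.R simulate --seed 7 --out table.csv
Rscript inst/cli/ciperm.R train --table table.csv --seed 7 --out artifacts/
```

See `vignettes/ciperm-methods.Rmd` for the model assumptions, parameter
choices and limitations.

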