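# glandmark

Dynamic risk prediction from longitudinal cohort data by **generalized
landmark analysis (GLA)**, with the classical landmark analysis (LA) and
the static prediction model (SPM) as built-in baselines, and a
censoring-adjusted validation protocol for comparing them.

## The problem and the method

In longitudinal cohorts (think of a chronic kidney disease registry:
annual clinic visits, an eGFR-like biomarker declining over time, a
terminal event such as ESRD or death), a risk prediction is wanted at
*every* visit, from the covariates measured at that visit. The
conventional SPM regresses follow-up time on baseline covariates only,
discarding all follow-up measurements and any resemblance between its
training population and the follow-up population where predictions are
used.

Landmark analysis stacks one record per at-risk visit — covariates
$Z_{ij}$ at visit time $t_{ij}$ paired with residual survival
$T_{ij} = T_i - t_{ij}$ and event indicator $\delta_i$ — and lets the
model parameters vary with the landmark time $t_{ij}$. GLA generalizes
the index from landmark *time* to an arbitrary landmark *variable*
$V$ (for example the current biomarker value), using the working model

$$\lambda(u \mid Z) = \lambda_0(u, V)\,\exp\{\beta(V)^{\mathsf T}\bar Z\},$$

estimated by kernel-weighted Cox regression: records near the query
subject's current $V^*$ get Epanechnikov (or uniform, i.e. caliper
matching) weights with a span-based adaptive bandwidth (the
$\lceil\gamma N\rceil$-th smallest distance), and a weighted Cox model
with a weighted Breslow baseline hazard turns the neighborhood into a
horizon-$\tau$ event probability
$p^* = 1 - \exp\{-\widehat\Lambda_0(\tau) e^{\hat\beta^{\mathsf T}(Z-c)}\}$.
Setting $V$ = `"time"` recovers classical LA exactly; a full-span
uniform kernel recovers the pooled landmark "super model"; the SPM is
the pooled fit restricted to baseline rows (all three identities are
enforced by tests).

Model comparison uses time-dependent AUC and Brier score with inverse
probability of censoring weighting, computed under a half-split
cross-validation protocol with subject-level bootstrap confidence
intervals, reported as relative Brier and absolute AUC differences
against a benchmark. A longitudinal-survival simulator with controllable
coefficient drift over the biomarker makes every estimator testable
without access to restricted registry data.

## Worked example

```r
library(glandmark)

# a simulated chronic-disease cohort: ~annual visits, declining biomarker,
# binary covariate whose log hazard ratio drifts over the biomarker range
x <- simulate_cohort(simulator_config(n_subjects = 500, seed = 7))
x
#> <gla_cohort> 500 subjects, 2531 visits, 255 events
#> covariates: biomarker, age, z

lm <- build_landmark_dataset(x)

# GLA localized on the biomarker, span 0.3, 3-unit prediction horizon
gla <- predictor_config("GLA", kernel_spec("biomarker", span = 0.3),
                        covariates = c("age", "z"), horizon = 3)

# risk for a query visit with a low biomarker value
q <- data.frame(visit_time = 2, biomarker = -2, age = 62, z = 1)
p <- predict_gla(lm, gla, q)
p
#> <risk_prediction> P(event within 3) = 0.6657
attr(p, "fit")
#> <local_cox_fit> 3 coefficient(s), 465 baseline event time(s), converged in 4 iteration(s)
#>          age            z    biomarker
#> -0.003357904  1.029565022 -0.254866110
```

The local fit at biomarker $-2$ recovers the generator's local log
hazard ratio of $+1$ for `z` (the pooled value is near 0 because the
effect flips sign across the biomarker range — exactly what localization
is for). Comparing GLA against the SPM benchmark:

```r
spm <- predictor_config("SPM", covariates = c("age", "z", "biomarker"),
                        horizon = 3)
res <- cross_validated_compare(x, methods = list(gla = gla), benchmark = spm,
                               horizons = 3, n_splits = 2, n_boot = 200,
                               seed = 1, boot_mode = "predictions",
                               grid_size = 10)
res[, c("auc", "brier", "benchmark_auc", "benchmark_brier",
        "delta_rel_brier", "delta_rel_brier_lo", "delta_rel_brier_hi")]
#>      auc  brier benchmark_auc benchmark_brier delta_rel_brier
#> 1 0.7883 0.1427        0.7535          0.1517         -0.0596
#>   delta_rel_brier_lo delta_rel_brier_hi
#> 1            -0.1085            -0.0029
```

A relative Brier difference of $-6\%$ (95% bootstrap interval excluding
zero) means the localized model is better calibrated than the static
benchmark on the follow-up visits of the validation halves.

A thin command-line front end over the same functions lives in
`inst/cli/gla.R` (subcommands `simulate`, `fit`, `predict`,
`select-span`, `evaluate`; one YAML config; every run writes a
`manifest.json` with the config snapshot, seed, and input digests):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/gla.R", package="glandmark"))')" \
  simulate --config run.yaml --out-dir out
```

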