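---
title: "Generalized landmark analysis: model, estimation, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized landmark analysis: model, estimation, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glandmark)
```

## The prediction problem

Longitudinal cohort studies of chronic disease follow subjects through
repeated clinic visits until a terminal event (for example, end-stage
renal disease or death in a kidney-disease cohort) or censoring. At any
visit a clinician wants the probability that the event occurs within the
next $\tau$ time units, given everything measured at that visit. The
conventional approach — a Cox regression of follow-up time on baseline
covariates, here called the static prediction model (SPM) — ignores all
post-baseline measurements and is trained on a population (the baseline
cohort) that can differ systematically from the follow-up population in
which predictions are actually needed.

Landmark analysis (LA) instead stacks the data: every visit $j$ of
subject $i$ at time $t_{ij}$ before the observed follow-up time $T_i$
contributes a record pairing the visit's covariates $Z_{ij}$ with the
*residual* survival time $T_{ij} = T_i - t_{ij}$ and the subject's event
indicator $\delta_i$. Model parameters are allowed to change with the
landmark time $t_{ij}$. That indexing is only meaningful when baseline
is a risk-changing clinical milestone (transplant surgery, treatment
start). In observational cohorts of chronic disease, "time since
enrollment" has no clinical interpretation.

Generalized landmark analysis (GLA) replaces the landmark *time* with a
landmark *variable* $V$ — any time-varying prognostic variable, ideally a
strong one such as an eGFR-like biomarker. The working model for the
residual-survival hazard at a visit with covariates $Z$ is

$$\lambda(u \mid Z) \;=\; \lambda_0\!\left(u, V\right)\,
  \exp\!\left\{\beta(V)^{\mathsf T}\bar Z\right\}, \qquad u \ge 0,$$

where $\bar Z$ is the covariate vector without $V$, whose effect is
absorbed into the baseline hazard. Both $\lambda_0(u, V)$ and $\beta(V)$
are estimated nonparametrically in $V$ by kernel weighting: for a query
subject with landmark value $V^*$, each training record receives weight
$W_{ij} = K_h(|V^* - V_{ij}|)$ and a weighted Cox model is fitted to the
stacked records. Localizing on $V = $ "time" recovers classical LA, and a
uniform kernel makes the procedure identical to caliper matching on $V$.
Because repeated records of one subject can carry positive weight, the
fit uses working independence; all uncertainty statements come from
subject-level resampling.

## Localization: kernels, spans, matching

- **Kernels.** Epanechnikov $K_h(d) = (4h)^{-1}(1 - (d/h)^2)\,
  1(|d/h| \le 1)$ (default) and uniform $K_h(d) = (2h)^{-1} 1(|d/h| \le 1)$.
  The multiplicative constants are kept as written even though the
  functions then do not integrate to one: the weighted partial likelihood
  is invariant to the weight scale, which the fitter makes exact by
  normalizing weights to mean one. Local-polynomial theory says the
  kernel shape matters far less than the bandwidth; only the local
  constant (kernel) estimator is implemented.
- **Span.** Rather than a fixed bandwidth, the default is adaptive: with
  span $\gamma \in (0, 1]$ the bandwidth is the
  $\lceil \gamma N \rceil$-th smallest distance between $V^*$ and the $N$
  training values — an order statistic without interpolation, so a
  uniform kernel is guaranteed to match at least $\lceil \gamma N \rceil$
  records even where $V$ is sparse. A zero quantile (mass of ties at
  $V^*$) falls back to the smallest positive distance.
- **Standardization.** Landmark variables are divided by their
  training-set standard deviation before distances are formed (default
  on), so spans mean the same thing for variables on different scales and
  weights are invariant to unit changes. Fixed bandwidths, by contrast,
  are interpreted on the variable's original scale, preserving the
  caliper-matching reading. Whether to standardize before forming
  bivariate weights is genuinely open; the flag makes the choice
  explicit.
- **Bivariate localization** uses a product kernel over per-variable
  distances with per-variable span-derived bandwidths: a record must fall
  inside the support of *both* variables. More than two landmark
  variables are deliberately unsupported; the curse of dimensionality
  makes such neighborhoods empty at realistic sample sizes.
- **Sparse-neighborhood guard.** A local fit needs events. If the
  weighted event count (discounted by relative weight) in the
  neighborhood falls below `min_events` (default 10), the weights
  constructor raises an error that names the smallest span on a 0.05 grid
  that would satisfy the guard, rather than silently widening the
  neighborhood.

## The weighted Cox engine

The weighted partial log-likelihood (working independence, Breslow
handling of tied residual times) is maximized by Newton–Raphson with
step-halving (up to 20 halvings), starting at $\beta = 0$, with
covariates centered at their weighted means for numerical stability.
Convergence requires a relative log-likelihood change below $10^{-9}$ or
a score norm below $10^{-7}$, within 100 iterations. Breslow ties were
chosen because the weighted Efron correction is nonstandard and the
weighting composes cleanly with Breslow risk sets. Three degenerate
regimes are handled explicitly:

- covariates constant across the positive-weight records are dropped
  with a warning; if none remain the fit degrades to the null model
  (baseline hazard only), which keeps one-record neighborhoods
  well-defined;
- a coefficient norm exceeding `coef_bound` (default 50) flags monotone
  likelihood (perfect separation) instead of iterating forever;
- neighborhoods with no events are an error.

The weighted Breslow cumulative baseline hazard
$\widehat\Lambda_0(u) = \sum_{t_k \le u} d_k / \sum_{R(t_k)} W e^{\eta}$
is stored as a right-continuous step function; the predicted event
probability within horizon $\tau$ is
$p^* = 1 - \exp\{-\widehat\Lambda_0(\tau)\, e^{\hat\beta^{\mathsf T}(Z - c)}\}$,
evaluated at the largest jump $\le \tau$. Horizons beyond the largest
residual event time in the neighborhood are flagged as extrapolations.
No model-based variance is computed: downstream uncertainty is
bootstrap-based throughout.

By default the landmark variable also enters the linear predictor of the
local fit (`adjust_landmark_linear`), which removes within-neighborhood
trend bias — important with the larger neighborhoods that bivariate
localization forces. The exception is localization on `"time"` alone,
where classical LA absorbs the landmark time entirely into the baseline
hazard, so the adjustment defaults to off there.

## Validation protocol

Accuracy at horizon $\tau$ is measured by the time-dependent AUC
(cumulative cases, dynamic controls) and the time-dependent Brier score,
both censoring-adjusted with inverse-probability-of-censoring weights
(IPCW). The censoring survival $G$ is a Kaplan–Meier estimate on the
validation records with the event indicator flipped. Cases
($T_{ij} \le \tau$, $\delta = 1$) weigh $1/G(T_{ij}^-)$, controls
($T_{ij} > \tau$) weigh $1/G(\tau)$, and records censored before $\tau$
weigh zero; prediction ties earn half credit in the AUC. With no
censoring these reduce exactly to the Mann–Whitney statistic and the
plain mean squared error, which the test suite verifies against
enumeration oracles. These are the standard cumulative/dynamic IPCW
constructions; incident/dynamic variants are out of scope.

`cross_validated_compare()` implements the half-split protocol: subjects
are split into equal training and validation halves; every method is
fitted on the training half; predictions are made at every eligible
validation visit (optionally restricted to strata such as biomarker bands
or visit-time bands); metrics get 95% percentile intervals from
subject-level bootstrap resampling of the training and validation halves
independently; and everything is averaged over split repetitions
(defaults: 5 splits, 2000 resamples, mirroring common practice; the test
suite scales these down). Because a subject's repeated visits are
correlated, the bootstrap resamples *subjects*, never rows. Two bootstrap
modes exist: `"refit"` (default) refits all models on each training
resample, which is the honest interpretation of repeating the
model-fitting in every resample; `"predictions"` is a labeled fast mode
that keeps the fits fixed and resamples only the validation records, so
its intervals reflect evaluation noise only. Comparisons against the
benchmark are reported as the relative Brier difference
$(\mathrm{BS}_m - \mathrm{BS}_b)/\mathrm{BS}_b$ and the absolute AUC
difference, the scales on which these two measures are informative.

How the SPM should predict at follow-up visits is underdetermined: the
model is trained on baseline rows, but validation visits are not
baseline. The default (`spm_mode = "current"`) plugs the visit's current
covariate values into the baseline-trained model and reads the predicted
probability over $[0, \tau]$ of the baseline time scale — the only
reading that yields visit-level predictions comparable with the dynamic
methods; `"baseline"` carries the subject's baseline covariates forward
instead. Both are implemented and the choice is recorded in the config.

**Span selection.** `select_span()` scores a candidate grid by
cross-validated Brier score (the more sensitive measure, since it uses
the probability values and not just their ranks), then applies a one-SE
rule: among spans whose Brier score is within one bootstrap standard
error of the best, the smallest is selected, because a smaller span
retains more parameter variation over the landmark variable. There is no
assumption of a U-shaped span-accuracy curve.

**Per-query cost and the grid approximation.** The reference semantics
refit one weighted Cox model per validation visit. For large validation
sets, `grid_size = G` fits local models at $G$ quantile points of a
single landmark variable and linearly interpolates each query's *log*
cumulative hazard at $\tau$ between the two neighboring grid fits
(clamping outside the grid). Interpolating on the log scale interpolates
the whole linear predictor, including the intercept-like baseline term,
and is well-behaved across hazard magnitudes. On simulated cohorts the
approximation stays within 0.02 of per-query probabilities at
`grid_size = 25` (tested); it is off by default.

## The cohort simulator

Because the motivating registry datasets are restricted-access, the
package ships a simulator whose default configuration defines the
benchmark conditions used across the tests and the acceptance script. It
emulates the structure of a chronic-disease cohort: roughly annual visits
(gap $1 \pm 0.1$, at most 8 visits), a declining strong biomarker on a
standardized scale following a linear mixed trajectory
($b_{0i} \sim N(0, 2^2)$, slope $N(-0.1, 0.05^2)$, measurement noise SD
0.2), an age-like fixed covariate $N(60, 10^2)$ that carries no effect by
default, a Bernoulli(0.5) binary covariate, and independent censoring
(exponential rate 0.04 plus an administrative cutoff at 10), yielding an
event fraction near 0.54. The hazard is
$\lambda(t) = 0.08\,\exp\{-0.2\,V(t) + \beta_z(V(t))\, z\}$ with the
drifted design $\beta_z = +1$ for $V \le -0.5$, $-1$ for $V \ge 0.5$,
linear between — so the *true local coefficient* is known exactly at any
interior query point, which is what the parameter-recovery tests need.
`simulator_config_homogeneous()` sets $\beta_z$ constant (0.5) as the
no-drift control, under which a single pooled model is essentially
correctly specified and localization should not help.

Event times are drawn by exact inversion of the piecewise-constant
hazard on a latent grid (default resolution 0.05 time units,
configurable; the null-effects closed form is verified to
Kolmogorov–Smirnov precision at $n = 5000$), evaluated on the *latent*
trajectory so the coefficient drift is honored between visits.

What the simulator does **not** emulate: informative visit schedules,
missing covariates, nonlinear biomarker trajectories, competing risks —
and, deliberately, it makes no attempt to generate data under which the
landmark working models are correctly specified at *all* landmark
values, a recognized open difficulty (the working models at different
landmark values are mutually incoherent). Passing tests therefore show
that the estimators recover known local structure and rank methods
correctly under controlled drift, not that the working model is true for
any real cohort.

## Problem sizes and numerical choices in the test suite

The test suite and acceptance script use sizes chosen to make
Monte-Carlo conclusions stable: coefficient recovery uses 20 replicates
of 1000 subjects at span 0.2; the method comparison uses 20 drifted and
10 homogeneous replicates of 1000 subjects with 2 split repetitions and
200 bootstrap resamples in the fast prediction-resampling mode (the mode
affects interval width only, not the point estimates being compared);
fitter cross-checks run on dozens of small random datasets against both
a derivative-free maximizer of the enumerated partial likelihood and
`survival::coxph` with Breslow ties. Tiny random datasets occasionally
exhibit monotone likelihood (no finite optimum); those are excluded from
coefficient-agreement checks since neither routine converges to a
comparable value.

## Known limitations

- No competing risks, interval censoring, recurrent events, or
  left-truncation adjustments; one terminal event, independent right
  censoring.
- Local-constant estimation only; no local-linear weighting.
- At most two landmark variables.
- The working models at different landmark values are not mutually
  coherent — predictions are honest only as visit-specific residual-risk
  statements, not as a joint survival process.
- Missing covariate values are dropped, not imputed.
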