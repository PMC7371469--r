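---
title: "Simulating prediction-model performance under shifting missing-data mechanisms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating prediction-model performance under shifting missing-data mechanisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misshift)
```

## The problem

Routinely collected health data — electronic health records above all — are
full of missing values, and the missingness is often *informative*: whether a
biomarker was measured at all depends on how sick the clinician thought the
patient was. A prediction model can harvest that signal, most simply by
imputing missing values with a constant and adding a binary missing-indicator
covariate. The catch is transportability: the indicator's predictive value is
a property of the *measurement behaviour* that generated the development
data. If deployment changes that behaviour — clinicians start measuring
everyone, or measurement becomes effectively random — a model that leaned on
the indicator can calibrate badly or lose discrimination entirely.

`misshift` turns this argument into a reproducible simulation experiment:
develop models under informative missingness, then deploy them under four
different missingness regimes and measure what happens.

## The data-generating mechanism

Each synthetic subject carries two independent Uniform(0,1) predictors: $P$,
potentially observed, and $U$, never available to the prediction model. The
binary outcome is

$$\Pr(Y = 1 \mid P, U) = \operatorname{expit}(-5 + 3P + 5U),$$

giving an outcome prevalence of 34.3% (the quadrature value of the mean risk
over the unit square is 0.3433). Informative missingness masks $P$ with

$$\Pr(R = 1 \mid P, U) = \operatorname{expit}(3 - 2P - 2U - 4PU),$$

where $R = 1$ means "$P$ is missing". Low-$P$, low-$U$ (low-risk) subjects
are the most likely to go unmeasured, and because the mechanism involves the
unobserved $U$ the missingness is missing-not-at-random: the indicator
carries outcome information that $P$ itself cannot. The marginal missingness
rate implied by these coefficients is 51.9% — "about half" of subjects.
`true_risk` is always computed from the true $P$, even after masking,
because prediction error is defined against the generating mechanism.

Masking is represented by an explicit flag `R` plus a maskable `P_observed`
column (`NA` when masked) rather than any sentinel value: `P = 0` is a legal
value, and zero imputation writes a genuine 0 on purpose.

## Handlers, models, scenarios

Four handling strategies are applied — identically at development and at
application, as a deployed system would:

* **zero imputation**: missing `P` becomes 0, plus a missing indicator;
* **mean imputation**: missing `P` becomes the mean of the *current
  cohort's* observed values, plus the indicator;
* **complete-case analysis (CCA)**: only subjects with observed `P` are
  fitted and predicted;
* **multiple imputation (single draw)**: predictive mean matching (PMM)
  using the observed `P` and the outcome `Y`, producing one imputed dataset.

The prediction model is a plain binary logistic regression of `Y` on the
prepared `P` (plus the indicator where the method adds one), fitted by
iteratively reweighted least squares with tolerance `1e-8` and at most 100
iterations. The tight tolerance matters: two of the package's invariants —
that the zero- and mean-imputation designs are exact reparameterizations of
each other, and that the indicator saturates the missing group at its
empirical outcome rate — hold only up to optimizer precision. Complete
separation on small cohorts is flagged (`converged = FALSE`) rather than
fatal, so simulation sweeps degrade gracefully. $U$ is never available to
the prediction model; it exists only in the truth and missingness machinery.

A developed model is then deployed on an independent application cohort
under four scenarios: (1) the development mechanism again, (2) no missing
values, (3) missing completely at random with probability 0.5 — implemented
as independent Bernoulli(0.5) draws per subject, not an exact half split,
mirroring the Bernoulli form of the informative mechanism — and (4) `P`
missing for everyone. A reference model fitted and evaluated with `P` fully
observed completes the grid. Scenario 4 admits only zero imputation (there
are no observed values to average, no complete cases, and no PMM donors);
those cells are recorded as not applicable rather than failing the run.

## PMM details

Chained-equations software defaults are not printed anywhere authoritative
for this design, so the package fixes and records them explicitly in the
handler state: one imputation ($m = 1$), donor pool of 5, type-1 matching
(donor predictions from the OLS point estimate of `P ~ Y` among observed
subjects; target predictions from a Bayesian draw of the coefficients, with
residual variance drawn from a scaled inverse chi-square), and uniform donor
selection. When predicted-value distances tie at the pool boundary, *all*
tied donors enter the pool before the uniform draw — with a binary `Y` the
imputation model produces only two distinct predicted values, so this
tie-inclusive rule effectively makes PMM a within-outcome-stratum hot deck
here, and it removes any dependence on row ordering. Imputed values are
always observed donor values, hence always inside the observed support.

A deliberate peculiarity, reproduced because the study protocol handles
missing data "the same way" in both phases: application-time mean imputation
and PMM recompute from the application cohort — including using `Y`, which a
real deployment would not know. The alternative (carrying the development
mean forward) is inconsistent with scenario 4 having no mean-imputation
cell, which requires that the application cohort supply the observed values.

## Metrics

Five measures per (scenario, method) cell, each computed only over subjects
that actually received a prediction (CCA at application time evaluates the
retained subset):

* mean and SD of the prediction error $\hat p_i - \pi_i$ against the true
  risk $\pi_i$ (positive = over-prediction; the SD uses the sample $n-1$
  denominator);
* RMSPE, $\sqrt{\tfrac1n \sum (\hat p_i - \pi_i)^2}$ (population
  denominator);
* the c-statistic as the tie-corrected Mann–Whitney statistic, computed via
  midranks in $O(n \log n)$ and cross-checked in the test suite against an
  exhaustive $O(n^2)$ pair count — constant predictions give exactly 0.5;
* the Brier score;
* calibration-in-the-large as the intercept of a logistic recalibration
  model with the logit of the predictions as a fixed offset (predictions
  clipped to $[10^{-10}, 1-10^{-10}]$ first); 0 means mean-calibrated,
  negative means over-prediction. The offset-intercept definition (rather
  than a difference of mean logits) is the standard recalibration form, and
  it makes self-fitted predictions score exactly 0 by the intercept score
  equation.

The sign convention for prediction error was chosen so that a positive mean
error coheres with a negative calibration-in-the-large on the same
predictions; it is the only convention consistent with nearly all cells of
the experiment simultaneously.

## Randomness and reproducibility

A study takes one master seed. From it a deterministic sequence of child
seeds is derived (via one `sample.int()` stream) for: the development
cohort, development missingness, the application cohort, per-scenario
application missingness, development and per-scenario imputation draws, and
plot subsampling. Consequences worth knowing: changing the mechanism never
changes `P`, `U` or `Y`; every cell is independently reproducible; and two
runs with the same configuration are identical. Multi-replication mode
(`replications > 1`) repeats the whole pipeline on independent substreams
and reports across-replication means, SDs and Monte Carlo standard errors —
single-run numbers at $n = 20000$ carry sampling noise of roughly 0.003–0.006
on the c-statistic, so conclusions about small differences need the
replication summary, not one run.

## What the defaults are and why

| Parameter | Default | Why |
|---|---|---|
| `n_dev`, `n_app` | 20000 | the study conditions; large enough that metric noise is a few thousandths |
| outcome model | $(-5, 3, 5)$ | gives 34% prevalence with both predictors material |
| missingness model | $(3, -2, -2, -4)$ | informative, MNAR, ~52% marginal rate |
| `mcar_rate` | 0.5 | scenario 3 matches the development missingness *rate* while destroying its information |
| `donor_count` | 5 | conventional PMM pool size |
| `tolerance` | `1e-8` | needed for the reparameterization and saturation identities |
| plot `jitter` | 0.02 | visual separation of the point masses at the indicator value; raw values are always retained alongside |
| plot `sample_size` | 500 | enough to show structure without overplotting |

## What the generator does and does not emulate

The generator reproduces a deliberately minimal world: one partially
observed predictor, one latent predictor, cross-sectional measurement, a
logistic truth, and missingness mechanisms that are constant over time.
Real EHR data have many correlated predictors with interlocking missingness
patterns, measurement timing that is itself informative, feedback between
deployed models and clinician behaviour, and drift. Passing this package's
tests therefore demonstrates that the *mechanism* — informative missingness
exploited at development, lost or transformed at deployment — behaves as
described, not that any particular real-world model will degrade by the
amounts seen here.

## Numerical choices and degenerate inputs

Empty designs, single-class outcomes, and metric calls on empty vectors
raise typed errors (`misshift_degenerate_fit`, `misshift_undefined_metric`)
rather than returning silent `NaN`s. Handlers that cannot run raise
`misshift_handler_inapplicable`, which the pipeline converts to a
not-applicable cell. The PMM regression adds a tiny ridge only if the
observed design is singular (all observed subjects sharing one outcome
class). The c-statistic is computed in double precision throughout — the
case/non-case pair count exceeds 32-bit integer range well below the default
cohort size.

## Problem sizes used by the test suite

Unit tests run on cohorts of a few hundred to 5000 subjects; distributional
checks use 20 replicate cohorts of 20000 or single cohorts of 100000–200000
where a tight standard error is the point; the acceptance checks run the
full default study once with 20 replications. All of it completes in a few
minutes on a single core.

## Known limitations

* One incomplete predictor only; no chained equations across several
  variables, no passive imputation, no pooling over $m > 1$ imputations.
* The application-time use of `Y` in mean imputation and PMM reproduces the
  study protocol and is unrealistic for genuine deployment; treat the MI
  cells as a property of the protocol, not a recommendation.
* Calibration is summarised in the large only — no calibration slope or
  smoothed calibration curves.
* The four scenarios are static snapshots; the feedback loop by which a
  deployed model changes measurement behaviour over time is motivation, not
  something simulated here.
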