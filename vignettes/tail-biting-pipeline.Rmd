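---
title: "Predicting tail-biting events from pen sensor streams: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting tail-biting events from pen sensor streams: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Tail biting in groups of finisher pigs is a welfare and economic problem: by
the time a bleeding tail wound is found, the damage is done. The pipeline in
`pigwatch` turns routinely available pen-level sensor streams — water flow
(L/h) and drinker activation frequency (starts/h), summed over a pen's two
drinker sensors, and hourly mean pen temperature above the solid and the
slatted floor — into a daily per-pen probability that a tail-biting event is
imminent, so a farmer can pay extra attention to the flagged pens.

The pipeline has five stages, each a module of this package:

1. **Dynamic linear models** (`dlm_spec()`, `dlm_filter()`) describe each
   stream's expected pattern and emit standardized one-step forecast errors.
2. **Daily features** (`build_feature_table()`) summarize each pen-day.
3. **Per-source classifiers** (`cv_optimize()`,
   `train_final_and_threshold()`) distinguish event from control pens.
4. A **fixed-probability logistic model** (`fit_fixed_model()`) supplies a
   weekly baseline risk from the pen's housing conditions.
5. A **Bayesian ensemble** (`bayes_update()`,
   `realtime_daily_probabilities()`) fuses the sources, and the
   **evaluation** module scores everything (`roc_auc()`,
   `realtime_evaluate()`).

A seeded synthetic barn (`simulate_barn()`) generates pens, streams and event
schedules so the full pipeline can be exercised and validated without any
farm data.

# The dynamic linear model

Each hourly stream $Y_t$ is modelled univariately as

$$Y_t = F' \theta_t + v_t, \qquad v_t \sim N(0, V),$$
$$\theta_t = G\, \theta_{t-1} + w_t,$$

with an eight-dimensional state: a local linear trend (level and hourly
slope) plus three harmonic waves with 1, 2 and 3 peaks per 24 h
($\omega = 2\pi/24$), stored in sine-cosine form. The system matrix is
block-diagonal — a $2\times2$ trend block $\begin{pmatrix}1&1\\0&1\end{pmatrix}$
and one $2\times2$ rotation block of angle $N\omega$ per wave — and the
design vector picks the level and each wave's cosine coordinate. Water flow
and activation frequency are square-root transformed before modelling
(`sqrt_transform()`); temperatures enter untransformed.

Parameters and their defaults:

* **Observational variance `V`** is held constant and set to a percentage of
  the series mean (on the modelling scale). Defaults per source: 7.50%
  (water flow), 16.00% (activation frequency), 0.40% (solid-floor
  temperature), 0.65% (slatted-floor temperature). The percentage is
  calibrated by `calibrate_obs_variance()`: it is the grid value whose pooled
  standardized forecast errors have sample standard deviation closest to 1 —
  the simplest criterion consistent with the requirement that the errors be
  approximately standard Gaussian, and monotone in the variance scale.
* **Discount factor** $\delta \in (0,1]$ replaces an explicit state-evolution
  covariance: the one-step prior covariance is
  $R_t = G C_{t-1} G'/\delta$ (`discount_covariance()`), applied to the
  whole state with a single discount per source. Defaults: 0.98, 0.97, 0.88,
  0.88 for the four sources. `calibrate_discount()` searches the 21-value
  grid 0.80–1.00 (step 0.01) and minimizes one-step forecast RMSE; the MAE
  minimizer is also computed and a disagreement is logged, with RMSE taking
  precedence (no tie rule is otherwise defined).
* **State prior $\theta_0$** comes from a harmonic regression of the
  training values on a linear time term and the 24/12/8-hour sine/cosine
  terms, pooling the no-event training pens with a pen-level random
  intercept (`lme4::lmer`; a fixed-effects `lm` is the fallback for a single
  pen or a failed mixed fit). Only the prior is affected: after a burn-in of
  a day or two the filter dominates. $C_0$ is a diffuse diagonal, 10 times
  the series variance — large enough to forget the prior quickly, finite
  enough to keep early forecast variances numerically tame.

**Standardized errors.** The one-step error is standardized as
$u_t = e_t / \sqrt{Q_t}$. The square root is deliberate: only with it do the
errors from a correctly specified model approach a standard Gaussian, which
is the stated purpose of the standardization (dividing by the variance
itself would leave the errors on an arbitrary scale). Missing hours — the
temperature streams lack the first hour of each day — propagate the state
without an update, and their `e`, `u` are absent; there is no imputation.

Time is hour-indexed from pen insertion; day $d$ (1-based) covers hours
$24(d-1)+1, \dots, 24d$, and week $w = \lceil d/7 \rceil$.

# Daily features and classifiers

For each pen-day-source the six order/location statistics (min, Q1, mean,
median, Q3, max; quantile type 7 — no rule is otherwise implied) are computed
twice, on the raw natural-scale values and on the standardized forecast
errors, giving 12 predictors. Days with at least one but fewer than 24
observed hours are summarized over the observed subset; all-missing days are
dropped. Predictors are z-scored with statistics computed on the training
pens only, globally per source (not per batch — the smallest-variance choice
for a single-herd data set); test data reuse the training statistics.

Each event pen (first tail-biting day = day 0) is matched to one control pen
from the same batch with the same straw and space levels and no event, so
training is exactly balanced; because most event pens have two eligible
controls, two training sets are built and one network trained per set.
Three alarm types select the contributing days: UNTIMED ($-3,-2,-1$),
BEFORE ($-3,-2$) and ON ($-1$).

The architecture grid crosses four activations (rectifier and two-piece
maxout, each with and without dropout 0.5) with six size choices: one hidden
layer of 2/3, 1 or 4/3 times the 12 predictors, or two hidden layers with
the second factor tied to the first — giving exactly 24 configurations. The
tied-factor reading is an interpretation: an unconstrained second factor
would give 48 combinations, contradicting the stated total of 24.
`cv_optimize()` runs leave-one-pair-out cross-validation (per-pen prediction
is the maximum daily probability over the alarm-type days, classified at
0.5) and picks the accuracy-maximizing configuration, ties going to fewer
parameters then grid order.

The trainer itself (`mlp_train()`) is a small fully connected network with
sigmoid output, binary cross-entropy loss and full-batch Adam, seeded and
with early stopping on a training-loss plateau. The optimiser, epoch count
and initialisation are free choices here. One non-obvious default matters: a
ridge penalty (`l2 = 0.05`). The training sets hold only a few dozen
pen-days, and without the penalty the networks memorize them, so their
training-set evaluation degenerates to sensitivity = specificity = 1 and the
accuracy-maximizing threshold collapses to the smallest tied value. Those
three numbers are exactly what the Bayesian ensemble consumes, and a
(1, 1)-member makes every Bayes update all-or-nothing, erasing the prior.
The default keeps the training evaluation honest; it was chosen as the
weakest penalty that avoids the degeneracy on training sets of this size.

After the search, one network per training set is trained on the full set
and the classification threshold is swept over 0.01–1.00 (step 0.01) on the
training pen-level predictions, keeping the accuracy-maximizing value
(smallest on ties — the more sensitive choice) with its sensitivity and
specificity. At prediction time the two networks' probabilities are
averaged; the ensemble uses the averages of the two sets' thresholds,
sensitivities and specificities.

# Fixed probability

Independent of the sensors, a pen's housing predicts its weekly risk. One
observation per pen-week (indicator: any tail-biting event that week) feeds
a main-effects logistic regression on tail docking, straw provision, space
allowance and week. Week enters as a 10-level categorical factor: the
reference weekly risk profile is non-monotone (a sharp drop from week 6 to
7), which a linear term cannot represent. No interactions are included; the
reference table is numerically consistent with pure main effects, which the
package verifies by logit-additive reconstruction
(`logit_additive_reconstruction()`): any cell is recoverable from three
same-week cells. Pens keep contributing pen-weeks after their first event,
since daily recording continues.

Threshold search is week-banded: weeks 1–6 use the 100-value grid 0.01–1.00
(step 0.01), weeks 7–10 the 91-value grid 0.001–0.010 (step 0.0001),
reflecting the late-study drop in risk; sensitivity and specificity are then
pooled over all ten weeks.

# Bayesian ensemble

The first member's predicted probability is the prior $P(TB)$; every further
member contributes a binary alarm (its probability thresholded at its
training threshold) through Bayes' theorem with its training sensitivity and
specificity:

$$P(TB \mid +) = \frac{sens \cdot p}{sens \cdot p + (1-spec)(1-p)}, \qquad
  P(TB \mid \div) = \frac{(1-sens) \cdot p}{(1-sens)p + spec(1-p)}.$$

The posterior is permutation-invariant over the non-first members; only the
choice of prior member changes the result. A degenerate $0/0$ update
(a perfect member contradicted by the evidence) returns the prior rather
than failing. Pen-days missing any member output are skipped and logged.

# Evaluation

Sensitivity, specificity, alarm error rate $FP/(TP+FP)$ and accuracy are
exact ratios of the confusion counts; zero-denominator metrics are reported
as absent. The ROC curve sweeps the 100-value threshold grid, appends the
$(0,0)$ and $(1,1)$ endpoints and integrates by trapezoids; the 95% CI uses
the Hanley–McNeil standard error with $z = 1.96$ exactly, clipped to
$[0,1]$. Training uses the accuracy criterion, test evaluation the highest
sensitivity + specificity.

Two protocols:

* **Pen-level**: each test-batch event pen is matched to 4–5 eligible
  controls (accuracy is not usable at this imbalance); the pen prediction is
  the maximum daily probability over the alarm-type days.
* **Day-level (real-life)**: every pen-day is scored, and alarms are
  clustered over the 3 days before each first tail-biting event — any alarm
  in the window is one true positive, none is one false negative; every
  other alarmed day is a false positive, every other quiet day a true
  negative. The event day itself and the day after count as false positives
  in the confusion counts but are also tallied separately, as are alarms in
  the 3-day windows before fouling and diarrhoea events (many "false" alarms
  precede those). $N_2$ for the CI is the number of non-window days.

# The synthetic barn

`simulate_barn()` emulates the study conditions end to end:

* Balanced $2^3$ factorial assignment of tail docking, straw and space over
  the pens; group size 18 (low space) or 11 (high).
* Hourly streams: level + slope $\times$ hour + three harmonic waves +
  Gaussian noise with variance pct/100 of the series mean on the modelling
  scale, using the four default percentages above. Water sources are
  generated on the square-root scale and squared back (negative draws
  clipped at 0 and counted); hour-0 temperatures are masked missing. The
  diurnal shapes are qualitative — a two-peak-dominant water pattern, a
  weaker activation pattern of the same form, single-peak temperature
  patterns with a slow downward trend matching a 21→17 °C ventilation curve
  over the period; the exact amplitudes are configurable defaults, not
  asserted constants, since no authoritative values are available.
* Weekly tail-biting hazard per treatment cell and week from the reference
  risk table shipped in `inst/extdata/` (the same table the logit-additivity
  check uses); first-event days are uniform within the week, resampled to
  day ≥ 4 so a full 3-day pre-event window exists. Fouling and diarrhoea
  follow independent weekly Bernoulli schedules (defaults 5% and 3% per
  pen-week) with no injected sensor signal of their own.
* Pre-event deviations on days −3..−1: +15% water flow, +10% activations,
  −0.5 °C above the solid floor, none above the slatted floor. No field
  magnitudes exist for these shifts, so they are free parameters whose
  defaults are justified empirically: the zero-deviation profile is the
  negative control, and with it the pipeline's day-level AUC is statistically
  indistinguishable from 0.5, while the default profile yields an AUC whose
  95% CI excludes 0.5. Deviations are never applied on day 0 or later — the
  pipeline is meant to alarm before serious tail damage.

What passing tests on this generator do and do not show: the generator has
identical diurnal parameters across pens, stationary noise, no sensor
failures beyond the hour-0 gap, and a pre-event signature of known form.
Real barns add between-pen heterogeneity, weather, management events and
event signatures of unknown shape; synthetic performance is therefore a
correctness check of the machinery, not a forecast of field performance.

# The packaged experiment

`run_synthetic_experiment()` wires everything: one training batch (default
32 pens) and one held-out test batch (28 pens), 10 weeks each; DLM priors
fitted on the training batch's no-event pens; UNTIMED features; two-network
training per source; Bayesian fusion of water flow (prior) and solid-floor
temperature (alarm member) — the two informative sources; day-level
evaluation with 3-day clustering on the test batch. The default
configuration list is a single rectifier network; passing
`grid = enumerate_grid()` runs the full 24-configuration search per training
set. The packaged test suite runs the experiment with the single-network
default to keep the suite fast; the cross-validation search itself is tested
separately on small constructed rosters.

Problem sizes used by the packaged checks: 5,040-hour streams for the
standardized-error and parameter-recovery checks (10 pooled pens for the
latter — pooling pens is exactly what the prior-estimation step does, and
the smallest temperature wave, 0.04 °C against 0.28 °C noise, needs the
pooled information to be estimated to within 10%); 60 pens for the
end-to-end experiment.

# Numerical choices and degenerate inputs

* Covariances are symmetrized after every Kalman update; forecast variance
  is strictly positive by construction ($Q = F'RF + V$, $V > 0$).
* A filter burn-in of 48 hours is discarded inside the calibration
  functions.
* Constant feature columns are centred but not rescaled (sd guard), logged.
* Threshold ties always break toward the smaller threshold.
* Complete separation in the fixed-probability fit stops with guidance to
  enlarge the sample; a week band with no events takes the band-maximum
  threshold, logged.
* Non-finite training loss triggers reinitialisation with a shifted seed, at
  most three times.

# Known limitations

* The ensemble consumes training-set sensitivities and specificities, which
  are optimistic even with the ridge penalty; cross-validated estimates
  would be less biased but are not part of the protocol implemented here.
* The fouling/diarrhoea schedules carry no sensor signature, so the
  day-level fouling/diarrhoea tallies on synthetic data reflect chance
  overlap only.
* The day-level CI treats days as independent, which ignores within-pen
  correlation; this mirrors the evaluation protocol rather than improving
  on it (DeLong-type or cluster-robust intervals are out of scope).
* Smoothing (a backward pass), multivariate state-space models and online
  re-calibration of the variance or discount are deliberately not
  implemented.
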