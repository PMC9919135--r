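---
title: "Flow correction for active-pumping e-nose trace-gas calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flow correction for active-pumping e-nose trace-gas calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Quantifying nitric oxide at parts-per-billion levels with an electrochemical
sensor in an active-pumping chamber faces a confound: the pump suction flow
changes how much gas reaches the sensor surface and how vigorously it mixes
there, so the equilibrium voltage at a fixed concentration varies with flow.
Across the 200–1200 SCCM working range the effect is unimodal — responses
grow with flow up to about 1000 SCCM and fall off beyond it — and large
enough that a calibration ignoring flow misreads concentrations by well over
10 % of full scale. `enoseflow` corrects this by calibrating concentration
jointly on the sensor response and the measured flow.

This vignette records the package's models, parameters, numerical choices,
and limitations. Everything quantitative stated here is computed by the test
suite or by `scripts/acceptance.R`; nothing is quoted from external data.

## The synthetic bench experiment

Real bench campaigns for this instrument are a factorial design: six target
concentrations spanning the FeNO-relevant range (5, 25, 35, 50, 100,
200 ppb) crossed with six pump flows (200–1200 SCCM), two replicate runs
per cell — 72 runs, one five-minute acquisition at 10 Hz each. Replicate 1
is used for model fitting, replicate 2 for testing. `generate_design()` and
`simulate_dataset()` reproduce this layout so the entire pipeline runs
without any external data.

Each simulated run has two channels:

* NO channel: `v(t) = v0 + S * (c / 200) * g(q) * (1 - exp(-t / tau_r)) + e(t)`,
  a first-order rise to a plateau proportional to concentration `c` and to
  the flow gain `g(q)`, with i.i.d. Gaussian noise `e(t)`.
* Flow channel: the set flow `q` plus i.i.d. Gaussian noise.

`g(q)` is a log-scale Gaussian bump with separate widths below and above its
peak, equal to 1 at 1000 SCCM. Defaults (`sim_params()`):

| parameter | default | units | rationale |
|---|---|---|---|
| `baseline_voltage` | 0.05 | V | small zero-gas offset |
| `sensitivity` | 3.0 | V at 200 ppb, unit gain | puts plateaus in the sub-3 V range of a typical acquisition card |
| `rise_time_constant` | 20 | s | electrochemical-sensor response time; equilibrium within ~2 min of a 5-min run |
| `gain_width_low` / `gain_width_high` | 2.82 / 0.48 | — | gain ≈ 0.85 at 200 SCCM and ≈ 0.93 at 1200 SCCM, matching the bench ordering 200 < {400, 600, 1200} < {800, 1000} with a ~15 % spread |
| `noise_sd_voltage` | 0.05 | V | after the default 51-sample smoothing, the trace keeps a 1–2 % coefficient of variation at mid-range plateaus |
| `flow_noise_sd` | 5 | SCCM | sub-percent pump pulsation |

The asymmetry of `g` (broad on the low-flow side, sharp above the peak) is
forced by the ordering it must reproduce: 1200 SCCM responses fall back to
the 400–600 SCCM band while 800 and 1000 SCCM stay on top. The ~15 % gain
spread means a flow-blind calibration carries errors around 15–20 % of full
scale at the extremes, which is what the correction is for.

Seeding: every run's noise stream is seeded by a stable hash of
(concentration, flow, replicate) combined with the master seed, so datasets
are pure functions of `(design, params)` and independent of row order.

What the generator does *not* emulate: temperature and humidity effects,
sensor drift between runs, non-Gaussian noise, and any nonlinearity of the
sensor in concentration (the plateau is exactly proportional to `c`). Tests
passing on this generator therefore validate the pipeline's statistics and
optimization, not robustness to those real-world effects.

## Preprocessing and features

The NO channel is smoothed with a centered moving average (default window
51 samples ≈ 5 s at 10 Hz; edges shrink symmetrically), the flow channel
with tricube local-linear loess (`stats::lowess`, span 0.3, no robustness
iterations). Each smoothed channel is reduced to five summary features —
maximum, mean, median, Q1, Q3 (type-7 quartiles, i.e. linear interpolation
between order statistics) — and features are paired by kind, so each run
yields exactly five calibration samples `(x1 volts, x2 flow, y ppb)`. The
36 training runs yield 180 samples, matching the protocol's training-set
size. The flow feature is divided by 1000 (SCCM → SLPM) so both model
inputs are order one; the divisor is recorded in the samples and model
metadata.

Because the features are taken over the whole run including the rise phase,
the five kinds are slightly different linear images of the same plateau
(the run-mean sits ~7 % below the maximum with the default 20 s time
constant). Pooling kinds is part of the protocol; it adds a small
irreducible spread that every calibrator shares.

## Two-factor ANOVA and LSD subsets

`two_way_anova()` implements the balanced two-factor decomposition with
interaction from cell, marginal and grand means:

```
SSA  = s*t * sum_i (Xbar_i.. - Xbar)^2          df = r - 1
SSB  = r*t * sum_j (Xbar_.j. - Xbar)^2          df = s - 1
SSAB = t * sum_ij (Xbar_ij. - Xbar_i.. - Xbar_.j. + Xbar)^2
                                                df = (r-1)(s-1)
SSE  = sum_ijk (X_ijk - Xbar_ij.)^2             df = rs(t-1)
```

with `SST = SSA + SSB + SSAB + SSE` an identity (tested to 1e-10 relative on
randomized tables, and against a naive-loop oracle and `stats::aov`). The
error term uses deviations from the *cell* mean — the only reading under
which the partition is an identity. F statistics are mean-square ratios
against MSE; p-values come from the F distribution and are printed as
`<0.001` when tiny rather than as zero.

The pipeline's ANOVA response is one feature kind per run (default `mean`),
so the within-cell replicates are the true replicate runs; with a single
replicate the interaction is inestimable and the pipeline stops with a
clear error. `lsd_subsets()` then compares flow levels:
`LSD = t_{1-alpha/2, df_E} * sqrt(2 * MSE / n)`, levels sorted by mean and
swept into maximal contiguous subsets whose extreme means differ by less
than the LSD; each subset carries the p-value of its extreme pair
(singletons report 1). Assumption checks are thin wrappers: Brown–Forsythe
Levene (median-centered, via `car::leveneTest`) and Shapiro–Wilk on the
cell-centered residuals.

## The MR calibration

`fit_mr()` is ordinary least squares of concentration on the features. The
quadratic form deliberately copies the reduced term set used for flow
correction — `1, x1, x2, x1*x2, x2^2`, with no `x1^2` term — because that
is the published structure of this correction; a full quadratic is
available behind `full_quadratic = TRUE` but is not the default.
`model_select()` applies a lexicographic rule: models whose coefficients
and overall F test all clear `alpha = 0.05` are preferred; ties resolve by
lowest AIC, then lowest RMSE. AIC uses the Gaussian profile form
`n * log(SSE / n) + 2(k + 1)`; RMSE is `sqrt(SSE / n)`; both are reported
on the ppb scale of `y`, stated explicitly since normalized variants exist.
`reference_mr_model()` exposes the published coefficient set
`{0.41225, 1.3929, -0.35554, -0.063957, 0.075741}` as immutable constants;
refitting noiseless data generated from it recovers every coefficient to
1e-8 (an exact-interpolation property), and its standard errors are
calibrated (3-SE coverage ≥ 95 % over 200 seeded noise replicates).

## The GA-BP calibration

The network is a 2-2-1 multilayer perceptron: logistic-sigmoid hidden
neurons, identity output (suited to regression on an unbounded scaled
target), each neuron computing `f(sum_i w_i x_i - theta)` with a subtracted
threshold. Inputs and output are min–max scaled to [0, 1] using
fitting-group ranges stored in the model. The training objective is the
mean per-sample error `E = mean_k (1/2)(yhat_k - y_k)^2`; gradients are
analytic and verified against central finite differences to 1e-5.

The 180 training samples are halved (seeded) into 90 fitting and 90
verification samples. A genetic algorithm chooses the initial weights and
thresholds (chromosome = 6 weights then 3 thresholds): tournament selection
of size 2, arithmetic blend crossover with probability 0.8, per-gene
Gaussian mutation (p = 0.1, scale 0.1), elitism 1, genes initialized
uniformly in [-1, 1], population 5 evolved for 50 generations. Fitness is
the verification error after a short inner backpropagation refinement
(default 200 epochs) — "good initial weights" are the ones that *train*
well, and raw-chromosome fitness is nearly flat across basins; a plain
`fitness = "initial"` mode is kept for comparison. The returned individual
is the unrefined initial parameter set, which full training then continues.

Training itself is full-batch backpropagation with two update rules.
Resilient backpropagation ("rprop": per-parameter step sizes grown 1.2x on
gradient-sign agreement, halved with the step rejected on a sign flip,
steps clamped to [1e-10, 1]) is the default: on this small full-batch
problem it reliably reaches error basins several-fold deeper than fixed-step
steepest descent within a few thousand epochs, which materially changes the
network's accuracy at the ends of the concentration range. Plain gradient
descent (`method = "gd"`, learning rate 0.05) is retained and
contract-tested. Convergence stops when the epoch-to-epoch change in `E`
stays below `tolerance` (1e-9) — for rprop it must persist for 10
consecutive epochs, because a single rejected step can leave `E` momentarily
unchanged — or at `max_epochs` (default 10000). Because the protocol's
verification group exists to prevent over-fitting, the returned parameters
are those at the verification-error minimum of the training trajectory
(early stopping); the fitting-trajectory itself is kept in the model.

## Hybrid routing and metrics

The routing threshold `tau` is the mean of the smoothed NO channel over the
training run(s) at 50 ppb / 1000 SCCM — the concentration boundary between
the regime where the polynomial is the more accurate corrector and the
regime where the network is. `predict_hybrid()` sends `x1 >= tau` to the
network and `x1 < tau` to the polynomial; the tie at exactly `tau` routes
to the network (a measure-zero event, fixed for determinism). Every hybrid
prediction is bit-identical to the routed sub-model's output.

Metrics (`evaluate_predictions()`): `R2 = 1 - SSE/SStot`, MSE and RMSE in
ppb, and precision %FS = max |error| / FS x 100 with full scale 200 ppb
(the top of the design range). Max-error is the conventional
instrument-precision reading; a mean-absolute-error variant sits behind
`precision_stat = "mean"` since the statistic's exact definition varies
between labs. The flow-blind baseline — a single linear sensitivity fitted
only at the peak-gain flow and applied at all flows — stands in for the
uncorrected instrument.

## Problem sizes, determinism, degenerate inputs

The default experiment (72 runs x 3000 samples, 180 + 180 calibration
samples, GA 5 x 50 with 200-epoch inner refinements, final training to
10000 epochs) completes in a few seconds per master seed; the test suite
exercises ten full end-to-end seeds plus reduced designs (2-3 levels,
30-60 s runs) for unit checks. All randomness flows from explicit integer
seeds through `withr::with_seed`; no global RNG state leaks.

Degenerate inputs fail loudly with stage-tagged errors: empty or
non-positive design lists, even or oversized smoothing windows, loess spans
covering fewer than two points, unbalanced factorial tables, single-replicate
interaction terms, rank-deficient regression designs, populations below 2,
training sets below 4, thresholds requested at conditions absent from the
training runs, and metric calls on constant truth vectors (R² undefined).

## Known limitations

* With the generator's strictly concentration-linear plateau, the reduced
  quadratic carries a structural lack-of-fit floor: its residuals on
  noiseless data are ~3 ppb at 5 ppb and ~8 ppb at 200 ppb, because the
  reciprocal flow gain is not well approximated by terms linear in
  `x1` and quadratic in `x2`. The sigmoid network can instead saturate onto
  the range ends, and in seeds where that works out at the low end too, the
  hybrid (which always uses the polynomial below `tau`) trails the
  all-network calibrator by 5–9 % RMSE. The hybrid's headline property —
  cutting the flow-blind baseline's %FS precision by more than half —
  holds in nearly all seeds regardless.
* The ANOVA machinery is balanced-design only (no Type II/III sums of
  squares); LSD is the only post-hoc comparison offered.
* No drift, temperature or humidity modelling; a real-data import adapter
  is limited to the documented per-run CSV format.
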