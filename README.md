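# enoseflow

Flow correction for trace-gas calibration in an active-pumping electronic
nose.

## The problem

Fractional exhaled nitric oxide (FeNO) is a breath biomarker of airway
inflammation: healthy adults sit below 25 ppb, asthmatics above 50 ppb.
Electrochemical e-nose systems can reach this ppb range, but when the sample
gas is pulled over the sensor by a pump, the sensor voltage depends not only
on the NO concentration but also on the pump suction flow (200–1200 SCCM):
the same gas reads differently at different flows. Left uncorrected, this
flow sensitivity costs double-digit percent-of-full-scale accuracy.

`enoseflow` implements the full correction workflow for a factorial
concentration x flow bench experiment:

1. **Synthetic bench data** — a seeded simulator of two-channel runs
   (NO-sensor volts + flow-sensor SCCM, 10 Hz x 5 min) over a
   6 concentration x 6 flow x 2 replicate design, with a unimodal flow-gain
   response surface peaking at 1000 SCCM.
2. **Preprocessing** — moving-average smoothing of the NO channel, loess
   smoothing of the flow channel, and reduction of each run to five summary
   features (maximum, mean, median, Q1, Q3), giving 5 calibration samples
   per run.
3. **Two-factor ANOVA with interaction** — the balanced decomposition
   `SST = SSA + SSB + SSAB + SSE` with F tests, Levene and Shapiro–Wilk
   assumption checks, and LSD homogeneous subsets of the flow levels.
4. **MR calibration** — ordinary least squares
   `y = b0 + b1*x1 + b2*x2 + b3*x1*x2 + b4*x2^2` (sensor feature `x1` in
   volts, flow feature `x2` in SLPM), with linear-vs-quadratic selection by
   significance screens, AIC and RMSE.
5. **GA-BP calibration** — a 2-2-1 sigmoid network trained by full-batch
   backpropagation on `E = mean_k( 1/2 * (yhat_k - y_k)^2 )`, with its
   initial weights and thresholds chosen by a genetic algorithm
   (population 5, 50 generations) and a 90/90 fit/verification split
   guarding against over-fitting.
6. **Hybrid routing** — a threshold `tau` (the mean smoothed NO response at
   50 ppb / 1000 SCCM) routes each sample to the MR model below `tau` and
   the GA-BP model at or above it; accuracy is reported as R², MSE, RMSE
   and precision %FS (max |error| / 200 ppb x 100).

## Worked example

```r
library(enoseflow)
res <- run_pipeline(experiment_config(sim = sim_params(seed = 1),
                                      ga  = ga_config(seed = 1)))
print(res)
```

```
Flow-correction pipeline: 72 runs, 180 train / 180 test samples
Routing threshold tau = 0.7513 V (50 ppb @ 1000 SCCM)

Verification-set comparison
            R2      MSE    RMSE precision %FS
mr     0.99570 18.38256 4.28749       9.71199
gabp   0.99645 15.17123 3.89503       7.81620
hybrid 0.99615 16.45605 4.05661       7.81620

RMSE by concentration (ppb)
  concentration     mr   gabp hybrid
1             5 3.2754 1.8291 3.2754
2            25 3.0571 2.5933 3.0571
3            35 2.1060 2.3791 2.1060
4            50 2.2417 2.7045 2.4990
5           100 3.3489 7.3121 7.3121
6           200 8.3394 3.8098 3.8098

Flow-blind baseline: precision = 19.58 %FS; hybrid = 7.82 %FS
```

Reading this: the uncorrected, flow-blind calibration (one linear
sensitivity fitted at the peak-gain flow and applied everywhere) is off by
up to 19.6 % of the 200 ppb full scale on the test split; after flow
correction the hybrid's worst error is 7.8 %FS — better than half. The
quadratic regression is the stronger calibrator at the low-ppb end, the
network at the top of the range where it can saturate onto the 200 ppb
plateau; the threshold stitches the two together.

The ANOVA on the same dataset shows both main effects (flow and
concentration) overwhelmingly significant, and the LSD comparison places
200 SCCM alone at the bottom of the flow ordering with 1000 SCCM at the
top — the reason the bench protocol prefers flows near 1000 SCCM.

A command-line shim over the same functions is installed at
`system.file("cli", "enoseflow.R", package = "enoseflow")` with subcommands
`simulate`, `preprocess`, `anova`, `fit-mr`, `fit-gabp`, `evaluate`,
`run-all`.

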