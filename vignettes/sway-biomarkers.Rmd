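---
title: "Methods: from raw accelerometry to digital biomarkers of disability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw accelerometry to digital biomarkers of disability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

swaymarkers turns short tri-axial accelerometer recordings of two bedside
neurological tests — quiet-stance postural sway and outstretched-arm
pronator drift — into a fixed panel of digital biomarkers, screens them for
test–retest reliability, relates them to age and clinical/imaging outcomes,
and aggregates them into regularized predictive models of disability.  This
vignette is the package's own account of the methods: the models, the
parameters that matter, the numerical conventions, and what the synthetic
data generator can and cannot tell you.

## Signal model and calibration

Each test yields roughly 9.5 s of device-frame acceleration at a nominal
50 Hz.  Traces are trimmed to their **final 9 s**
(`trim_trace(target_duration = 9)`): the surplus is at the start of the
recording, where the reaction to the start cue lives, so the leading samples
are the ones dropped.  The retained length is `round(9 * rate)` samples;
traces shorter than the target are rejected by name.

Calibration (`calibrate_trace()`) is the standard mean-gravity tilt
correction for body-worn accelerometry:

1. the mean acceleration vector over the trace estimates the vertical;
2. the minimal (Rodrigues) rotation taking that vector to $(0, 0, \lVert
   \bar a \rVert)$ is applied to every sample;
3. the two horizontal components after rotation are assigned to
   medio-lateral (M-L) and antero-posterior (A-P) axes — the mapping is a
   configuration knob (`axis_map`) because device orientation in the hand
   is not guaranteed;
4. each horizontal series is mean-subtracted;
5. the net (radial) series is $a_{\mathrm{Net}}[i] = \sqrt{a_{\mathrm{ML}}[i]^2
   + a_{\mathrm{AP}}[i]^2}$.

A trace whose mean vector is below 1 m/s² has no usable gravity direction
and is refused.  The rotation is norm-preserving and the procedure is
idempotent; no low-pass pre-filtering is applied before feature extraction,
so the analysis band (below) is the only spectral gate.

## The four measurement families

For each calibrated axis (M-L, A-P, Net):

* **RMS** $= \sqrt{\tfrac1N \sum_i a_i^2}$ — sway amplitude (m/s²).
* **Jerk** $= \int_0^t (\mathrm{d}Acc/\mathrm{d}t)^2\,\mathrm{d}t$,
  discretized with forward first differences and the rectangle rule —
  sway jerkiness.  The net jerk is half the sum of the M-L and A-P jerks.
* **Spectral centroid** $\mu_1 = \sum_k f_k s_k / \sum_k s_k$ — the
  PSD-weighted mean sway frequency (Hz).
* **Spectral spread** $\mu_2 = \sqrt{\sum_k (f_k - \mu_1)^2 s_k / \sum_k
  s_k}$ — its dispersion (Hz).

The spectrum is a one-sided periodogram of the mean-subtracted series with
a rectangular window and no segment averaging (a 450-sample record is too
short to segment profitably); it is scaled so that the full-band integral
of the PSD equals the series variance.  The spectral moments are computed
over an analysis **band of 0.15–10 Hz** by default: the lower edge excludes
residual drift and DC leakage, the upper edge bounds voluntary sway and
physiological tremor well below the 25 Hz Nyquist limit.  Both edges are
configurable (`band`) and echoed into every report, since no universal
convention exists for them.  Degenerate flat signals produce zero in-band
power; the moments are then returned missing with a `zero_power` flag
rather than fabricated.

## The 60 + 16 biomarker panel

Sway: 4 measures × 3 axes × 3 stances (eyes open feet apart `EOFA`, eyes
open feet together `EOFT`, eyes closed feet together `ECFT`) = 36 columns,
plus the same 12 measures for two condition ratios — `Romberg`
(EC-FT : EO-FT, the effect of removing vision) and `FTFA` (EO-FT : EO-FA,
the effect of narrowing the stance) = 24 columns; 60 in total.  Drift: 4
net-axis measures × dominant hand, non-dominant hand, across-hand sum and
difference = 16 columns.  Names follow `<measure>_<axis>_<condition>`,
e.g. `RMS_Net_ECFT`, `Jerk_ML_Romberg`, `SC_Net_Diff`.

Numerical conventions, chosen once and applied everywhere:

* ratios and sums are computed on the **raw scale first**, then
  log10-transformed — so each ratio column is exactly the difference of its
  two stance columns on the log scale (an identity the tests assert);
* the across-hand **Diff** is the difference of the log10 hand values
  (equivalently the log of the raw ratio): the raw difference can be zero
  or negative, where a direct log is undefined, and the log-ratio is the
  only order-preserving finite choice;
* raw values that are zero or negative (possible only for degenerate flat
  signals) become missing before the log;
* a ratio cell is missing whenever either constituent is missing;
* columns are never dropped — missing inputs produce missing cells in a
  panel whose 76 columns are stable across runs.

Outliers are flagged per biomarker with the Tukey fence: cells outside
$[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$, with quartiles
computed by linear interpolation (type-7, R's default — stated explicitly
because fences are convention-sensitive) on the training subjects only.
Values are preserved; downstream stages consult the flags.

## Test–retest reliability

Reliability is the two-way, absolute-agreement, single-measurement
intraclass correlation ICC(2,1), with trials as raters:

$$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \tfrac{k}{n} (MS_C - MS_E)}$$

with $MS_R$, $MS_C$, $MS_E$ the subject, trial and residual mean squares
over an $n \times k$ complete-case matrix.  The p-value tests zero
reliability through $F = MS_R / MS_E$ on $(n-1, (n-1)(k-1))$ degrees of
freedom; p-values are Benjamini–Hochberg adjusted across the panel, and
biomarkers with ICC > 0.5 pass the screen.  Complete cases are taken per
biomarker (a subject missing either trial's value is dropped for that
biomarker only), and outlier-flagged cells count as missing.  Any trial
pairing can be screened — the default is the first two trials; a
first-trial versus closest-at-home pairing is the same operation on a
different pair.  The implementation is checked to 1e-10 against a
brute-force two-way ANOVA oracle.

## Age bands, abnormality calls and group comparisons

Associations use one subject-level value per biomarker: the mean over the
subject's non-outlier trials (whether to use a single trial or a mean is
not externally fixed; the mean is the lower-variance choice and is stated
in every report).  Pearson correlations (point-biserial for binary
variables such as sex) are BH-adjusted within each report family — one
family per correlation grid, mirroring per-figure adjustment.  Strata with
fewer than 10 subjects are not analysed.

The healthy-reference age regression is ordinary least squares of a
biomarker on age in the HV group, with the textbook 95% prediction
interval

$$\hat y(x) \pm t_{0.975,\,n-2}\; s \sqrt{1 + \tfrac1n + \tfrac{(x - \bar
x)^2}{S_{xx}}}.$$

`predict_band()` returns this two-sided band (its empirical coverage of
fresh reference draws is a headline acceptance property, checked at
93–97%).  The **abnormality call is one-sided** — increased sway is the
direction of dysfunction — so `call_abnormal()` compares each subject
against the one-sided upper prediction limit at the band level
($t_{0.95}$ for a 95% band), giving a designed ~5% exceedance in the
reference population.  Using the upper edge of the two-sided interval
instead would shift the reference exceedance to ~2.5% but would also leave
a group shifted by three residual standard deviations only ~85% abnormal
($\Phi(3 - 1.96)$), which contradicts the intended tail behaviour of the
call; the one-sided limit gives $\Phi(3 - 1.645) \approx 0.91$.  Subjects
more than 10 years outside the reference age range are flagged
extrapolated.  Group differences in age residuals are tested pairwise with
Wilcoxon rank-sum (delegated to `stats::wilcox.test` — screened, standard
methodology), BH-adjusted across the pair family; groups under 2 subjects
are skipped.

## Predictive modeling

Subjects are split 80/20 into training and validation **before any
analysis touches the outcomes**; the split is subject-level, so all trials
inherit their subject's label.  Model features pass a two-stage gate
computed on training data only: ICC > 0.5 and a BH-significant correlation
with at least one relevant clinical/imaging outcome.

Three collinearity regimes are tuned per outcome — ridge (mixing 0),
lasso (mixing 1) and elastic net (mixing searched over 0.1–0.9) — each
optionally paired with a PCA-component variant fitted on leading principal
components (both component-count-by-CV and variance-explained use are
possible; the package searches the count over 1–10 by CV, the sweep being
visible in the CV table).  Hyperparameters are searched by 5-fold
cross-validation on a 13-point logarithmic penalty grid ($10^{-3}$ to
$10^3$), scoring by mean held-out-fold R².  Within a family the package
applies the **one-standard-error rule**: among grid points within one
standard error of the best mean CV R², the most regularized wins.  This is
the conventional guard against overselection along a penalty path; the raw
CV maximum systematically kept many pure-noise features in sparse designs,
while the 1-SE rule retains the informative set and suppresses noise (the
acceptance suite quantifies both).  Fold-level standardization and
fold-level PCA rotations prevent any held-out information from leaking
into tuning; features are z-scored by training statistics, outcomes stay
on their native scale; missing cells are median-imputed from training.

Families are compared by mean CV R² (ties: fewer nonzero coefficients,
then the fixed order ridge, elastic net, lasso).  The winner is refit on
the full training set and evaluated **once** on the untouched validation
split with Pearson's r, R² $= 1 - SS_{res}/SS_{tot}$, and Lin's
concordance correlation coefficient

$$\mathrm{CCC} = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}$$

with population (1/n) moments; $|\mathrm{CCC}| \le |r|$ is asserted on
every report.  Each model is also compared against the *best single
predictor*: the feature with the highest absolute training correlation,
fitted by univariate OLS on training.  Drift-only models target the
dominant-hand cerebellar subpanel by default, the outcome family that
drift biomarkers actually track; combined sway + drift models target the
global disability scales.

## What the synthetic data emulates — and what it does not

The generator exists so that every stage is testable against known ground
truth without patient data.  Per horizontal axis it sums sinusoids (default
peaks at 0.3 and 0.9 Hz, the postural band) and band-limited Gaussian noise
(30% of variance, low-passed at 10 Hz), scaled so the designed series
standard deviation is met analytically — the empirical standard deviation
converges to the design as the record lengthens.  Baseline amplitudes are
0.015 (M-L) and 0.020 (A-P) m/s², rising across stance conditions by
factors 1 / 1.6 / 2.4 (EO-FA / EO-FT / EC-FT): a few hundredths of g, the
scale at which trunk-worn accelerometers record quiet stance, with eyes
closed and feet together the hardest condition.  Device tilt is a fixed
per-subject rotation of the gravity vector (uniform up to 8° by default),
exercising the calibration nontrivially.

Reliability structure enters through the log10 amplitude: per subject
$N(0, \sigma_b)$, per trial $N(0, \sigma_w)$ (defaults 0.20 / 0.12), so a
log-amplitude biomarker has designed ICC $\sigma_b^2 / (\sigma_b^2 +
\sigma_w^2)$ — the variance components are deliberately attached to the one
parameter the reliability-bearing biomarkers measure.  Cohort outcomes are
linear in the latent severities with group offsets and an age trend, then
clipped to their scales (EDSS rounded to 0.5 steps in 0–10, CombiWISE in
0–100, panel scores truncated at zero); the sway-relevant examination
composite is the square root of the sum of its three panel scores, the
drift composite the sum of the per-hand subsystem scores.  One global seed
expands into per-subject and per-trial substreams through a counter-based
hash, so generation order is irrelevant and any subject can be regenerated
in isolation.

What the generator does **not** emulate: inverted-pendulum balance
dynamics, tremor pathologies, non-stationarity within a trial, sensor
dropout, or realistic covariance among the 76 biomarkers (biomarkers of
one trial share one amplitude multiplier, which induces strong positive
correlation — convenient for testing the collinearity-handling of the
models, but not a fitted model of patient data).  Passing tests therefore
demonstrate that the pipeline recovers designed structure under its own
assumptions — amplitude scaling, spectral content, variance components,
linear outcome coupling — not that the same numbers would be obtained on
clinical recordings.

## Problem sizes and runtime choices

The test suite and the acceptance script run at deliberately desk-scale
sizes, chosen to keep Monte-Carlo error well inside the asserted bands:
ICC recovery at 200 subjects × 2 trials through the full raw-signal path;
the reliability screen at 150 subjects over 20 seeds; prediction-interval
coverage at 500 reference subjects with 2000 fresh draws; sparsistency at
n = 200 with 5 informative + 20 noise features over 10 seeds; the
end-to-end fixture at 20 subjects × 2 trials, run twice to confirm
hash-identical artifacts.

## Known limitations

* The calibration assumes a quasi-static gravity direction over the 9-s
  record; violent re-orientation mid-trial would corrupt the vertical
  estimate (such traces should fail the jitter/monotonicity screens first).
* No resampling is performed: traces with more than 20% timing jitter are
  flagged rather than interpolated, because the jerk and spectral
  estimators assume uniform sampling.
* ICC confidence intervals are not computed — the screen needs only the
  point estimate and its F-test, and the filtering decision is a hard
  cutoff at 0.5.
* The panel's ratio columns inherit the instability of small denominators;
  the missing-propagation rules keep them honest but cannot make them
  precise.
* With small cohorts (tens of subjects) the feature gate can pass only a
  handful of biomarkers, and CV R² estimates at 16 training subjects are
  noisy; the pipeline logs every skip decision rather than silently
  proceeding.
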