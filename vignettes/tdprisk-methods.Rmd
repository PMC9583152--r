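---
title: "Methods: in silico TdP-risk classification in tdprisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in silico TdP-risk classification in tdprisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdprisk)
```

This vignette documents the models, the numerical conventions and the
genuinely open design choices in `tdprisk`. The package classifies drugs
into three ordinal Torsade-de-Pointes (TdP) risk levels from per-channel
dose–inhibition data, via drug-block myocyte simulation, twelve-biomarker
extraction and single-feature proportional-odds regression, evaluated by
a repeated one-sample-per-drug bootstrap.

## 1. Channel block and in vitro uncertainty

Drug action on each of the seven measured currents is a static
(equilibrium) pore block: the conductance multiplier at dose $D$ is

$$IF(D) = \frac{1}{1 + (D/IC_{50})^h},$$

so $IF(0) = 1$ and $IF(IC_{50}) = 1/2$ for any Hill coefficient $h$.
Note the convention: although the CiPA literature calls this the
"inhibition factor", it is the conductance fraction that *remains*; it is
multiplied into the channel's maximum conductance
(`apply_drug_block()`). Kinetic (state-dependent) hERG binding is out of
scope by design.

`fit_hill()` estimates $(IC_{50}, h)$ by ordinary nonlinear least
squares on the inhibition scale, parameterised in
$(\log IC_{50}, \log h)$ so positivity is structural. The optimiser is a
damped (Levenberg) Gauss–Newton iteration started from the logit-scale
linearisation; the same routine, vectorised across replicates, powers
the uncertainty sampler. At least three distinct positive doses are
required; a flat response is rejected ("no dose response").

**Uncertainty clouds.** The reference methodology quantifies in vitro
uncertainty with an MCMC sampler over Hill-curve posteriors; this
package uses a *residual bootstrap* with the same output contract —
`sample_hill_uncertainty()` returns 2,000 positive $(IC_{50}, h)$ pairs
per drug–channel. Each replicate refits the model to fitted values plus
resampled residuals (clipped to $[0,1]$), so the two parameters are
drawn jointly and their strong negative correlation survives. With zero
residual noise the cloud collapses to the point estimate (continuity),
and as the noise grows the cloud widens; both properties are tested.
Blocks with only point estimates fall back to a lognormal cloud with a
stated coefficient of variation. A refit that diverges in more than half
of the replicates aborts with "unstable uncertainty".

Seeding: every (drug, channel) pair derives its own stream from the
master seed by string hashing, so per-drug results do not depend on the
order in which drugs are processed.

## 2. The myocyte model and the pacing protocol

The pipeline's simulation contract is the `cell_model()` interface: a
per-channel conductance registry (scale factors in $[0,1]$, all 1 when
drug-free), a state vector with membrane potential and intracellular
calcium, and a single-beat trace generator. The packaged backend is an
analytic surrogate (section 5); an ODE-backed ventricular model — e.g. a
CellML import of a modern human ventricular myocyte — can be supplied
through the same interface without touching any downstream stage. The
reference protocol is retained as defaults everywhere: 2,000 ms cycle
length (30 bpm, the bradycardic, QT-prolonging condition), 10,000
drug-free conditioning beats (`run_to_steady_state()`, disk-cached),
1,000 recorded beats at a fixed 0.1 ms output grid, last 250 beats kept
(`paced_simulation()`'s memory contract). Drugged runs start from the
drug-free steady state rather than re-equilibrating under drug; with the
memoryless surrogate the two are identical, and for ODE backends this
mirrors the reference protocol's initialisation.

The cell sub-type (endo/epi/mid-myocardial) is deliberately left to the
backend: the surrogate is not a specific cell type, and an ODE backend
should document its own choice.

## 3. Biomarker extraction

All features come from the **worst beat**: the retained beat whose
minimum $dV_m/dt$ after the AP peak is most negative (steepest phase-3
descent), ties resolved towards the latest beat. This reading of
"maximal repolarisation velocity" (rather than a positive-slope
early-afterdepolarisation criterion) is a documented interpretation; the
selector is a single function (`select_worst_beat()`) and can be
swapped.

Numerical conventions, all tested against closed-form fixtures:

* Slopes are centred first differences on the output grid (one-sided at
  the ends). The grid step is a recorded configuration item because the
  upstroke velocity is resolution-sensitive.
* **Timing tie-break.** On piecewise-linear traces the discrete maximal
  slope is attained over a run of grid points; activation (and calcium
  onset) time is the *centre* of that run, which is unbiased for linear
  ramps. One convention is used for both Vm and Ca.
* $APD_x$ is the linearly interpolated time from activation to the first
  fall below $V_{peak} - (x/100)\,A$, with amplitude $A$ measured
  against the membrane potential at stimulus onset of the same beat (no
  separate resting-potential feature is needed). $CaD_x$ is analogous
  from the calcium-onset time with the diastolic level at stimulus
  onset. Triangulations are exact differences
  ($APD_{tri} = APD_{90} - APD_{50}$).
* A beat that never recrosses the $APD_{90}$ level (repolarisation
  failure) yields missing durations, not an error; a beat with no
  upstroke above a detection floor (default 5 mV/ms) raises "no AP".
* qNet is the trapezoidal integral over the beat of
  $I_{NaL}+I_{CaL}+I_{Kr}+I_{Ks}+I_{K1}+I_{to}$ (A/F, seconds →
  µC/µF). qInward is the mean of the INaL and ICaL absolute-charge
  ratios against the drug-free control beat, so current sign conventions
  cannot flip it; a zero control charge is a hard "degenerate control"
  error.
* Calcium is carried in mM throughout (diastolic $10^{-4}$ mM scale);
  reports that label peak calcium in other units are treated as display
  artifacts.

Per drug and uncertainty sample, the four dose-level feature vectors
(1–4× Cmax) are averaged component-wise. A component missing at any dose
stays missing in the average and is excluded (with a logged count) from
the regression for that feature — failures are not diluted into the
mean.

## 4. Ordinal regression and classification

For each biomarker separately (the study design compares features
individually; no multi-feature model), `fit_olr()` maximises the
proportional-odds likelihood

$$P(Y \le j \mid x) = \mathrm{logistic}(\zeta_j - \beta x),
  \qquad \zeta_1 < \zeta_2,$$

with the ordering enforced through $\zeta_2 = \zeta_1 + e^{\delta}$. The
optimiser is a damped Newton iteration with analytic gradient and a
halving line search, so the recorded likelihood trace (`fit_log`) is
non-decreasing; three deterministic restarts guard against bad basins.
The feature is standardised internally and the coefficients mapped back,
making predictions exactly invariant to affine rescaling. Convergence is
declared when the per-observation mean gradient falls below $10^{-8}$
(sup-norm); complete separation therefore surfaces as a structured
`converged = FALSE` result with a diagnostic — downstream tables print a
dash — never as an exception. The implementation is cross-checked in the
test suite against an independent proportional-odds fitter on the same
data (coefficients and log-likelihood to $10^{-4}$).

Thresholds are $TH_j = \zeta_j/\beta$: the feature values where the
cumulative probability of the lower class group is exactly one half.
When a feature decreases with risk ($\beta < 0$), $TH_1 > TH_2$ — the
qNet fits reproduce this inversion. Classification uses the cumulative
rule ($P(Y \le \text{low}) \ge 1/2 \Rightarrow$ low;
$P(Y \le \text{intermediate}) < 1/2 \Rightarrow$ high), which equals the
threshold comparison oriented by the sign of $\beta$.

## 5. The surrogate myocyte and the synthetic cohort

The surrogate (`surrogate_params()`, `surrogate_trace()`) is a
piecewise-linear beat whose geometry is an explicit function of the
conductance scales: the duration factor is

$$f = 1 + 0.8\,(1 - s_{IKr}) + 0.3\,(1 - s_{IKs}) - 0.4\,(1 - s_{ICaL}),$$

with $APD_{90} = 270 f$ ms and $APD_{50} = 230 f$ ms, upstroke and peak
modulated by $s_{INa}$, calcium amplitude by $s_{ICaL}$, calcium
durations scaled by the same $f$, and the six qNet currents rendered as
plateau-spanning trapezoidal pulses scaled by their conductance factors.
The sensitivity coefficients are fixed documented constants chosen for
*directional* realism only — IKr/IKs block prolongs, ICaL block shortens,
blocking IKr removes outward charge and lowers qNet — they are not
fitted to any reference ventricular model, and no acceptance property
references reference-model values. Because every biomarker has a closed
form (`surrogate_features()`), large sweeps can bypass trace synthesis;
the equivalence of the closed-form and trace-extraction paths (within
one grid step) is itself a test, and the trace path is used wherever
extractor fidelity is the thing under test.

What the surrogate does *not* emulate: stiff upstroke dynamics,
early/delayed afterdepolarisations, alternans, rate dependence, memory
between beats, and any quantitative correspondence to a biophysical
model. Passing tests therefore demonstrate the correctness of the
pipeline's plumbing and statistics on controllable inputs, not the
physiological fidelity of any particular myocyte model.

The synthetic cohort (`synth_cohort_spec()`) reuses the packaged 28-drug
table (Cmax values, risk labels, 12/16 train/test split) and draws true
IC50/Cmax ratios from class-conditional lognormals: high-risk drugs
block IKr near therapeutic exposure (median ratio 0.7), low-risk drugs
spare IKr (median 100) but tend to block ICaL (median 4,
calcium-blocker-like), intermediate drugs sit between. The
drug-to-drug spread (sdlog 0.5) and the measurement noise (SD 0.03 on
inhibition fractions at four doses spanning the curve) were chosen once
as plausible for patch-clamp Hill data; ground truth is retained so
recovery is testable. Class structure enters *only* through the channel
blocks — everything downstream must rediscover it.

## 6. Evaluation

`make_test_sets()` draws, per repeat, one uncertainty sample per test
drug (16-item sets), with per-repeat seed streams derived from the
master seed. Per repeat, `evaluate_repeats()` scores each class with its
predicted class probability (the natural choice for a
three-class ordinal model; the score source is a single point in the
code if raw feature values are preferred), computes one-vs-rest midrank
AUC (`roc_auc_ovr()`, equal to exhaustive pair counting with half-credit
ties — verified against brute force and an independent ROC package),
and the confusion-matrix metrics of `confusion_metrics()`. Likelihood
ratios with zero denominators are reported as missing with reason codes
rather than as infinities, and an AUC undefined in a repeat (single-class
set) becomes a missing cell; the sweep never aborts. Summaries are
median (min–max), formatted to two decimals. Cross-dataset comparisons
(`compare_datasets()`) run the two-sided variance-ratio F test and then
Welch's unequal-variance t test, delegating to the standard
implementations in base R.

## 7. Problem sizes and limitations

The test suite and the acceptance script run the synthetic pipeline at
the full reference bookkeeping scale — 28 drugs, 2,000 Hill samples per
channel, 8,000 biomarker evaluations per drug, 24,000 train and 32,000
test rows, 10,000 evaluation repeats for the headline feature — using
the closed-form surrogate path; trace-mode checks use reduced sample
counts (4–50 samples, 1–2 beats) since the surrogate's beats are
identical by construction. Null references use drug-level label
permutations, averaged over several permutations because a single
16-drug relabelling is a noisy draw from the null.

Known limitations: no ODE myocyte backend ships with the package (the
interface is the extension point); the bootstrap is a pragmatic stand-in
for posterior sampling of Hill parameters and understates uncertainty
when only four doses are measured; drug-level feature clouds are
unimodal by construction; and single-feature ordinal regression is the
design under study — regularised, multi-feature or non-ordinal models
are out of scope.
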