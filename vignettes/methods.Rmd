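---
title: "Frontal NIRS verbal-fluency features: simulation and analysis methods"
author: "nirsvft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frontal NIRS verbal-fluency features: simulation and analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsvft)
```

## The problem this package addresses

Multi-channel near-infrared spectroscopy (NIRS) during a 60-s letter
verbal-fluency block is a practical probe of prefrontal function in
clinical psychiatry. Two scalar summaries of the frontal oxy-hemoglobin
waveform carry most of the clinically used information:

* the **integral value** — the signed area under the baseline-corrected
  frontal signal over the task period (signal units × s), indexing the
  *intensity* of the activation; and
* the **centroid value** — the time (s after task onset) at which the
  cumulative *positive* signal area over the task-plus-post-task period
  first reaches half of its total, indexing the *timing/efficiency* of
  the activation.

The clinical questions attached to these features are group contrasts
(diagnosis; psychiatric family history) adjusted for age, gender and task
performance, plus an individual-level screen against fixed cutoffs
(integral 73; centroid 54 s) derived elsewhere from a multi-site ROC
analysis and taken here as given constants.

Raw clinical recordings of this kind are not public. The package
therefore pairs the analysis machinery with a synthetic-data generator
whose ground truth is known exactly, so every stage — channel QC,
baseline correction, feature extraction, ANCOVA/LSD/Cohen's d,
classification — is testable end to end.

## The recording model

A recording is a channels × samples matrix over a fixed block design:
10 s pre-task, 60 s task, 55 s post-task, sampled at 0.1 s on 52 channels
(both configurable; the frontal cluster is channels 25–28, 36–38, 46–49).
Each channel carries the subject's hemodynamic response kernel plus
i.i.d. Gaussian noise. The kernel is piecewise: zero until the
(per-subject) onset latency $L$, a linear ramp to the (per-subject)
plateau amplitude $A$ over 15 s, a plateau until task offset, then an
exponential return to baseline with a 15-s time constant. This shape is
not claimed to be a physiological model; it was chosen because it mimics
the canonical task-locked frontal response qualitatively while having a
closed-form task-window area,

$$\int_0^{60} k(t; A, L)\,dt = A\,(60 - L - 15/2), \qquad 0 \le L \le 45,$$

which gives exact oracles for the extraction code (`kernel_task_area()`).

Per subject, $A \sim N(\mu_g, 0.5^2)$ and $L \sim N(\lambda_g, 5^2)$
(truncated at 0) with group-specific $\mu_g, \lambda_g$. Latency jitter
is deliberately the dominant source of within-group centroid variance:
with deterministic latencies the centroid would be nearly noiseless and
any latency difference would produce absurdly large effect sizes.

Artifact-corrupted channels (rate 0.02 by default) receive a step
discontinuity of 12× the noise SD plus three spikes at twice that height,
and are recorded in the generation ground truth. The artifact model is
intentionally simple: it is exactly the kind of contamination the
jump-based QC detector is built to find, no more.

## Cohort structure and calibration

The default cohort reproduces the emulated study's structure: 45
schizophrenia (SCZ), 26 major depressive disorder (MDD), 22 bipolar
disorder (BIP) and 51 healthy controls (HC); nested family-history (FH)
indicators (same disorder ⊆ any major psychiatric ⊆ any psychiatric) at
per-diagnosis fractions derived from the study's cumulative FH counts
(any: 17/45, 10/26, 10/22; major: 15/45, 3/26, 7/22; same: 8/45, 2/26,
3/22); demographics from truncated normals / exact-count categoricals at
the study's group means, SDs and ratios. The true FH subgroup sizes were
published only in supplementary material unavailable here, so these
fractions are configuration defaults, not claims. The rate of "unknown"
family history defaults to 0 — the study's pooled FH model used all 144
subjects — and is configurable to exercise the exclusion logic.

Activation parameters are keyed by diagnosis × FH-status labels (the FH
split on the *any-psychiatric* indicator, matching the per-diagnosis FH
analysis the calibration targets). The amplitude means are solved
numerically so that each subgroup's integral distribution sits at the
study's standardized gap versus controls,

$$d_g = \frac{\mu_g a(\lambda_g) - \mu_{HC}\,a(\lambda_{HC})}{s_p},$$

with $a(\lambda)$ the kernel task-window area, $s_p$ the pooled SD at the
default subgroup sizes, and per-group integral variance
$\sigma_A^2 a^2 + (\mu_A^2 + \sigma_A^2)\sigma_L^2 + \sigma_{noise}^2$
(amplitude spread, latency jitter, channel noise). Targets are the
per-diagnosis FH-subgroup values (SCZ±: −1.21/−0.48; MDD±: −1.21/−0.80;
BIP±: −0.74/−1.34). The diagnosis-level and pooled-FH contrasts then
emerge as mixtures of these subgroups; they land near, but not exactly
on, their own printed values, which are mutually inconsistent with any
single normal-mixture generator — a property of real data, not a bug.
Latency means (HC 12 s; MDD 13 s; SCZ−/BIP− 14 s; SCZ+/BIP+ 17 s) place
every group's centroid near the 54-s cutoff, with FH-positive
psychosis-spectrum subgroups delayed by roughly 0.6 within-group SDs —
the scale of the study's FH centroid contrasts.

What the generator does *not* emulate: serial correlation and 1/f drift
of real NIRS noise, systemic (scalp/Mayer-wave) components, spatial
correlation between channels, motion artifacts with physiological
structure, deoxy-hemoglobin dynamics, or any optical physics. Passing
tests therefore validate the *analysis machinery* under a clean,
known-truth model; they do not certify performance on instrument data.

## Feature extraction choices

**Channel QC.** "Software filtering" of unusable channels is
unspecified in the source literature, so the package uses a deterministic
two-rule screen: a channel is dead if its variance is zero, and corrupted
if its largest absolute first difference exceeds `jump_k` (default 10)
times the raw median absolute deviation (consistency constant 1) of its
first differences. The raw MAD makes a 10×-noise step sit just above the
default threshold. The detector is scale-free and needs the noise floor
to dominate the smooth response's sample-to-sample slope — true at any
realistic noise level, but in the exact noise-free limit the MAD
collapses to the kernel's kink scale and every channel trips the rule;
noise-free oracle tests therefore disable it (`jump_k = Inf`). Subjects
with fewer than 6 usable frontal channels (of 11) are excluded with
reason `"insufficient_channels"`.

**Baseline.** The default corrects each channel by the straight line
through the pre-task mean (10 s) and the mean of the final 5 s of the
post-task window, removing offset and linear drift. A pre-task-only mode
is provided: with the 15-s decay constant the response has not fully
returned to baseline at the end of the post-task window
($e^{-50/15} \approx 0.036$), so the pre/post line tilts a noise-free
integral down by about 1%; the exact noise-free identity
integral = amplitude × kernel area holds in `"pre"` mode and is tested
there, with the pre/post bias asserted separately at its known size.

**Averaging.** The region signal is the unweighted mean of the usable
baseline-corrected cluster channels (average-then-extract, not
extract-then-average).

**Integral.** Trapezoid rule from task onset to offset, signed.

**Centroid.** Positive part only, task onset through end of post-task
(115 s window), reported relative to task onset — consistent with a 54-s
cutoff inside a 60-s task. Cumulative trapezoid areas are linearly
interpolated between bracketing samples and ties resolve to the earliest
crossing; zero positive area yields an undefined (NA) centroid, flagged
rather than thrown. Whether the original denominator is the positive
area or the total |area| is ambiguous in the source wording; the
positive-area reading is implemented, and because the sign convention
only matters for waveforms with substantial negative lobes, the choice
is exposed by construction (the centroid operates on `pmax(signal, 0)`).

## Statistical choices

* ANCOVA: ordinary least squares with one group factor and covariates
  age, gender (0/1 indicator, 1 df) and task performance; type-III sums
  of squares (the convention of the study's stated software) via
  `car::Anova` on a sum-contrast fit. With no interactions the factor
  test coincides with type II; type III is used for fidelity.
* Fisher's LSD: unadjusted pairwise t-tests on covariate-adjusted means
  at the analysis-sample covariate means, using the omnibus model's
  residual variance and df; verified against `emmeans` in the tests.
* Cohen's d: raw group values with pooled SD, not adjusted means — the
  convention of the effect-size calculator the study cites. Both the raw
  and an adjusted-mean variant were considered; raw-pooled is the
  implemented headline because the source pairs d with raw group
  descriptives.
* Demographics: Kruskal–Wallis (Mann–Whitney U for two groups) for
  continuous variables, Pearson's χ² without continuity correction for
  categorical ones, and a Lilliefors-corrected Kolmogorov–Smirnov
  normality screen (parameters estimated from the data; a plain-KS
  switch is provided since the source names only "Kolmogorov–Smirnov").
* Missing data: listwise within each model, with logged counts.
* Classification ties: values exactly at 73 or 54 classify as the case
  category (patient / psychosis-spectrum) — deterministic, conservative
  toward caseness, and reported per subject. Denominators are
  QC-passing subjects; undefined centroids are reported separately as
  indeterminate.

## Numerical and testing notes

The pooled-SD Cohen's d estimator is biased upward in magnitude by the
factor $c(\nu) = \sqrt{\nu/2}\,\Gamma(\frac{\nu-1}{2})/\Gamma(\frac{\nu}{2})$
(about 1.01 at $\nu \approx 70$–$90$). Effect-size recovery tests compare
replicate means against $c(\nu)\,\delta$ within 3 Monte-Carlo standard
errors, since the bias is deterministic rather than Monte-Carlo error;
the acceptance script reports the uncorrected replicate mean.

Problem sizes used by the test suite were chosen to keep the full run
in the low minutes on one core: the replicate-cohort effect-size
calibration uses 200 two-group cohorts of 12+12 subjects on a reduced
12-channel montage (the 3-MC-SE acceptance band is computed at that
size, so the check is statistically equivalent to a larger run); the
plain-normal effect-size recovery uses the full 2000 replicates at the
study ns; the null-calibration check runs 5000 ANCOVA simulations with
two groups of 25.

Known limitations: the generator's noise is white and channel-independent,
so the QC detector's false-positive behaviour under structured noise is
untested; the latency/amplitude calibration reproduces printed
standardized gaps, not raw feature units, so the integral threshold 73
sits at a different quantile of the synthetic patient distributions than
it did in the clinical data (classification *operations* are exercised;
the study's classification percentages are real-data values and are not
reproduction targets); and the centroid's sensitivity to the positive-area
convention is untested against waveforms with large negative lobes of
clinical origin.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config()
study <- generate_study(cfg)
feats <- extract_features_cohort(study$recordings)

fit <- ancova(feats, study$cohort, dependent = "integral_value",
              grouping = "diagnosis")
fit
lsd_posthoc(fit, pairs = list(c("SCZ", "HC"), c("MDD", "HC"), c("BIP", "HC")))

summarize_classification(feats, study$cohort)
```

The numbered scripts under `analysis/` in the source repository run the
same stages against on-disk fixtures and write their tables under
`results/`.
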