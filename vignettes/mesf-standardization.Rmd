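---
title: "MESF standardization and immune-monitoring statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MESF standardization and immune-monitoring statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytomesf)
```

## Why standardize

nCD64 rises sharply with bacterial and fungal infection; mHLA-DR falls with
immunosuppression and is depressed in sepsis. Both are routinely read out
as MFI, which confounds biology with instrument settings. Converting MFI to
MESF (PE-molecule equivalents) via calibration beads puts every instrument
on the same absolute scale, making cross-protocol, cross-lab and
longitudinal comparison meaningful. This vignette records the models,
defaults and design choices behind each stage of `cytomesf`.

## The calibration model

Each acquisition protocol is modelled as log-linear:
`log10(MFI) = a + b·log10(MESF)`, with `b` the log-domain gain and `a` the
offset. The bead regression fits exactly this line by ordinary least
squares of log10 peak MFI on log10 lot MESF; conversion inverts the fitted
line algebraically (`mfi_to_mesf()`), rather than refitting the reverse
regression, because the forward model is the stated one and the inverse
exists whenever `b > 0`. Consequences that the tests assert:

* bead points that lie exactly on a line round-trip to the lot values to
  1e-9 relative tolerance;
* multiplying all MFIs by a constant (a pure gain change) is absorbed by
  the intercept and leaves recovered MESF unchanged;
* on noise-free synthetic protocols the fitted `(a, b)` equal the
  generating offset and gain.

An R² floor (default 0.98) flags poor calibrations with a warning; no
acceptance threshold is imposed because rejection policy is a lab decision.
The PE channel must be uncompensated for the bead model to hold; event
tables flagged as compensated should not be fed to this pipeline.

## Harmonization across protocols

With four protocols measuring the same samples, reliability is summarized
by ICC(2,1) — two-way random effects, absolute agreement, single
measurement — computed from the two-way ANOVA mean squares. Absolute
agreement (not consistency) is the form chosen, because the entire point of
MESF standardization is that different instruments should report the *same
number*, not merely correlated numbers. The model descriptor is recorded in
every result. Note the point estimate is not bounded below by −1 in finite
samples (a 3×2 anticorrelated toy matrix yields exactly −3); the unit tests
pin this behaviour against a hand-computed variance-components oracle.

Agreement per protocol uses Bland–Altman differences against the
per-sample mean of all protocols, with limits of agreement
bias ± 1.96·SD. Outliers are cells with |difference − bias| > 3·SD of that
protocol comparison's differences — the SD is per comparison, not pooled,
since each plot is a separate difference plot. Exclusion runs exactly once
(a single exclude-and-average pass, no iteration), and the consensus MESF
is the arithmetic mean over retained protocol values. A subject with every
protocol excluded falls back to the unfiltered mean with a warning: a
consensus is always emitted. `harmonize()` reports the maximum standardized
absolute difference before and after exclusion so the consistency gain of
the pass is measurable.

## Indices and clinical rules

* CD64 index `(nCD64/lymCD64)/(mCD64/nCD64)` and Sepsis Index
  `100·nCD64/mHLA-DR` are computed on consensus MESFs (post-harmonization),
  matching the analysis convention that the cross-protocol mean is the
  working value. Both are dimensionless and scale-invariant
  (degree-zero homogeneous), which the tests assert.
* Longitudinal deltas are second test minus first; ΔSOFA > 0 defines the
  exacerbation group, ΔSOFA ≤ 0 non-exacerbation.
* Renal SOFA: transplant recipients often run chronically elevated
  creatinine, so the renal component is retained only at creatinine
  ≥ 171 µmol/L or a relative rise; "obvious increase" is not a defined
  quantity, so it is implemented as a configurable ratio with default
  1.5× baseline.
* Diagnostic dichotomization uses strict `>` at the configured cutoffs
  (defaults 3089 for nCD64 MESF, 2433 for mHLA-DR MESF, the Youden-derived
  operating points used for risk modelling).

## The statistics layer

Group comparisons are implemented to be computable from printed
(n, mean, SD) summaries, because that is what published cohort tables
expose: SSB/SSW reconstruct the one-way ANOVA exactly; Fisher's LSD uses
the within-group mean square pooled over *all supplied groups* (the pooling
set is an explicit argument — for a stable/sepsis/non-sepsis table the MSW
pools all three); the two-sample t defaults to the pooled variant with
Welch selectable, since pooled is the variant that reproduces the
longitudinal table cells. Pearson χ² is computed without Yates continuity
correction, again the convention that matches the printed sex-distribution
p-value; Fisher's exact test is available for sparse tables.

ROC analysis uses the rank (Mann–Whitney) AUC with midrank tie handling;
its p-value against 0.5 uses the normal approximation to the Mann–Whitney
statistic with tie correction (the source analyses do not state their
method; this is the standard large-sample choice). The Youden cutoff
maximizes sensitivity + specificity − 1 over observed score values with
ties broken toward the lower threshold, and a `direction` argument covers
markers where low values indicate the outcome (mHLA-DR for sepsis).
Logistic models are fitted by maximum likelihood via IRLS (`stats::glm`),
with Wald z tests and 95% intervals `exp(β ± 1.96·SE)`; multivariate mode
enters covariates with univariate p < 0.05 by default (configurable), and
separation/non-convergence is flagged rather than hidden. Multivariate odds
ratios are adjusted estimates and are labelled as such.

## What the synthetic generator emulates — and what it does not

Markers are positive and heavy-tailed, so each stratum draws from a
lognormal whose *arithmetic* mean and SD are moment-matched to the target
(meanlog = log m − s²ₗ/2, s²ₗ = log(1 + s²/m²)); at n = 5000 the sample
mean lands within 2% and the SD within 5% of the targets. The default
strata are 26 healthy controls, 65 stable recipients and 50 infected
(19 sepsis / 31 non-sepsis), with nCD64 and mHLA-DR parameters taken from
published group summaries of a transplant immune-monitoring cohort.
Choices where no published value exists, made once and documented here:

* **lymCD64 / mCD64 parameters** (e.g. stable: 51 ± 20 and 3200 ± 1000
  MESF) were set so the implied CD64 index magnitudes per stratum are
  realistic (healthy ≈ 12, stable ≈ 18, infection ≈ 80–100). Pathogen
  labels (26 bacterial / 13 viral / 11 fungal) are assigned independently
  of marker values: marker parameters are conditioned on sepsis status, and
  the pathogen and sepsis splits cannot both be matched by independent
  draws.
* **Instrument model:** MFI = 10^(offset + gain·log10 MESF) × unit-mean
  lognormal noise. Defaults model three voltages on one cytometer plus a
  second instrument: gains {1.00, 1.05, 0.95, 1.02}, offsets
  {0, 0.3, −0.2, 0.6}, CV 5%. Multiplicative lognormal noise is chosen
  because it is the noise family under which the log-domain calibration
  model is exact.
* **Bead lot** MESF levels {500; 5,000; 25,000; 60,000} are arbitrary
  placeholders spanning the physiological range (no lot sheet is
  published); four levels by default.
* **Event-level model:** per-population Gaussian CD45/side-scatter/CD14
  clusters with wide separation (the study's gating figures are not
  available, so the gating convention — CD45-dim/SSC-high neutrophils,
  CD45-bright/SSC-low lymphocytes, intermediate monocytes, CD14⁺
  monocytes — is declared, not inferred), and a PE channel whose
  per-population mean equals the protocol-transformed truth (30% CV
  default). 1000 events per population by default.
* **Second timepoint:** 21 infected subjects (14 sepsis, 7 non-sepsis) are
  retested; 3 deteriorate. Markers drift multiplicatively with direction
  tied to exacerbation (nCD64 up / mHLA-DR down on deterioration, the
  reverse on recovery, log-scale noise SD 0.25), giving Δ analyses a known
  ground truth.

Not emulated: spectral spillover/compensation, doublets, debris,
acquisition-time drift, day-to-day calibration drift, and non-lognormal
marker shapes. Passing tests therefore demonstrate correctness of the
*computational* pipeline under its stated noise model, not robustness to
every artifact of real cytometry data.

## Numerical choices and degenerate inputs

* Bead clusters are found by one-dimensional k-means on log10 PE with
  quantile initialization and Lloyd iterations to a 1e-12 center tolerance:
  deterministic, invariant to event order, and adequate because beads are
  single-parameter clusters. Adjacent centers closer than 0.05 log10 units
  (≈12%) are reported as merged levels, an error naming the levels.
* MFI averaging is arithmetic by default — the convention when "mean
  fluorescence intensity" is unqualified — with geometric available; the
  rule used is recorded in every result, since practice varies between
  labs. Populations under 100 events carry a quality flag.
* Zero within-group variance with unequal means reports p = 0 with a
  warning; equal means with zero variance reports F = 0, p = 1. Empty
  cohorts produce empty (not failing) measurement sets; empty event tables
  are errors.
* All generators take explicit integer seeds; identical spec + seed gives
  bit-identical output. Pipeline stages derive child seeds from the single
  configured seed.

## Problem sizes

The reliability study used throughout the tests and the acceptance script
is 100 subjects × 4 protocols at 5% CV, with bead runs of 500 events per
level; the coverage simulation uses 200 replicates of n = 500; the binormal
ROC check uses 10⁵ scores per class; end-to-end event-level runs in the
test suite use small cohorts (≈15 subjects, 150 events per population).
These sizes give stable estimates while keeping the default test run fast.

## Limitations

* ICC confidence intervals are not reported, only point estimates; the
  outlier pass is single-shot by design.
* Full SOFA scoring is out of scope: totals are inputs and only the renal
  component is adjusted.
* FCS ingestion is not built in; the canonical interchange is a per-event
  channel table (CSV) with declared channel names, to which any FCS reader
  can be adapted.
* The published per-patient data behind the bundled summary tables are not
  available, so patient-level quantities (the study's exact ICCs and odds
  ratios) are validated as recovery *properties* on synthetic data rather
  than reproduced numerically; the summary-level table cells are reproduced
  exactly.
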