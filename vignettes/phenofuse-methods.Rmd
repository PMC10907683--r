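---
title: "Methods: fusing keyboard dynamics, accelerometry and daily self-report"
author: "phenofuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fusing keyboard dynamics, accelerometry and daily self-report}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Smartphone digital phenotyping produces data streams at wildly different
rates: a replacement keyboard logs hundreds of keypress events and in-session
accelerometer samples per day, while validated self-report batteries arrive
once daily and span dozens of Likert items. Relating the passive streams to
the self-reports therefore requires (1) reducing every modality to a common
time unit, (2) reducing the dimensionality of the self-report panel without
destroying its time axis, and (3) a regression framework that respects the
strong participant- and week-level dependence of longitudinal affect data.

phenofuse implements that pipeline: daily keyboard-dynamics and accelerometer
features, temporal independent component analysis (ICA) of the
log-transformed self-report panel, and per-component linear mixed-effects
models under a family-wise Bonferroni correction — plus a synthetic-study
generator with known ground truth, because the motivating clinical data
cannot be redistributed. Everything the package claims is demonstrated on
that generator by the test suite and `scripts/acceptance.R`; nothing in this
vignette reports an empirical result the code does not itself compute.

## Daily passive features

**Typing sessions.** A session starts at a keypress and ends at keyboard
dismissal or when at least 6 s pass before the next press (a gap of exactly
6 s closes the session — the boundary had to land somewhere deterministic and
testable). Sessions are assigned the participant-local civil date of their
first press and are never split across midnight; the input contract carries
that date explicitly, so the package performs no timezone arithmetic.

**Session features.** Inter-key delays (IKDs) are computed between
*immediately* successive alphanumeric presses; an intervening autocorrect,
backspace or other press breaks the pair. Per session we take the median IKD
(an inverse measure of typing speed), the 95th-percentile IKD (within-session
pausing; linear interpolation between order statistics, fixed so outputs are
stable), and the mean absolute deviation of the IKDs about the session
*median* (typing-speed variability; the deviation centre pairs naturally with
the median-based speed measure — the field's wording does not pin down the
centre, so the choice is explicit here and in the accessors' documentation).
Autocorrect and backspace rates are counts over all presses. IKD statistics
of sessions with fewer than two adjacent alphanumeric presses are absent, not
zero, and are ignored by the daily means.

**Daily aggregation.** Session statistics are averaged per participant-day;
keypress counts are summed. Days under 750 presses are flagged and excluded
from modelling (the boundary day of exactly 750 is retained). The daily
keypress count is log-transformed and all eight features are z-scored against
the analysis sample — the complete-case aligned rows — because "the entire
sample" is ambiguous between pipeline stages; the fitted means and SDs are
returned so any alternative population can be reproduced and the transform
inverted exactly.

**Accelerometry.** Only in-session samples exist (recording while typing
keeps the battery cost acceptable). Each session's axes are low-pass filtered
with a second-order Butterworth (4 Hz cutoff) applied forward and backward.
The zero-phase application is implemented in the package (odd-reflection
padding of 3·(order+1) samples with steady-state initial conditions) on top of
`signal::butter`, giving unit DC gain to machine precision and the squared
single-pass magnitude — exactly 1/2 — at the cutoff; both are verified against
the designed transfer function in the tests. Sessions shorter than 10 samples
cannot be padded and are classified on raw magnitudes, flagged
`unfilterable`. A sample is *active* when its filtered magnitude leaves the
inclusive band [0.95, 1.05] g; a session is active when strictly more than 8%
of its samples are; a session is *upright* when its median filtered z is
strictly below 0.1 and its median filtered x lies within ±0.2 (inclusive).
Daily movement and upright rates are the fractions of a day's sessions so
classified. The sampling rate is a configuration parameter (default 10 Hz);
the thresholds act on magnitudes and medians, which tolerate mild timing
jitter, so samples are treated as regularly spaced.

## Temporal ICA of the self-report panel

Likert items are strictly positive, so the panel is log-transformed
elementwise; days with any missing item are dropped whole (no imputation is
attempted — the missingness unit in this design is the day). Participants'
day series are concatenated along the time axis, giving the p × n matrix

$$X = A S + \epsilon,$$

with A the time-free p × q mixing matrix (item loadings) and S the q × n
component time courses. Concatenation both lengthens the series available to
the ICA and yields one set of components common to all participants. When
q = p the residual vanishes; the test suite asserts this identity to 1e-8.

Estimation is symmetric (parallel) FastICA with the logcosh contrast
(a₁ = 1): PCA whitening to q dimensions, the fixed-point update, and
symmetric decorrelation, with tolerance 1e-4 and at most 200 iterations by
default (both configurable; non-convergence is recorded in the metadata,
never hidden). The FastICA implementation lives in this package and is
validated by recovery experiments: on 10-item, 3-source Laplace mixtures with
noise SD 0.1 and n = 2000, matched absolute mixing-column correlations exceed
0.95 across seeds.

ICA solutions are defined only up to scale, sign and order, so every fit is
canonicalized: unit-variance sources (the scale moves into A, making loadings
comparable across components), the largest-magnitude loading of each
component positive, components ordered by explained variance. Canonical form
is idempotent and leaves A·S unchanged.

Run-to-run variability is assessed with restarts: R independent fits, pooled
canonical mixing columns, average-linkage clustering on 1 − |cor| cut at 0.3
(an ICASSO-style summary; the cut height is a tuning constant, not a claim).
Restarts that fail to converge are listed in the report and excluded from
clustering. A companion check correlates per-participant mean responses with
per-participant component means to spot "offset" components that merely track
response level; within-participant mean-centring (provided as
`centerWithinParticipant()`) removes such components, and the tests plant one
and confirm it disappears.

## Fusion models

For each component k, on the complete-case table (days with volume-included
keyboard features, accelerometer rates and component scores all present):

$$y_{ijk} = \beta_0 + b_i + b_{ij} + \boldsymbol{\beta}_1^\top
\boldsymbol{x}_{ijk} + \epsilon_{ijk}, \qquad
b_i \sim \mathcal{N}(0, \sigma_1^2),\;
b_{ij} \sim \mathcal{N}(0, \sigma_2^2),\;
\epsilon_{ijk} \sim \mathcal{N}(0, \sigma^2),$$

with participant i, week-within-participant j, day k, and the eight
standardized passive features in x. Weeks are 7-day blocks counted from each
participant's first retained day (nothing in the source material defines the
week boundary; calendar weeks would make the first "week" of most
participants short, so block weeks are the default). The week-within-
participant intercept needs at least two observations per participant-week;
under the default `drop-week` policy only offending weeks are removed, while
`drop-participant` removes the whole participant — both are implemented and
logged because retaining compliant weeks preserves more data, yet the
stricter policy matches how such exclusions are often reported.

Models are fitted with lme4: maximum likelihood for the forwards-fitting
likelihood-ratio sequence over random terms (fixed effects only → participant
intercept → week-within-participant intercept → optional uncorrelated random
slopes), REML for the reported estimates. Each LRT uses a 1-df chi-square
reference, conservative at the variance boundary; no mixture correction is
applied, and the boundary test in the suite confirms the resulting type-I
rate stays below nominal. Wald 95% intervals and p values use a t reference
with the residual degrees-of-freedom approximation df = n − 8 − 1; at the
row counts this design produces (hundreds to thousands) the approximation is
indistinguishable from normal, and the simulation suite verifies empirical
CI coverage within [0.90, 0.99]. Exact small-sample df methods are out of
scope.

p values from all q models are Bonferroni-corrected with CF = q · 8 (fixed
terms only, intercept excluded), capped at 1. Diagnostics emit the tables
behind the usual visual checks — residual and random-effect QQ tables,
standardized residuals against fitted values — plus Shapiro–Wilk summaries.

## The synthetic-study generator

`syntheticTruth()` fixes every generative parameter; `simulateStudy()` emits
raw keypress streams, in-session accelerometer traces and the daily item
panel, plus the ground truth needed for scoring. Defaults emulate the
motivating study's scale: 55 participants, 33 consecutive days, 34 items
across mixed response formats, q = 5 components, and a planted
movement-rate effect of −0.12 on the second (anhedonia-like) component. Two
design points deserve explanation:

* **The components are generated from the *realized* daily features.** The
  generator runs the keyboard module on its own simulated streams,
  standardizes those features together with the planted movement/upright
  rates over the complete-case days, and only then draws the component
  values. The fusion model regresses components on *measured* features, so
  the ground-truth coefficient must be defined on the measurement scale;
  generating from pre-discretization targets would plant classical
  measurement-error attenuation into every recovery experiment. Movement and
  upright rates are planted as exact session-count fractions, which the
  classifier recovers exactly (a property the tests assert), and days outside
  the complete-case set receive standard-normal latent features — they feed
  the ICA only.

* **Latent noise is Laplace by default.** ICA cannot separate exactly
  Gaussian sources — the unmixing rotation is unidentifiable — so a generator
  whose random effects and residuals were all Gaussian would make end-to-end
  component recovery impossible *by construction*, regardless of
  implementation quality. Real daily-affect panels are skewed and
  heavy-tailed, which is precisely the non-Gaussianity temporal ICA exploits;
  the generator emulates this with variance-matched Laplace random effects
  and residuals. `dist = "gaussian"` restores strict normality for
  validating the mixed-model stage in isolation (coverage, family-wise error,
  boundary behaviour), where the Gaussian assumptions are the thing under
  test.

Other generator choices: per-session inter-key gaps are log-normal (positive,
right-skewed, parameterized by its median — the measure the keyboard module
targets), capped just below the 6 s session rule; autocorrect/backspace
presses are planted at exact per-session counts in uniformly random
positions; daily volumes are log-normal around 1050 presses so a realistic
minority of days falls under the 750-press filter; stationary sessions sit at
unit magnitude with 0.01 g axis noise while active sessions carry a slow
(0.4 Hz, within the passband) magnitude burst over 30% of the trace, far
clear of the 8% rule on either side; upright and reclined orientations place
the median z at ≈0.03 and ≈0.9. Item responses are exponentiated from
`base_log + A y + noise`, rounded half-up and clipped to each item's range.
The catalogue mixes 5- to 7-point Likert scales with 1–100 EMA sliders, as
daily-diary batteries do; with 6-point scales only, the log-scale
quantization step (≈0.4–0.7 near the bottom of the scale) is large enough to
visibly attenuate component recovery — a limitation worth remembering when
interpreting ICA on coarse Likert panels, and the reason moderate loadings
(items responding without saturating their bounded ranges) are the default.
Missingness is missing-completely-at-random by day and modality; informative
missingness is out of scope.

What passing these tests does *not* show about real data: the generator has
no circadian or weekly periodicity, no autocorrelated affect dynamics beyond
the week blocks, no informative missingness, no typing content, and its
non-Gaussianity is a convenient parametric stand-in. Recovery under the
generator demonstrates the pipeline's correctness, not that five components
are the right description of any particular panel.

## Validation problem sizes

The suite validates feature extraction against brute-force oracles on 550
randomized small streams; all printed thresholds on and off their boundaries;
the filter against its designed transfer function; the q = p reconstruction
identity; mixing recovery over 10 Laplace-mixture seeds; mixed-model CI
coverage and variance recovery over 100 replicates of a 40 × 6 × 4 design;
family-wise error over 200 all-null replicates with q = 5 (CF = 40); and
end-to-end recovery of the planted −0.12 movement effect over 30 generator
seeds at the 55-participant scale, with proportionally scaled pass
thresholds (27/30 CI coverage, 29/30 negative sign). `scripts/acceptance.R`
recomputes the headline quantities from scratch for any `--seed`.

## Known limitations

IKD-derived and movement features are daily means over sessions, so days with
few sessions are noisier than the model's homoskedastic residual admits; the
Wald df approximation ignores the variance-component uncertainty; the
Bonferroni family is the q · 8 fixed-effect tests only (variance-component
LRTs are reported uncorrected); the forwards-fitting selects greedily and is
not a formal model-averaging procedure; canonical component signs are a
convention and need not match any external report's polarity; and accelerometer
sessions are matched to typing sessions purely by the `session_index` column
of the input contract.
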