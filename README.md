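# phenofuse

Multimodal fusion of smartphone keyboard dynamics, in-session accelerometry
and daily self-report via temporal ICA and nested mixed-effects models.

## The problem

Passive smartphone streams (keypress events, accelerometer traces recorded
while typing) arrive at hundreds of samples per day; validated self-report
batteries arrive once daily across dozens of Likert items. Relating them
requires aligning everything to a common time unit, compressing the
high-dimensional self-report panel without collapsing its time axis, and a
regression framework that handles participant- and week-level dependence.
phenofuse is for researchers analysing dense longitudinal digital-phenotyping
studies who need that full path — raw event streams to corrected
fixed-effect estimates — in one reproducible, heavily tested package.

## The method

1. **Keyboard features.** Keypresses are segmented into typing sessions
   (ended by keyboard dismissal or ≥ 6 s inactivity). Per session: median,
   95th-percentile and mean-absolute-deviation of inter-key delays between
   successive alphanumeric presses, autocorrect and backspace rates. Daily
   means over sessions; daily keypress totals; days under 750 presses
   excluded; the log count and all features z-scored.
2. **Accelerometer features.** In-session traces are filtered with a
   zero-phase second-order Butterworth low-pass (4 Hz). Samples whose
   magnitude leaves [0.95, 1.05] g (inclusive band) are *active*; a session is
   active if > 8% of its samples are, and *upright* if median z < 0.1
   (strict) with median x in ±0.2 (inclusive). Daily movement/upright rates
   are session fractions.
3. **Temporal ICA.** The log-transformed panel, participants concatenated
   along time, is decomposed as `X = A S + ε` by symmetric FastICA (logcosh,
   a₁ = 1), with canonicalized, restart-stability-checked components. With
   q = p the residual is zero.
4. **Fusion.** Per component:
   `y_ijk = β₀ + b_i + b_ij + β₁ᵀ x_ijk + ε_ijk`, with random intercepts for
   participant (`b_i ~ N(0, σ₁²)`) and week-within-participant
   (`b_ij ~ N(0, σ₂²)`), the eight standardized passive features in `x`,
   forwards-fitted random effects (ML likelihood-ratio tests, REML reporting),
   and Bonferroni correction `CF = n_IC · n_fixed` across the model family.

A synthetic-study generator (`syntheticTruth()` / `simulateStudy()`) produces
raw streams and panels from a known mixing matrix, fixed effects and variance
components, so the whole pipeline is testable without restricted clinical
data.

## Worked example

Simulate a full study at the default scale (55 participants, 33 days, 34
items, 5 components, planted movement→anhedonia effect of −0.12), run the
pipeline, and score recovery:

```r
library(phenofuse)

truth  <- syntheticTruth(seed = 42)
bundle <- simulateStudy(truth)
bundle
#> SyntheticStudy: 1805534 keypresses, 2806595 accel samples,
#>                 1724 self-report days (1308 aligned)

res <- runPipeline(pipelineConfig(q = 5),
                   keypresses = bundle$keypresses,
                   accel      = bundle$accel,
                   selfreport = bundle$selfreport)
res$ica
#> ICADecomposition: 34 items x 5 components over 1724 participant-days
#>   contrast=logcosh (a1=1), seed=1, converged=TRUE after 17 iterations

subset(res$models$estimates, term == "movement_rate")[,
  c("component", "estimate", "ci_lower", "ci_upper", "p_corrected")]
#>  component estimate ci_lower ci_upper p_corrected
#>       IC_1   -0.019   -0.048    0.010     1.00000
#>       IC_2   -0.022   -0.067    0.023     1.00000
#>       IC_3   -0.012   -0.057    0.034     1.00000
#>       IC_4   -0.104   -0.150   -0.057     0.00056
#>       IC_5    0.034   -0.013    0.080     1.00000

scorePlantedEffect(bundle, res, "IC_2", "movement_rate")[
  c("matched", "match_cor", "beta_scaled", "ci_scaled", "covered")]
#> $matched      [1] "IC_4"       # estimated order is arbitrary; matched by |cor|
#> $match_cor    [1] 0.949
#> $beta_scaled  [1] -0.102       # planted value: -0.12
#> $ci_scaled    [1] -0.1485 -0.0564
#> $covered      [1] TRUE
```

The planted anhedonia-like component surfaces here as estimated `IC_4`
(component order and sign are ICA conventions; `scorePlantedEffect()` matches
by source correlation and rescales the coefficient to ground-truth units).
Its movement-rate coefficient is the only family-wise significant effect, as
planted: less phone movement while typing, more anhedonia.

A thin CLI over the same functions lives at `inst/cli/phenofuse.R`
(`simulate`, `features-keyboard`, `features-accel`, `ica`, `fuse`, `run`,
`validate`), configured by flags or a YAML file.

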