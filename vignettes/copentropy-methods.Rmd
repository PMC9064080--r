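---
title: "Regularity analysis of postural sway: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularity analysis of postural sway: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copentropy)
```

## The problem

Standing still is an active control problem: the center of pressure
(COP) under the feet fluctuates continuously as the nervous system
corrects the body's sway. Beyond *how much* a person sways, the
*regularity* of those fluctuations is informative — highly trained
standers (here, competitive biathletes holding a shooting posture) can
show more regular, more automatized sway than novices. Sample entropy
(SampEn) quantifies that regularity: 0 for a perfectly repeatable
signal, larger for more unpredictable ones.

`copentropy` implements the complete chain from raw force-plate
channels to group-level inference:

1. six channels (Fx, Fy, Fz, Mx, My, Mz) at 50 Hz, 30 s per trial;
2. 4th-order Butterworth low-pass at 7 Hz on each channel;
3. COP trajectory from the filtered forces and moments;
4. first-difference (increment) series per sway direction (AP, ML);
5. SampEn with m = 3, r = 0.2 per trial and direction;
6. repeats averaged per subject and condition; two-way mixed-design
   ANOVA (group between subjects, task within subjects) with
   generalized eta squared, assumption checks and Bonferroni pairwise
   post hocs, per direction.

The study design it targets: three groups (15 controls, 15 beginners,
8 biathletes) by three tasks (quiet standing QS, shooting position SP,
aiming at target AT), three repeats each.

## COP computation

Force plates do not report COP directly; it follows from moment
balance. With the plate origin at its surface we use the standard
flat-plate convention

$$ x_{COP} = -\frac{M_y}{F_z}, \qquad y_{COP} = \frac{M_x}{F_z}, $$

omitting the vertical moment-arm correction (the plate-surface origin
makes it zero by construction; for plates whose sensing plane sits
below the surface the correction term is plate-specific and would
require the transducer offset, which tabular exports rarely carry).
The plate y axis is mapped to anterior–posterior (AP) and x to
medio–lateral (ML). Whether axes are body- or plate-relative is
genuinely ambiguous when the stance rotates between tasks (a shooting
stance stands roughly 90° to the target); we default to plate-relative
and expose `axis_rotation_deg` in `compute_cop()` to remap per trial.
A guard `fz_min = 10` N (far below any standing subject's weight)
makes division by a near-zero vertical force fail loudly instead of
producing silent garbage on unloaded plates.

## Filtering

The channels are filtered *before* COP computation — the stated
processing order — with a 4th-order Butterworth low-pass at 7 Hz
(`filter_spec()`); a `filter_target = "cop"` switch filters the COP
signal instead for sensitivity analysis. Two implementation choices
matter for reproducibility:

* **Zero-phase application (default on).** A single causal pass
  delays the signal by a frequency-dependent lag, which distorts the
  increment series that SampEn sees. Forward–backward filtering
  cancels the phase response (and squares the magnitude response); it
  is the norm in biomechanics. `zero_phase = FALSE` gives the single
  causal pass for comparison.
* **Deterministic edge handling.** The series is padded at both ends
  by odd-symmetric (point-reflected) extensions of length
  3 × (order + 1), and each pass starts from the filter's steady state
  for the first padded sample (the standard initial-condition
  construction solving $(I - A)z_i = B$ for the direct-form-II
  transposed state). A constant series therefore passes through with
  unit gain to machine precision, and results are bit-reproducible.

## Sample entropy

For a series $x_1,\dots,x_N$ and template length $m$, SampEn is

$$ \mathrm{SampEn}(m, r, N) = -\log\frac{A}{B}, $$

where $B$ counts pairs of distinct length-$m$ templates within the
tolerance radius and $A$ the subset still within it when extended to
length $m+1$. Conventions, each fixed and documented because the
definition leaves them open:

* **Distance:** Chebyshev (max-norm), the Richman–Moorman convention.
* **Comparison:** inclusive (≤ radius). This is what makes a constant
  series — radius exactly 0 — give $A = B$ and SampEn $= 0$ rather
  than an undefined value.
* **Tolerance radius:** $r \times$ *population* SD (divisor $N$) of
  the analyzed increment series itself, computed after filtering: the
  tolerance should describe the series actually compared.
* **Template set:** indices $1,\dots,N-m$ for both counts, so every
  length-$m$ template has a length-$(m+1)$ extension; self-matches
  excluded.
* **Logarithm:** natural (nats).
* **Degenerate counts:** $A = 0$ with $B > 0$ returns a `+Inf`
  sentinel with a warning (legitimately reachable for short, very
  regular series); downstream averaging treats it as missing, never as
  a large number. $B = 0$ is an error — the statistic is undefined.

Defaults m = 3 and r = 0.2 follow the parameter study standardly cited
for COP increments. The optimized counter is a small C++ double loop
with early abort; `sample_entropy_oracle()` is an independent,
literal-definition R implementation used to verify the counts
integer-exactly in the test suite (and refused above N = 5000, where
its quadratic cost stops being harmless).

## Cohort statistics

The dependent variable is the per-subject mean SampEn over the (up to
three) repeats of each condition. Per direction we fit the univariate
mixed-design ANOVA with group (between) and task (within). Choices:

* **Sums of squares:** type III with sum-to-zero contrasts (fitted via
  a multivariate `lm` and `car::Anova`), the conventional treatment
  for the unbalanced 15/15/8 groups. For this one-between-factor
  design the between-subjects test coincides with the one-way ANOVA on
  subject means; type III matters for the within-stratum effects.
* **Effect size:** generalized eta squared,
  $\eta^2_G = SS_\text{effect} / (SS_\text{effect} + SS_\text{subjects}
  + SS_{\text{task}\times\text{subjects}})$ — all subject-related
  variance in the denominator (Bakeman's formulation), which makes the
  measure comparable across between- and within-subject effects. The
  test suite verifies it against hand-computed sums of squares.
  Bands: < 0.01 below-small, 0.01 small, 0.06 medium, ≥ 0.14 large.
* **Assumptions:** Shapiro–Wilk per group×task cell, classical Levene
  (centered on the mean) across groups per task, Mauchly for
  sphericity of the task factor. All are reported as flags, not hard
  failures. When Mauchly rejects at α = 0.05 a Greenhouse–Geisser
  corrected p is reported alongside; the uncorrected F/df remain
  primary.
* **Post hocs:** Welch two-sample t-tests between groups within each
  task, paired t-tests between tasks within each group. Each scope is
  its own Bonferroni family (k = 9 under the full design):
  $p_{adj} = \min(1, k\,p_{raw})$. The family definition is a genuine
  choice — corrections could also be applied per task or globally —
  and is the most conservative of the per-scope options; it is
  configurable by recomputing from `p_raw`. Post hocs are computed for
  a scope only when an omnibus effect licenses it (`force = TRUE`
  overrides).
* α = 0.05 throughout.

## The synthetic generator

No raw recordings ship with the package; every stage is exercised on
synthetic data whose ground truth is known.

**Signal level.** A trial's COP increment series is a MIX(p) process:
$\sqrt{2}\sin(2\pi i/12)$ with each sample independently replaced by
uniform $(-\sqrt3, \sqrt3)$ noise with probability $p$. SampEn is
monotone in $p$, giving a graded regularity dial with known endpoints
(p = 0 perfectly periodic, SampEn ≈ 0; p = 1 i.i.d.). Increments are
scaled to 0.5 mm per step, integrated into a COP path, and inverted
algebraically into plausible channels: $F_z$ from the subject's body
mass (group means 74.8 / 73.9 / 58.9 kg, subject SDs 9.5 / 8.8 /
11.5 kg) with 0.5 % multiplicative noise, $M_x = y_{COP} F_z$,
$M_y = -x_{COP} F_z$, small-noise shear forces. `compute_cop()`
recovers the synthesized path exactly before filtering.

The default group×task irregularity targets (`default_effect_matrix()`)
encode the qualitative expert/novice pattern: near-common p in QS
(0.45 / 0.45 / 0.42), controls and beginners rising to 0.68 in SP and
AT, biathletes dropping to 0.32 / 0.28. Magnitudes are free design
parameters — the study this emulates prints no SampEn means, only bar
charts — chosen once so that the simulated group effect lands in the
"large" η² band; they are deliberately not calibrated to figure
heights. Between-subject variability is a Gaussian random intercept
(SD 0.05) on p, clipped to [0.02, 0.98].

**SampEn level.** `simulate_sampen_trials()` samples the cohort-level
response model directly: trial SampEn = (group, task) mean + Gaussian
subject intercept (SD 0.25) + repeat noise (SD 0.12), with default
means (`sampen_effect_means()`) encoding the same pattern on the
SampEn scale (1.70 / 2.05 in controls and beginners, biathletes 1.60 →
1.35–1.40). Statistical calibration — type-I error over 500 null
cohorts and power over 200 patterned cohorts — runs at this level: the
ANOVA's operating characteristics depend only on the distribution of
the dependent variable, so synthesizing half a million force-plate
channels for the same check would add cost, not evidence. The signal
path is validated end-to-end separately (full-cohort runs and
directional checks over seeds in the tests and `analysis/` scripts).

**What the generator does not emulate.** Real COP is non-stationary
and spectrally colored in ways MIX(p) is not; there is no
inverted-pendulum biomechanics, no weight shift between feet, no rifle
or arm dynamics, and repeats differ only by noise realization, not by
fatigue or learning. Passing tests therefore demonstrate that the
pipeline measures what it claims on signals of controlled regularity —
not that any particular physiological interpretation of real sway is
correct.

## Problem sizes and numerical choices

The shipped analyses use: 1500-sample trials (30 s × 50 Hz, increment
series length 1499); the full 38-subject cohort for end-to-end runs;
500 replicates for null calibration and 200 for power; 100 random
series (N up to 2000) for oracle verification; 20 seeds for
directional single-trial comparisons. Tolerances: filter DC gain to
1e-9; linearity to 1e-9; COP inversion round-trip to 1e-9; ANOVA
versus hand-computed sums of squares to 1e-8; SampEn counts
integer-exact. Ties at band edges classify upward (0.14 is "large").
Per-trial seeds are derived deterministically from the design seed and
the (subject, task, repeat, direction) coordinates, so any single
trial is reproducible without generating the whole cohort, and
generators restore the caller's RNG state.

## Known limitations

* The COP convention must match the acquisition software's to compare
  absolute values against externally computed trajectories; the
  formula here is the standard flat-plate one, with the moment-arm
  correction omitted.
* Whether the emulated study filtered with or without zero phase, and
  which SD estimator scaled its tolerance, is not stated in the
  source; both are exposed as options, with the field-standard choice
  as default.
* `+Inf` SampEn sentinels reduce the number of repeats averaged; with
  all three repeats degenerate a cell goes missing and the ANOVA
  refuses to fit rather than imputing.
* The mixed ANOVA is the classical univariate decomposition; no REML
  mixed-effects alternative is provided.
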