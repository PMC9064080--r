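# copentropy

Sample-entropy analysis of center-of-pressure (COP) postural sway, end
to end: from raw force-plate channels to group-level mixed-design
ANOVA, with a synthetic sway/cohort generator that makes every stage
verifiable without any external data.

## What it computes

Standing posture is quantified by the COP trajectory under the feet.
Beyond sway magnitude, the *regularity* of sway carries information
about motor control: highly trained standers (e.g. biathletes holding
a shooting posture) can sway more regularly than novices. Regularity
is measured by sample entropy,

```
SampEn(m, r, N) = -log(A / B)
```

where `B` counts pairs of length-`m` templates lying within a
tolerance `r·SD` of each other (Chebyshev distance, self-matches
excluded) and `A` those still within tolerance at length `m + 1`. A
perfectly repeatable series scores 0; more unpredictable series score
higher.

The pipeline, following standard practice for 50 Hz / 30 s trials:

1. low-pass each channel (4th-order Butterworth, 7 Hz, zero-phase);
2. COP from forces and moments: `x = -My/Fz`, `y = Mx/Fz`;
3. first-difference (increment) series per direction (AP, ML);
4. SampEn with `m = 3`, `r = 0.2` per trial;
5. average the 3 repeats per subject × task; two-way mixed-design
   ANOVA (group between, task within) with generalized eta squared
   (`η²G`), Shapiro–Wilk / Levene / Mauchly assumption checks, and
   Bonferroni-corrected pairwise post hocs.

The synthetic module generates force-plate trials whose COP increments
are MIX(p) processes (regularity tunable from perfectly periodic to
i.i.d. noise) and whole cohorts (15 controls / 15 beginners / 8
biathletes × tasks QS / SP / AT × 3 repeats) with a configurable
group-by-task effect structure.

## Worked example

```r
library(copentropy)

# one synthetic biathlete shooting-position trial: 1500 samples @ 50 Hz
design <- cohort_design(seed = 42)
rec <- generate_trial(design, "A01", "SP", 1)
inc <- preprocess_trial(rec)          # filter -> COP -> increments
sample_entropy(inc$ap)                # AP-direction regularity
#> SampEn(m=3, r=0.2, N=1499) = 0.465345  [A=11538, B=18375]

# full cohort, both directions, complete statistics
cohort <- generate_cohort(design)
res <- run_analysis(cohort$recordings, run_config(seed = 42))
res$anova_ap
#> Mixed-design ANOVA (AP direction), alpha = 0.05
#>   group        F = 70.704; df = 2, 35; p < 0.001; eta_G^2 = 0.779 (large)
#>   task         F = 49.862; df = 2, 70; p < 0.001; eta_G^2 = 0.154 (large) [GG p = 0.000]
#>   group x task F = 194.040; df = 4, 70; p < 0.001; eta_G^2 = 0.586 (large) [GG p = 0.000]
#>   Mauchly W = 0.502, p = 0.000
```

Reading the output: the group × task interaction is the scientific
quantity of interest — sway regularity changes across tasks
*differently* for biathletes than for the other groups. The post-hoc
table (`res$posthoc_ap`) localizes it: no group differences in quiet
standing, biathletes significantly below both other groups in the two
shooting tasks, controls vs beginners never different. `df = (2, 2, 4)`
with denominators (35, 70) is fixed by the 15/15/8 × 3-task design.

## Analysis workflow

The `analysis/` scripts run the study as a narrative sequence, writing
small tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R    # cohort -> per-trial SampEn table
Rscript analysis/02_entropy_validation.R # oracle agreement, MIX monotonicity, (m,r) sensitivity
Rscript analysis/03_cohort_statistics.R  # assumptions, ANOVA, post hocs per direction
Rscript analysis/04_calibration.R        # type-I error (500 null cohorts), power (200 cohorts)
```

Step 4 should report each omnibus test rejecting at ≈ 0.05 under the
null and near-certain detection of the group × task interaction under
the default effect pattern.

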