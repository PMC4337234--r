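# changegrid

Pattern destabilization analysis for observationally coded psychotherapy
sessions.

Clinical theory treats rigid personality pathology as a self-reinforcing
*attractor*: a stable configuration of cognition, emotion, behavior, and
somatic functioning. Effective therapy should first destabilize that pattern
— visible as increased variability of the patient's session-to-session
state — before a more adaptive pattern consolidates. `changegrid` implements
the measurement pipeline for testing that idea in archived therapy trials
whose sessions were coded with the CHANGE observational system, and a
synthetic-cohort generator so the whole pipeline is testable without any
clinical data.

## What it computes

Per session (two coders, ordinal 0–3 ratings, averaged per item):

- four **node scores** per valence — cognitive (mean of View of Self, Hope,
  Relationships), emotion, behavior, somatic;
- **pattern strength** = sum of the four nodes, range 0–12;
- **pattern activation** = number of nodes at a moderate-to-high level
  (node score ≥ 2), range 0–4.

Per patient and treatment phase (phase 1: sessions 1–10, phase 2: 11–34),
sessions become points on a 5×5 **state-space grid** (x = positive
activation, y = negative activation) with occupancy counts d_i over the
n = 25 cells and D coded sessions, and destabilization is the grid
**dispersion**

    1 - [(n * sum_i (d_i / D)^2) - 1] / (n - 1)

(0 = all sessions in one cell; 1 = uniform occupancy of the full grid).
The outcome layer reproduces the standard analysis around these scores:
pairwise correlation matrix, paired t-tests with Cohen's d, hierarchical
regressions with ΔR²/ΔF tests (Step 1: pretreatment score; Step 2: phase
dispersion and peak emotional processing), inter-rater ICC(A,1), and a
bridge that reconstructs standardized regressions directly from a printed
correlation table (β = R⁻¹r).

## Worked example

```r
library(changegrid)

co  <- generate_cohort(synthetic_config(seed = 7))   # 27 synthetic patients
fit <- pattern_analysis(co$codings, co$outcomes)
fit
#> Pattern-destabilization analysis: 27 patient(s) analyzed, 0 dropped
#> Phase schedule: baseline 1 | phase 1: 1-10 | phase 2: 11-34 | post target 34
#>   dispersion: phase 1 mean 0.57 (SD 0.16), phase 2 mean 0.55 (SD 0.17)
#>   peak processing: phase 1 mean 1.70, phase 2 mean 2.31
#> Use summary() for paired tests and regressions.

fit$regressions$phase2$scid
#> Hierarchical regression of scid_post (n = 27)
#> Step 1: R2 = 0.06, dR2 = 0.06, dF(1, 25) = 1.60, p = 0.2173
#>  predictor     B    SE  beta     t     p
#>   scid_pre 0.573 0.453 0.245 1.266 0.217
#> Step 2: R2 = 0.34, dR2 = 0.28, dF(2, 23) = 4.83, p = 0.01769
#>         predictor      B    SE   beta      t     p
#>          scid_pre  0.529 0.406  0.226  1.302 0.206
#>       dispersion2 -6.887 3.486 -0.342 -1.976 0.060
#>  peak_processing2 -2.420 0.961 -0.431 -2.517 0.019
```

Reading the step-2 block: after controlling for pretreatment symptom
severity, more schema-phase destabilization (dispersion 2) and deeper peak
emotional processing each predict *lower* posttreatment SCID-II symptom
counts (negative betas), and together they add ΔR² = 0.28 of outcome
variance (ΔF test p ≈ 0.018). The cohort was generated with standardized
effects −0.35 and −0.45 planted on exactly those two predictors, which is
what the fitted betas (−0.34, −0.43) recover at n = 27.

Scoring primitives are exposed directly:

```r
pattern_strength(c(3, 3, 3, 1))   # 10   (cognition, emotion, behavior, somatic)
activation_score(c(3, 3, 3, 1))   # 3    nodes at moderate-to-high level
as.numeric(dispersion(build_grid(c(0, 1, 2, 3, 4, 0), c(0, 0, 0, 0, 0, 1))))
# 0.8680556  -- six sessions spread over six cells
```

A command-line wrapper lives at `inst/exec/changegrid`
(`changegrid simulate|validate|analyze`), writing a deterministic,
config-hash-stamped report bundle (per-patient summaries, correlations,
paired tests, both phases' regression tables, GridWare-style trajectory
export).

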