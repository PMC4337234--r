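---
title: "Scoring pattern destabilization in coded psychotherapy sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pattern destabilization in coded psychotherapy sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(changegrid)
```

## The measurement model

`changegrid` analyzes psychotherapy process data in which trained coders rate
audio-recorded sessions with the CHANGE observational system. Each session
receives ordinal ratings 0--3 (0 = not present/very low, 3 = high) on six
positively and six negatively valenced variables -- View of Self, Hope,
Relationships, Emotion, Behavior, Somatic functioning -- plus Emotional
Processing. Two coders rate every session independently; their ratings are
averaged per item, so averaged ratings live on the half-point grid
0, 0.5, ..., 3.

From the averaged ratings each valence is reduced to four *nodes* of a
cognitive-affective-behavioral-somatic pattern. The cognitive node is the
mean of View of Self, Hope, and Relationships (the cognitive triad: self,
future, others); the other three nodes are single variables. Two summaries
are computed per valence per session:

* **Pattern strength** -- the sum of the four node scores, range 0--12. A
  global intensity measure, used at baseline (session 1) and posttreatment
  (the coded session nearest session 34).
* **Pattern activation** -- the number of nodes engaged at a moderate-to-high
  level (node score $\ge 2$), range 0--4. A breadth measure: how multimodal
  the pattern is in that session.

Activation applies a strict threshold at 2.0 to the node score after coder
averaging and, for the cognitive node, after the three-variable mean: an
averaged 1.5 does not activate, a 2.0 does. The moderate floor comes from the
rating anchors (2 = moderate, 3 = high). Because one can also read the
threshold as applying to the raw CHANGE variables rather than the averaged
node, `session_profiles()` exposes `cognitive_activation = "per-variable"`,
which instead activates the cognitive node when a majority (two of three) of
its source variables reach the threshold. The node-mean rule is the default;
the two rules differ only when the cognitive mean is carried over the
threshold by one extreme variable (or held under it despite two moderate
ones).

Missing ratings are an explicit `NA` sentinel. A node with no available
source stays missing, and strength/activation for that session are `NA`
rather than a rescaled partial score -- rescaling would silently change the
0--12 and 0--4 semantics.

## State-space grids and dispersion

Each session is a point on a 5x5 grid: positive activation on the x-axis,
negative activation on the y-axis. Per patient and treatment phase the grid
tallies occupancy counts $d_i$ over its $n = 25$ cells, with $D$ the number
of coded sessions in the phase. Destabilization is quantified as
**dispersion**:

$$ 1 - \frac{n \sum_i (d_i/D)^2 - 1}{n - 1}, $$

algebraically equal to the normalized Simpson diversity
$n(1 - \sum_i p_i^2)/(n-1)$ with $p_i = d_i/D$ (the test suite verifies the
two forms agree to 1e-12 on random grids). The value is 0 when every session
falls in one cell. $D$ sessions spread over $D$ distinct cells give
$1 - (n/D - 1)/(n - 1)$ -- e.g. 0.868 for six spread sessions -- and the
maximum 1.00 requires uniform occupancy of the full grid ($D = n$). Informal
descriptions of the statistic sometimes call any all-distinct configuration
"maximum dispersion (1.00)"; the formula itself does not do that
normalization, and published per-patient values (such as 0.868 for a
six-session phase) are only consistent with the unnormalized formula, which
is what `dispersion()` implements. $n$ is always the full cell count, not
the number of visited cells, and each coded session counts one unit of
duration, so phases with more coded sessions can express more spread.

Grids with a single observation return dispersion 0 (the formula's value)
but carry a degenerate flag; empty grids raise an error rather than
returning a value.

## Phases and the per-patient analysis row

The therapy protocol has a symptom-reduction phase (sessions 1--10) and a
schema-focused phase (sessions 11--34). `build_summaries()` reduces each
patient to one analysis row under these rules:

* Baseline = session 1; posttreatment = the coded session minimizing
  $|s - 34|$, the *earlier* session on ties (deterministic, and it keeps the
  posttreatment measure from preceding the process windows inconsistently).
* Phase-1 dispersion uses phase-1 sessions *excluding baseline*; phase-2
  dispersion uses phase-2 sessions *excluding the posttreatment session*, so
  no session serves as both a process point and an endpoint.
* Peak emotional processing is the maximum averaged processing rating in the
  phase (the earliest session on ties). Processing typically rises and
  falls, so the peak detects shifts better than the mean. The phase-1 window
  includes the baseline session; the phase-2 window excludes the
  posttreatment session so the peak always precedes the outcome.
* Patients lacking a baseline, a posttreatment session, or a usable session
  in either phase window are dropped with a logged reason. Dropped patients
  are excluded listwise from regressions; the correlation matrix uses
  pairwise-complete rows, which mirrors how published correlation and
  regression tables can disagree slightly on effective n.

## The outcome layer

`pattern_analysis()` assembles: the 10-variable pairwise Pearson correlation
matrix (with per-pair n and p values); paired pre/post t-tests with Cohen's
$d = \bar{d}/s_d$ (so $|t| = |d|\sqrt{n}$ exactly); and hierarchical OLS
regressions per outcome (SCID-II symptoms, negative strength, positive
strength): Step 1 enters the pretreatment score, Step 2 adds the phase's
dispersion and peak processing. The R-squared-change test uses the standard
current-step convention

$$ \Delta F = \frac{\Delta R^2 / q}{(1 - R^2_{\text{full}})/(n - k_{\text{full}} - 1)}, $$

identical to the model-comparison F of `anova()`. Standardized betas scale
the raw coefficients by predictor/outcome standard deviations.

`regression_from_correlations()` is a validation bridge: given only a
printed correlation table it reconstructs the standardized solution
($\beta = R^{-1} r$, $R^2 = \beta^\top r$) step by step, which lets a
published regression table be audited against its published correlations.

Inter-rater agreement uses ICC(A,1) -- two-way random effects, absolute
agreement, single rater -- computed from the two-way ANOVA mean squares.
The absolute-agreement form is chosen because coder mean differences should
count against agreement when averaged ratings feed the analysis; the
source study names no variant, so this is the package's choice (verified in
tests against an independent variance-component fit).

## The synthetic cohort generator

No session recordings accompany the design this package implements, so
`generate_cohort()` produces cohorts with the statistical structure the
analysis assumes. Defaults emulate the study conditions: 27 patients; coded
sessions 1, 2, 4, 6, 8, 10 (every other early session), 14, 18, 22, 26, 30
(every fourth schema-phase session), and 34; non-anchor sessions missed with
probability 0.18 (about the reported 82% tape coverage, with at least one
session guaranteed per phase window); two coders per session.

Each patient carries a latent two-state chain per phase: a
negative-dominant and a positive-dominant attractor. Per coded session the
chain switches with a patient-specific probability drawn uniformly from a
per-phase range -- the "flickering" mechanism by which a system transiently
visits a competing attractor. The active state sets the emission means of
the 12 pattern variables (negative variables high in the negative state and
low in the positive state, and vice versa); session-level Gaussian noise
(SD 0.3) and independent per-coder noise (SD 0.2) are added before
discretizing to 0--3. Processing ratings sit near a low base in phase 1 and
rise along a Gaussian bump toward a patient-specific phase-2 peak (mean peak
session 15). Emission and switching defaults were calibrated once so the
cohort-level summaries land where the method's literature reports them:
mean dispersion about 0.6 in phase 1 and 0.55 in phase 2, peak processing
means about 1.6 and 2.3, and a pooled two-coder ICC of about 0.8 on the
pattern variables (processing, with less between-session variance, sits
near 0.75).

Outcomes are linearly coupled to the *realized* process measures. The
generator computes each cohort's phase-2 dispersion and peak processing with
the same pipeline rules the analysis applies, z-scores them, and builds

$$ y = \beta_1 z_{\text{pre}} + \beta_2 z_{\text{disp2}} + \beta_3 z_{\text{proc2}} + \sigma e $$

with planted standardized coefficients (SCID-II model: 0.24, -0.35, -0.45;
positive-pattern model: 0.25, 0.39, 0.46, mirroring the published effect
sizes) and $\sigma$ set so the standardized outcome has unit variance. The
SCID-II outcome is then mapped to score units, rounded, and floored at 0;
the positive-pattern outcome is *realized physically* by regenerating the
posttreatment session's six positive ratings around the target strength, so
the planted effect must survive rating discretization and the full scoring
pathway to be recovered.

Three numerical design choices matter here:

* **Outcome locations.** The posttreatment score scales (SCID-II mean 6.5,
  SD 3.35; positive strength target mean 4.5, SD 2.0) are set so the score
  floors censor almost no probability mass. Locations matching the source
  study's posttreatment descriptive means would put 7--14% of the planted
  linear outcome below zero; that censoring measurably attenuates the
  planted coefficients and makes the change-F test conservative, defeating
  the generator's purpose as a pipeline oracle.
* **Exact planting.** By default the outcome noise $e$ is residualized
  against the predictor directions carrying nonzero planted coefficients
  and rescaled to unit sample variance. The cohort's sample coefficients
  then equal the planted values exactly up to realization noise, instead of
  wandering with OLS sampling error (SE about 0.033 per coefficient at 500
  patients). Zero-planted directions are left untouched, so cohorts with
  null process effects keep honestly stochastic R-squared-change behavior --
  their type-I rate stays at the nominal level. Set
  `exact_planting = FALSE` to study pure sampling behavior.
* **Seeding.** A global seed drives a per-patient substream, so patient k's
  codings are bit-identical whether the cohort has 27 or 500 patients.
  Outcome columns are cohort-level (they standardize across patients) and
  the posttreatment positive ratings inherit that coupling; everything else
  is patient-local.

What the generator does *not* emulate: real CHANGE ratings' marginal
distributions (only their scale and rough location), therapist effects,
diagnostic subgroups, temporal autocorrelation within phases beyond the
two-state chain, or any treatment-as-delivered content. Passing pipeline
tests on synthetic cohorts therefore demonstrates that the scoring,
grid, and regression machinery is correct and internally consistent -- not
that the substantive findings generalize.

## Problem sizes used in the checks

The bundled checks run the worked scoring example (four nodes), dispersion
identities on 1000 random grids, parameter recovery on one 500-patient
cohort per outcome model, and type-I calibration over 1000 null cohorts of
27 patients; these sizes give Monte-Carlo standard errors small enough to
detect coefficient errors of a few hundredths while keeping a full test run
in a few minutes.

## Known limitations

* Dispersion treats each coded session as one unit of duration; tools that
  weight by real elapsed time will differ when coding density varies within
  a phase.
* With five-ish sessions per phase window, dispersion is coarse: its
  attainable values are few, and region-specific dispersion (within- vs
  between-attractor movement) needs denser sampling than the emulated
  schedule provides.
* The effective n of each regression depends on listwise deletion and can
  differ from the correlation matrix's pairwise n; both are reported.
* Exact integer SCID-II scores and half-point averaged ratings make ties
  common; all tie-breaks (modal cell, peak session, posttreatment session)
  are deterministic and documented above.
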