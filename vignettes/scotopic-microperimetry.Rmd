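---
title: "Dark-adapted two-color microperimetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dark-adapted two-color microperimetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scotoperim)
```

## The measurement problem

Dark-adapted two-color fundus-controlled perimetry ("scotopic
microperimetry") measures retinal sensitivity under rod-dominated
conditions. Cyan (505 nm) stimuli preferentially probe rod function and red
(627 nm) stimuli elicit mixed rod–cone responses; because the two dB scales
are calibrated to the CIE scotopic luminosity function, a healthy retina
shows a cyan–red difference of 0.0 dB everywhere except the rod-free fovea,
where cyan sensitivity collapses to a central scotoma. In rod–cone
degenerations such as choroideremia, rods fail before cones, so negative
cyan–red differences (outside the fovea) flag relative rod dysfunction.

`scotoperim` implements the full outcome-measure analysis for such exams:
reliability gating, sensitivity indices, test–retest repeatability, cyan–red
difference interpretation, cohort statistics and structure–function
correlation — together with a synthetic-cohort generator so that every stage
is testable end-to-end without patient data.

## Coordinates and the test grid

All coordinates are retinal degrees with the origin at the anatomical
fovea; +x is temporal retina and +y superior, in right-eye (OD) convention.
Left-eye exams are mirrored (`normalize_eye()`), which turns hemifield
analysis into a sign test on x. The default scotopic pattern is a 37-locus
radial grid: one foveal locus plus three rings of 12. The device's exact
ring radii are not published; the package defaults to 1°, 3° and 7°
(configurable in `build_grid()`), giving a convex-hull footprint of
147 deg² that is consistent with healthy flat-field volumes of roughly
3000 dB·deg² at ~20.5 dB mean sensitivity.

Thresholds live on a 36.0 dB dynamic range (stimulus luminances 0.00064 to
2.545 cd/m²; `dynamic_range_db()`); loci where the brightest stimulus is
not seen carry the export sentinel −1.0 dB, stored verbatim.

## Reliability gating

Three reliability signals are computed per exam:

* **Fixation losses** — the percentage of suprathreshold blind-spot catch
  trials responded to (false positives). The gate fails at ≥ 30% (the
  published rule is phrased as "\> 30%" but the corresponding summary table
  bins at "≥ 30"; the conservative ≥ 30 reading is the default and the
  cutoff is exposed).
* **Fixation stability** — P1/P2 (the percentage of fixation samples within
  1°/2° of the preferred retinal locus) with the Fujii classification
  (stable if P1 > 75, relatively unstable if P2 > 75, unstable otherwise),
  and the bivariate contour ellipse area
  `BCEA(P) = 2k·pi·sx·sy·sqrt(1 − rho²)`, `k = −log(1 − P)`. The "63%"
  output uses the exact `P = 1 − exp(−1)` convention (`k = 1`); the
  constant is configurable because the device's convention is unpublished.
  The preferred retinal locus is estimated as the coordinate-wise median of
  the trace (robust to saccades); the device's estimator is unknown, so a
  mean option is provided.
* **Rod-free zone detection** — under scotopic cyan testing, the foveal
  locus should be a scotoma (non-seen, 0.0 dB, or a low cone-driven
  residual). A central cyan threshold above 8.0 dB indicates failed rod-free
  mapping and an unreliable test. The 8.0 dB cutoff is applied uniformly to
  both groups (published practice flagged 12–24 dB values in patients and
  \>8 dB in controls; a single default covers both and is configurable).

`gate_exam()` reports *all* failing reasons, and the pipeline excludes both
colors of a subject-session when either fails (a cyan rod-free failure
indicates unreliable responding, not a cyan-specific artifact).

## Sensitivity indices

**Mean sensitivity** is the arithmetic locus average with the −1.0 sentinel
mapped to 0.0 dB. That mapping is inferred from device behavior (patients
with all-non-seen maps report 0.0 dB means) and is configurable
(`nonseen = "exclude"`). On a radial grid this average is spatially
weighted — the dense center contributes far more per unit area — which the
test suite demonstrates on the field S(r) = r.

**Volume sensitivity** (the "hill of vision", dB·deg²) avoids that bias: a
piecewise-linear interpolant over the Delaunay triangulation of the loci is
integrated exactly over the convex hull, each triangle contributing its
area times the mean of its vertex values. The triangulation comes from
`deldir`; on the perfectly symmetric radial grid the Delaunay solution is
degenerate up to cocircular ties, which affects the triangle list but, in
the tested configurations, reproduces the hull exactly (the suite asserts
agreement with an independent dense-quadrature oracle to 10⁻⁶ relative,
and exact flat-field volumes S·A). No extrapolation beyond the hull is
performed and no smoothing is invented; linear interpolation is the
default and only the interpolant the integration rule is exact for.

**Cyan–red differences** are computed per locus (undefined when exactly one
color is non-seen; both-non-seen loci default to difference 0 and the
"equally impaired" class, matching the convention that such loci are
reported black). `classify_difference()` assigns the four-class code —
equal-normal, equal-reduced, rod dysfunction (diff below −threshold), cone
dysfunction (above +threshold) — at a configurable variability allowance;
0, 4 and 13 dB correspond to no allowance, the device's arbitrary cutoff,
and the combined cyan–red test–retest variability. "Reduced" means below a
per-locus healthy normative bound (mean − 2 SD, `normative_pointwise()`),
since no quantitative definition is published. Summary differences (mean
and volume) support central-locus exclusion, which is recommended: the
rod-free fovea otherwise skews every global cyan–red summary towards
apparent rod dysfunction.

## Repeatability

Pointwise test–retest differences (`d = test2 − test1`; the direction is a
package convention) are modelled as `d_ij = mu + u_i + e_ij` with subject
random intercepts, fitted by REML (`lme4`). The coefficient of
repeatability uses the within-subject SD only, in the reporting convention

CoR = 2 × 1.96 × SD_within,

implemented verbatim as the default (`cor_formula = "1.96xsqrt2"` gives the
alternative 1.96·√2·σ convention behind a flag). Limits of agreement use
the total SD √(σ_b² + σ_w²). Using the pooled SD of all differences in
place of the model's within-subject SD inflates the CoR whenever subjects
differ systematically; `cor_pooled` reports that naive value and the test
suite asserts the inflation on simulated data. Confidence intervals come
from a cluster bootstrap (subjects resampled with replacement, model
refitted, percentile intervals, 1000 resamples by default, seeded).

For balanced designs the one-way ANOVA moment estimator coincides with
REML; the package exposes it as `engine = "anova"` and uses it for the
bootstrap inner loop, with the equivalence asserted against `lme4` in the
tests. Whole-exam indices (one pair per subject) use the standard
Bland–Altman analysis with `SD_within = SD(d)/√2`.

The combined cyan–red pointwise CoR first forms the cyan–red index per
locus and session, then drops loci non-seen (below 0 dB) at either session
in either color — the exclusion rule as stated in the methods of the
source literature; a stricter variant that also drops exact 0.0 dB values
is available (`exclusion = "zero_any"`) because published phrasings differ,
and the CoR is computed on the cyan−red index itself (rather than pooling
per-color variabilities), which is the reading this package adopts.

## The synthetic cohort generator

The generator exists so that every analysis stage has a ground truth. Its
defaults *are* the emulated study conditions and are not tuned per
analysis:

* **Groups and sessions**: 21 healthy controls, 20 patients, one eye each,
  cyan and red exams; the first 10 patients repeat both exams.
* **Healthy fields**: peak ~N(23, 1.2) dB shared between colors with
  0.6 dB per-color jitter, radial fall-off ~N(0.5, 0.08) dB/deg, rod-free
  radius 0.5°, central cyan residual ~N(4, 1.5) dB clamped to [0, 7]
  (the 4 dB default is the reported healthy median). Equal color peaks
  encode the CIE calibration: the ~20 dB radiance offset between colors is
  absorbed into the per-color dB scales, so equal dB means equal scotopic
  visibility and the healthy off-fovea cyan−red median is 0 by
  construction.
* **Choroideremia fields**: a residual island ellipse with lognormal
  semi-axes (medians 4.5° × 3.2°, sdlog 0.40), shifted temporally by
  ~N(2.5, 0.7)° to produce the temporal sparing typical of the disease;
  inside the island, rod (cyan) deficits ~N(16, 3) dB exceed cone (red)
  deficits ~N(7, 2.5) dB; outside it, loci are non-seen. Deficits apply
  after the rod-free substitution, so patient central cyan clamps to
  ~0 dB. Island areas convert to mm² via 1° = 0.288 mm (the single
  emmetropic conversion constant in the configuration).
* **Observer**: a cumulative-Gaussian psychometric function in dB
  (slope 1.5 dB) with a 4% false-positive and 2% lapse mixture, measured
  through a 4-2 dB bracketing staircase: start 18 dB, 4 dB steps towards
  brighter after each miss, 2 dB steps after the first response reversal,
  one further presentation after the second reversal, estimate = last seen
  level; misses at 0 dB return the non-seen sentinel. The device's start
  level, reversal count and estimator are unpublished; all are exposed as
  arguments. A slope of 0 gives the deterministic step observer used by
  the staircase oracle tests, for which the measurement error is bounded
  by the 2 dB terminal step.
* **Reliability failure modes**: catch-trial presses are Bernoulli(4%)
  over 10 trials; 8% of subjects draw a structurally unmapped rod-free
  zone (central cyan 12–24 dB). Because the fovea receives a single
  staircase, a lone false-positive press during the descent can also lock
  in a spuriously high central threshold (probability ≈ 2·fp·(1−fp) ≈ 8%),
  so the total failed-mapping rate is ~15%, consistent with reported
  detection rates of ~85%. The acceptance suite computes the expected gate
  failure rate exactly by probability propagation over the staircase state
  space.
* **Retest noise**: an additive per-locus, per-color perturbation of the
  *true* thresholds at test2 (~N(0, 3.5 dB)), on top of independent
  staircase noise, so the variance components are separable in tests; a
  systematic session offset (learning/fatigue) defaults to 0. The 3.5 dB
  default was set from the magnitude of published pointwise coefficients
  of repeatability (±12–16 dB, i.e. within-SDs of 3–4 dB).
* **Fixation**: bivariate-normal jitter with 0.25° SDs scaled per subject
  by a lognormal factor (sdlog 0.3), yielding 63% BCEA values around
  0.3–0.5 deg², and 500 trace samples per exam.

What the generator deliberately does **not** emulate: dark-adaptation
kinetics (adaptation time is metadata), eye-tracker latency, spatial
correlation of staircase errors between neighboring loci, learning and
fatigue beyond the session-offset hook, and irregular island shapes
(ellipses only). Passing tests therefore demonstrate correctness of the
analysis pipeline under a plausible generative model, not clinical validity
on real exams.

## Numerical and design choices

* Non-seen sentinel −1.0 is preserved verbatim in pointwise outputs and
  histograms; all global indices branch on it explicitly.
* Fujii boundaries use the strict inequalities (P1 exactly 75 is not
  stable).
* Degenerate repeatability inputs (all differences identical) return zero
  variance components rather than erroring; all-zero paired differences in
  the Wilcoxon wrapper return p = 1 by policy.
* Non-parametric tests call the standard `stats` routines; exact vs
  approximate p-values follow their sample-size rules. No multiple-testing
  correction is applied, matching common practice in this literature.
* Exclusion logs state one row per failed exam with reason enums; report
  denominators are always explicit.
* Test problem sizes: mixed-model recovery uses 20 subjects × 37 loci over
  50 replicates; bootstrap coverage uses 20 × 10 over 200 replicates with
  120 resamples (the closed-form engine makes this cheap); the gate
  calibration uses a 1000-exam cohort; Monte-Carlo BCEA coverage uses 10⁶
  samples. These sizes were chosen to keep sampling error well inside the
  asserted tolerances.

## Known limitations

* The triangulation of the perfectly symmetric radial grid has cocircular
  ties; a different tie-break could change individual triangles (not the
  flat-field volume, and in practice not the tested volumes).
* Mean-sensitivity sentinel handling and the device's exact staircase,
  BCEA constant and PRL estimator are inferred or configurable stand-ins,
  as the device internals are unpublished.
* The island-area scale of the generator is modest compared to areas traced
  on fundus autofluorescence in practice, because the emulated grid spans
  only the central 14°; structure–function correlations are driven by the
  within-cohort ordering, which is preserved.
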