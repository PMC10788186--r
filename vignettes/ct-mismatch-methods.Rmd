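---
title: "Methods: CT hypoperfusion-hypodensity mismatch vs. automated perfusion mismatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT hypoperfusion-hypodensity mismatch vs. automated perfusion mismatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctmismatch)
```

## The problem and the two classifiers

Intravenous thrombolysis is licensed up to 4.5 h after stroke onset, yet the
onset time is often unknown. Both classifiers in this package answer the
same question from admission CT alone: *is this patient (still) suitable for
thrombolysis?* A patient counts as eligible when imaged within 4.5 h of
onset, or later if the automated perfusion mismatch is present; the window
boundary is read strictly (exactly 4.5 h is *not* within the window).

**Hypoperfusion-hypodensity mismatch (HHM).** Ischemic tissue takes up
water, so its CT attenuation falls over time. The net water uptake of the
ischemic core relative to its mirror-image healthy counterpart,
$\mathrm{NWU} = (1 - \mathrm{HU}_{core}/\mathrm{HU}_{mirror}) \times 100\,\%$,
is therefore a tissue clock. HHM is present when a core lesion is visible on
the perfusion maps *without* a clear corresponding hypodensity on the
non-contrast CT — the hallmark of an early stroke. The human call "clear
hypodensity" is operationalised as NWU strictly above a threshold
$\delta$ (default 5 %); equality counts as doubt, and doubt is rated as
*absence* of hypodensity, reproducing the conservative reading rule the
original raters used. No published figure quantifies the HU deficit a rater
perceives as "clear", so $\delta$ is a calibration choice of this package,
exposed in the configuration; with the phantom's default uptake rate it
places the detectability flip near the 4.5 h window edge, consistent with
the observation that hypoperfusion and hypodensity usually match beyond
4.5 h. Negative NWU (core denser than mirror) is legal and reads as "no
hypodensity". A `slice_rule = "all_slices"` variant requires every
core-bearing axial slice to exceed $\delta$ individually (a match "should
encompass all slices"); on noise-free phantoms it coincides with the global
rule, and the global rule is the default.

**Automated perfusion mismatch (EXTEND criteria).** Core = CBF < 30 % of
the contralateral value; penumbra = Tmax > 6 s; positive when core < 70 mL,
absolute mismatch > 10 mL and mismatch ratio > 1.2. The published sentence
chains the clauses with an ambiguous "or"; we default to the conjunctive
reading (all three clauses), which is how the validating trial applied it,
and keep the literal disjunctive reading available as
`extendCriteria(logic = "disjunctive")` rather than resolving the ambiguity
silently. A zero core with non-empty penumbra has ratio $\infty$ (positive
if the absolute clause passes); an empty penumbra with empty core is
negative — nothing to salvage — not an error.

## Segmentation

The rater algorithm is: find the total ischemic area on "sensitive MTT or
TTD maps"; within it, find the core on CBV (< 2 mL/100 mL absolute or
< 30 % of contralateral); if no CBV lesion is present, fall back to CBF
(< 30 mL/100 mL/min or < 60 %). Choices this package had to make where the
published description is visual rather than numeric:

- *Ischemic area*: relative MTT > 145 % of the mirrored value OR
  Tmax > 6 s. The 145 % figure is a conventional penumbra threshold; it is
  configuration, not code.
- *Speckle*: the largest 26-connected component of the ischemic area is
  kept (a rater ignores isolated voxels); switchable off, and implemented on
  the voxel adjacency graph via `igraph`.
- *"No CBV lesion present"*: fewer than `minCoreVoxels` (default 1) voxels
  satisfy the CBV rule.
- *Absolute vs. relative criteria*: the text does not say whether raters
  required them jointly; the alternative (OR) reading is the default, with
  `cbvJoint = TRUE` as the AND switch.
- *Zero mirrored values*: a relative comparison against 0 is undefined;
  such voxels are judged on the absolute criterion alone.
- All masks are evaluated inside the brain mask only; the contralateral
  reference is the reflection across the midsagittal plane, assumed to be
  the central plane of the left-right axis (phantoms are generated
  pre-aligned; no registration stage exists).

Volumes are voxel count × voxel volume / 1000 (mL).

## The phantom: what it emulates and what it does not

`generatePhantom()` builds an ellipsoidal brain, mirror-symmetric about the
midsagittal plane, with an ellipsoidal penumbra confined to one hemisphere
and a concentric core. Defaults (all configurable, `phantomSpec()`):

| parameter | default | why |
|---|---|---|
| grid, spacing | 64×64×16 voxels at 2×2×5 mm | seconds-scale tests, multi-mL lesions, CT-like slice thickness |
| healthy baselines | HU 33, CBF 50 mL/100 mL/min, CBV 4 mL/100 mL, Tmax 0.5 s, MTT 4.8 s, TTD 6 s | conventional gray-matter values; MTT = CBV/CBF × 60 |
| penumbra | Tmax 8 s, MTT/TTD ×2, CBF 65 % of contralateral | clearly hypoperfused but above every core criterion |
| core | CBF 25 % of contralateral, CBV 1 mL/100 mL | below the relative CBF criterion and below *both* CBV core criteria |
| lesion radii | 20/20/18 mm penumbra, 10/10/9 mm core | ≈ 31 mL penumbra, ≈ 4 mL core: EXTEND-positive geometry |
| NWU | 1.3 %/h, cap 12 % | see below |
| NCCT noise | SD 0.5 HU | modest scanner noise; 0 for exact-recovery tests |

**NWU trajectory.** The package asserts only that water uptake follows a
characteristic monotone course; no quantitative trajectory is published in
the source we implement, so the phantom uses the simplest monotone,
continuous form — linear with saturation,
$\mathrm{NWU}(t) = \min(1.3\,\%/h \times t,\ 12\,\%)$ — and keeps it
swappable (`nwuTimeCourse()` is a free function; the rate and cap are
fields of the spec). The default rate makes the phantom's hypodensity cross
$\delta = 5\,\%$ at about 3.8 h, i.e. near the window edge. The generator
writes exactly this deficit into the true core, so on a noise-free phantom
the measured NWU equals `nwuTimeCourse(onset)` to floating-point precision
— which is what the recovery tests assert.

**Cohorts.** `generateCohort()` draws three strata: within-window patients
(onset from a normal with mean 2.7 h, SD 2.3 h, truncated to (0, 4.5)),
late-eligible patients (same distribution truncated above 4.5 h,
EXTEND-positive geometry), and late non-eligible patients (mean 8.27 h, SD
6.1 h, truncated above 4.5 h, EXTEND-*negative* geometry). Negative draws
are rejected and resampled. EXTEND-negative geometry is a "matched" lesion
— core radii equal to penumbra radii, so the mismatch ratio is exactly 1 —
which guarantees the non-eligible stratum fails the rule and the evaluated
specificity of the automated classifier is 100 % by construction, exactly
as in the observed cohort where the rule *defines* the late-eligible group.
Within-window patients receive EXTEND-positive geometry with probability
88/197 (the observed within-window detection rate; `CohortSpec` field
`extendPosRateWithinWindow`). Lesion radii are jittered by a common factor
in [0.85, 1.2], chosen so the EXTEND call per stratum stays guaranteed
(smallest mismatch geometry: ≈ 18 mL penumbra, ≈ 2.3 mL core, mismatch
≈ 16 mL > 10 mL).

The phantom deliberately omits: skull and CSF, partial-volume and
beam-hardening artifacts, patient motion, raw CTP time series and
deconvolution (the package consumes parameter maps, as the clinical
workflow does), and lesion shapes more irregular than ellipsoids. Passing
recovery tests therefore show the *rules* are implemented exactly, not that
the pipeline is robust to real-scanner artifacts; the noise knob only
perturbs the NCCT, where the HHM statistic lives.

## Statistics

Confusion tables count classifier calls against eligibility labels.
Sensitivity, specificity, PPV and NPV carry exact Clopper–Pearson 95 %
intervals computed from beta quantiles (lower bound 0 at $k=0$, upper bound
1 at $k=n$); the test suite checks them against a brute-force inversion of
binomial tail probabilities on a $10^{-4}$ probability grid. For a binary
test the AUC is $(\mathrm{sens}+\mathrm{spec})/2$, an identity asserted for
every table. The published analysis does not name its AUC CI method; we use
the Hanley–McNeil standard error (truncated to [0, 1]) and do not treat the
published AUC interval bounds as reproducible. Group comparisons use
Pearson's chi-square without continuity correction (the SPSS convention of
the original analysis), Fisher's exact test by flag, Student's equal
variance t-test, and the Mann–Whitney U-test (normal approximation without
continuity correction under ties; exact otherwise). Percentages are
reported with half-up rounding to one decimal, matching the published
tables; a metric with a zero denominator is NA, never fabricated.
`referenceCohort()` expands the published stratum counts into a 247-row
record table; only the per-stratum marginals are published, so the joint
assignment of the two classifiers within a stratum is arbitrary — it does
not affect any per-classifier confusion table.

## Reproducibility and problem sizes

Every stochastic step takes an explicit seed; `generatePhantom()` refuses
to run without one, and identical (spec, seed) pairs are bit-identical.
The pipeline regenerates phantoms one at a time rather than holding the
cohort in memory. The test suite runs the full 247-patient default cohort
(about 10 s), exact-recovery sweeps of 49 noise-free phantoms over 0–24 h,
2000-draw coverage checks of the exact intervals, and brute-force oracle
comparisons on 8×8×4 grids.

## Known limitations

- The hypodensity threshold $\delta$ emulates a rater with a single global
  statistic; real raters integrate texture and anatomy, so phantom HHM
  accuracy does not transfer to clinical accuracy.
- Ellipsoidal, pre-aligned, skull-free geometry; no registration errors.
- The NWU trajectory is a stand-in; rate and cap should be refit before any
  use against real data.
- The binary-test AUC and its Hanley–McNeil interval are descriptive only.
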