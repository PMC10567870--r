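---
title: "Identifying body fluids from CpG methylation: the methylfluid workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying body fluids from CpG methylation: the methylfluid workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylfluid)
```

## The problem

Forensic casework often needs to know not just *whose* DNA a stain contains
but *which tissue* it came from: vaginal secretion versus skin cells, nasal
blood versus peripheral blood, menstrual blood versus a blood/vaginal
mixture. Protein-based rapid tests exist only for blood (hemoglobin), saliva
(amylase) and sperm (seminal markers), and cannot be applied retrospectively
to extracted DNA. DNA methylation is stable, survives storage, and differs
systematically between secretions, so targeted bisulfite pyrosequencing of a
small CpG panel can fill the gap.

`methylfluid` implements a complete rule-based identification workflow for
seven secretions — nasal secretion, nasal blood, peripheral blood, menstrual
blood, saliva, vaginal secretion and sperm secretion — from six CpG markers:

| marker | CpG id     | targets                         | direction |
|--------|------------|---------------------------------|-----------|
| NB21   | cg16518142 | nasal secretion / nasal blood   | below 67% |
| B7     | cg13763232 | peripheral blood                | above 80% |
| MB4    | cg04255276 | menstrual blood                 | above 21% (tiered) |
| SA4    | cg21597595 | saliva                          | above 35% (partial > 18%) |
| V2     | cg26079753 | vaginal secretion               | above 50% (tiered) |
| N27SE  | cg20864568 | sperm (> 75%) and nasal (band)  | band      |

The central idea is that the three rapid pre-tests and the methylation panel
are *combined*: a confirmed-negative pre-test removes fluids from
consideration and thereby shrinks the non-target methylation range a marker
must clear, which lets several thresholds relax. The clearest example is the
N27SE nasal band: its upper bound is fixed at 70%, while the lower bound
drops from 40% (sperm excluded) to 30% (sperm and blood excluded) to 22%
(sperm, blood and saliva excluded).

## The decision procedure

`classify()` applies, in order:

1. **Exclusions.** A negative blood test excludes peripheral, menstrual and
   nasal blood; negative amylase excludes saliva; a negative seminal test
   excludes sperm. `not_done` excludes nothing and — equally important —
   *activates* nothing: threshold tiers conditioned on a negative pre-test
   stay inert until that test has actually been run and returned negative.
   This is deliberately conservative; thresholds only relax on confirmed
   negatives.
2. **Threshold tiers**, most specific first (see `default_thresholds()`).
   All comparisons are strict (`>` / `<`), values are compared at full
   precision, and a value exactly on a cutoff does not fire. Tiers are
   *full* calls (fluid clearly identified), *partial* calls (fluid present
   at least as a mixture component) or *mixture* calls (the MB4 18–21% band
   under a positive sperm test, which names menstrual blood *and* sperm).
3. **Pre-test-supported components.** A positive pre-test adds its fluid as
   a partial component when the methylation evidence does not contradict it.
   "Contradict" is defined per fluid: sperm is withheld when N27SE lies
   below 33%, the lowest value observed for sperm-containing mixtures;
   saliva is withheld when SA4 is at or below its 18% partial-component
   bound. A positive blood test that no marker can resolve into a specific
   blood-containing fluid yields the composite label `blood_unspecified`
   rather than a guess.

Conflicts resolve in favor of exclusion: if a tier names a fluid a pre-test
has excluded, the call is suppressed and a flag records the conflict.

Two ambiguities are reported rather than resolved, because the chemistry
cannot resolve them. NB21 below 67% identifies "nasal secretion or nasal
blood"; the package disambiguates only through the blood pre-test (positive
gives nasal blood, negative nasal secretion, otherwise the composite label
stays). And under a positive blood test with B7 in the 18–80% range and
V2 above 25%, menstrual blood cannot be distinguished from a mixture of
peripheral blood and vaginal secretion; a flag says so.

One subtlety in the nasal logic deserves a note. A stain with all three
pre-tests negative and N27SE at 29% is identified as nasal secretion *via
the saliva-negative tier* (lower bound 22), not the blood-negative tier
(lower bound 30, which 29 does not clear). The implementation carries the
full tier chain, so the call follows from whichever active tier actually
spans the value.

### Marker selection

`select_markers()` plans which assays to run from the pre-test pattern: the
blood-resolution panel (NB21, B7, MB4) only when blood is positive or
untested; SA4 unless amylase already excluded saliva; V2 unless blood is
confirmed present (in which case V2 cannot separate vaginal secretion from
menstrual blood and the blood panel takes over); N27SE always, being the
only marker for nasal samples, which have no rapid test. This reproduces
the three canonical casework patterns: all-negative gives {V2, N27SE};
blood and sperm positive gives {NB21, B7, MB4, N27SE}; saliva positive
alone gives {SA4, V2, N27SE}. `classify()` itself uses whatever markers the
profile contains; selection is a planning aid, not a gate.

## Quality control

Samples are measured in duplicate. `check_sample()` enforces three
acceptance rules: the bisulfite conversion control must pass (a failure
makes the whole sample unusable), the DNA concentration must reach
2.5 ng/µl (the defined input for conversion), and duplicates may deviate by
at most 5 *percentage points*. We read the duplicate rule as absolute
points, not relative percent: a relative rule would reject arbitrarily
small differences near 0% methylation, where four of the six markers sit
for most fluids. Failing markers are dropped, never imputed — the
classifier tolerates partial profiles and flags reduced coverage. A
single-replicate fallback exists behind an explicit `allow_single` policy
flag, default off.

## Calibration

`derive_cutoff()` formalizes how the panel's thresholds were set: place the
cutoff at the edge of the pooled non-target range, on the target's side.
For a below-direction marker the cutoff is `floor(min(non-target)) − 1 −
margin`; for an above-direction marker `ceil(max(non-target)) + margin`.
All published cutoffs are integers and this derivation keeps them so. The
published panel used heterogeneous margins (0 for B7, which sits exactly at
the non-target maximum of 80%; 4 points for MB4, whose cutoff of 21% sits
above a 17% non-target maximum, presumably as a safety band — the source
gives no rationale, so we preserve the margin as data rather than invent
one). Consequently the shipped defaults are authoritative and calibration
is used for validation and for extending the panel, not to regenerate the
defaults. Conditional cutoffs are derived by removing the pre-test-excluded
fluids from the non-target pool (`derive_marker_cutoff(..., exclude =)`).
Overlapping target/non-target ranges produce a warning with the fraction of
target values that no margin can recover — NB21 is the canonical case, and
its low sensitivity (61% in validation) is exactly that overlap.

## The synthetic cohort generator

No raw per-sample data accompany the reference study, so the package ships
a generator that reproduces the *published statistical structure* and makes
every pipeline stage testable end to end.

**Distribution family.** Each of the 36 (fluid group × marker) cells is
modeled as a beta distribution rescaled to 0–100 and moment-matched to the
cell's published mean and SD. Methylation fractions are bounded in [0, 1],
and the beta family is the standard model for them; unlike a normal
truncated or clamped at the bounds, it matches *both* moments exactly for
every cell, including boundary cells such as sperm at NB21 (mean 98.21,
SD 1.91) where any truncation scheme biases the mean by more than the
sampling error of a 10 000-sample cohort. Large simulated cohorts therefore
converge to the configured parameters, which is what the law-of-large-
numbers tests assert (n = 10 000 per fluid, 3-SEM tolerance).

**Outliers.** Three cells carry documented outliers: peripheral blood at B7
(7 of 42 samples down to 60%), sperm at N27SE (2 of 18, at 81% and 73%) and
nasal at N27SE (1 of 52, at 8%). The published mean/SD describe the full
sample *including* those values, so the generator treats each such cell as
a two-component mixture — outliers at their documented rate and positions,
and a core component whose moments are recovered by de-mixing so that the
mixture reproduces the published moments. The de-mixed B7 core (mean 90.2,
SD 1.7) lands neatly inside the published core range of 86–93%, which is a
good consistency check on this reading.

**Mixtures.** A mixed stain's methylation is the DNA-mass-weighted mean of
independent single-source draws, the standard model for pooled DNA. The
reference study reports only empirical ranges for its lab mixtures, without
mixing proportions; notably its nasal + vaginal mixtures at N27SE ran
17–21%, below the equal-weight mean of the component means (23.0), so no
single default weight reproduces them and weights are left fully
configurable.

**Pre-tests and noise.** `derive_pretests()` sets a rapid test positive
when the triggering components jointly exceed a detection-floor weight
(default 0, i.e. ideal tests). Duplicates are the latent value plus
independent uniform noise of ±2.5 points, so pairwise deviation respects
the 5-point QC bound by construction; QC failures (deviation exceedances,
conversion-control failures) are injectable at configurable rates for
testing the QC path. Simulated concentrations are uniform on 2.5–20 ng/µl,
respecting the protocol's minimum. One master seed deterministically
derives a sub-stream per design block, so identical (design, seed) give
identical cohorts.

**Post-menopausal vaginal samples** showed a markedly lower V2 signal
(mean 22%, SD 7%, n = 4) in the reference data; the generator exposes this
as an optional extra group (`marker_distributions(include_postmenopausal =
TRUE)`), off by default given the tiny reference sample.

**What the generator does not emulate.** Values are summary methylation
percentages, not read-level bisulfite sequencing; inter-assay batch
effects, degradation, inhibitors and within-fluid donor correlation across
markers are not modeled (cells are drawn independently per marker).
Passing tests on synthetic cohorts therefore demonstrate the *logic* of the
workflow under the published distributional assumptions, not field
performance on casework.

## Validation metrics

`validation_report()` scores a labeled cohort marker by marker into the
confusion layout of a validation study: per (marker, target, truth-fluid)
cell, the cohort size and how often the identifying rule fired.
`confusion_summary()` reduces that to sensitivity and specificity,
rounded half-up to two decimals; rates over empty cohorts are
not-applicable (`NA`), never 0. N27SE is scored twice — once per target —
and for each target row the other target's cohort is omitted, mirroring the
dual-target layout of the published table. The published validation counts
ship as a plain-text fixture (`published_validation_counts()`); for the
V2/vaginal cell, where the printed table (10/10) and the running text
(9/10) disagree, both variants are recorded and selectable.

## Numerical choices and problem sizes

Strict inequalities everywhere, exactly as printed; no rounding before
comparison; percentages half-up to two decimals; cutoffs integer by
construction. The test suite exercises single cells at n = 10 000–20 000
draws and full cohorts of 10 000 samples per fluid for the boundedness and
convergence properties, with classification spot-checked on systematic
subsamples — sizes chosen so the full suite runs in well under a minute
while keeping 3-SEM assertions meaningful.

## Known limitations

* A moment-matched beta reproduces each cell's mean and SD but not its
  observed *range*: its tails extend over all of [0, 100], so noisy
  synthetic cohorts show occasional threshold crossings (false positives)
  that the cleanly separated reference ranges did not. Idealized
  (`sd = 0`) cohorts, where every fluid sits at its reference mean,
  reproduce the published 100% specificity exactly.
* NB21 cannot see nasal mixtures: nasal + vaginal and nasal + sperm
  mixtures ran 71–95% in the reference data, above the 67% cutoff, and are
  reported as such by the classifier (no nasal call) — a reproduced blind
  spot, not a defect.
* Menstrual blood versus peripheral blood + vaginal secretion is
  structurally unresolvable; the classifier flags it.
* The decision order implements the documented workflow and the three
  published worked cases; any further branches of the original workflow
  figure that are not described in text are not guessed.
* Sensitivities published for the real validation cohort cannot be
  recomputed here (no raw data are deposited); the package reproduces their
  arithmetic from the printed counts and verifies classification behaviour
  on synthetic cohorts instead.
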