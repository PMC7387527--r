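---
title: "Methods: TMTV delineation, agreement and prognosis in tmtvkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TMTV delineation, agreement and prognosis in tmtvkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Total metabolic tumor volume (TMTV) — the volume, in cm³, of all voxels of an
FDG-PET image classified as tumor — is a quantitative burden marker used for
staging and prognosis in lymphoma. In routine practice TMTV is obtained by
drawing a region of interest around the avid disease and applying a SUV
threshold inside it: either a fixed absolute cutoff (SUV > 2.5) or a relative
one (SUV > 41% or 50% of the regional SUVmax). Both the contouring workflow
and the threshold choice change the measured volume, and therefore the
prognostic cutoffs derived from it. `tmtvkit` implements the whole comparison
pipeline — volume-of-interest (VOI) construction, threshold segmentation,
metric extraction, paired agreement statistics, and ROC/Kaplan–Meier
prognostic analysis — together with a seeded synthetic phantom cohort
generator that stands in for clinical data, which cannot be redistributed.

# Image model and conventions

A `suv_volume` is a 3D grid of nonnegative SUV values with voxel spacing and
a world origin in millimetres. Voxel `(i, j, k)` (1-based) has its center at
`origin + (c(i,j,k) - 1) * spacing`; the third index is the axial (slice)
axis. All region membership — ellipsoid ground truth, polygon ROIs — is
decided by the **voxel center**: a voxel belongs to a region iff its center
does. Polygon membership uses the even-odd (ray crossing) rule; points
exactly on an edge are resolved deterministically by the crossing arithmetic
but should be treated as undefined boundary behaviour.

Segmentation is **strict**: a voxel is selected iff its SUV is strictly
greater than the applied threshold. The single predicate
`suv_over_threshold()` encodes this so the opposite convention would be a
one-line change. The same strict `>` is used when a cohort is dichotomised at
a prognostic cutoff. No connected-component filtering is applied anywhere:
excluding physiological uptake is the VOI's job, not the threshold's.

For a relative threshold, the reference SUVmax is the maximum **over the
VOI** (not the whole volume): the threshold is applied to the defined VOI,
and any avid structure captured by the VOI — tumoral or not — legitimately
participates in the reference. This is the mechanism by which a sloppy VOI
corrupts relative thresholds but not absolute ones.

# VOI strategies

Three contouring idioms are modelled:

* **Single-region prism** (`extrude_single_roi`): a 2D region drawn on one
  axial slice is copied to every slice of a given range. Anything inside the
  footprint at other depths is swallowed, including physiological hot
  structures (heart, brown fat analogues). This failure mode is deliberate
  and must not be "fixed" in the prism code path: it is one of the phenomena
  the package exists to quantify.
* **Slice-wise editing** (`stack_slicewise_rois`): an individually edited 2D
  region per slice, union over slices; physiological voxels can be erased
  slice by slice.
* **Per-lesion regions** (`lesion_set` + `delineate_multiple`): one VOI per
  lesion, pairwise disjoint; TMTV is the sum over lesions, SUVmean the
  volume-weighted mean over the union. For relative thresholds the reference
  SUVmax is per-lesion by default (`suvmax_scope = "per_lesion"`), with a
  `"global"` option; the choice is echoed in every result because the two
  readings genuinely differ for unequal lesions.

Empty-mask policy differs by mode on purpose: a single-VOI delineation with
an empty mask is an error (the caller asked for exactly one region and got
nothing), while in multi-lesion mode a cold lesion contributes zero with a
warning, so one cold lesion cannot abort a cohort run.

# Metrics

From a segmentation mask the package extracts TMTV (voxel count × voxel
volume), SUVmean, SUVmax, TLG = SUVmean × TMTV, and SUVpeak. SUVpeak is the
maximum, over candidate centers, of the mean SUV inside a 1.0 cm³ sphere
(radius ≈ 6.2 mm) of voxel centers, clipped at grid edges (clipped members
leave both numerator and denominator). The candidate scope is configurable:
`peak_scope = "voi"` scans the whole VOI, making SUVpeak identical across
thresholds applied to that VOI; `peak_scope = "mask"` scans only the
thresholded mask, making SUVpeak threshold-dependent. Both behaviours exist
in clinical software, and the package treats the scope as an explicit
parameter rather than an implementation accident.

# The phantom generator

`generate_phantom()` renders a `phantom_spec`: a uniform background, plateau
ellipsoid lesions, optional physiological hot structures, isotropic Gaussian
blur of stated FWHM (σ = FWHM/2.355 per axis, kernel truncated at 4σ,
normalised, zero-padded), then additive Gaussian noise in SUV space clipped
at zero. Ground truth is the **unblurred** voxel-center ellipsoid
membership; the partial-volume bias that blur induces downstream is exactly
what the threshold comparison is meant to expose. Blur conserves total
activity to well under 1% for objects a few FWHM from the grid edge; near
the edge the zero padding lets the background decay, which is why edge
regions are excluded from profile assertions in the tests. Overlapping
structures are rejected outright — ground truth would be ambiguous — and so
are structures extending beyond the grid.

Noise is Gaussian in reconstructed-SUV space, not Poisson in counts: the
package operates entirely downstream of reconstruction, and count-space
simulation is out of scope.

## Cohort defaults

`cohort_sampler()` fixes the study conditions for a synthetic cohort. The
defaults were chosen once, from the following reasoning, and are not
re-tuned per analysis:

* **Grid** 64 × 64 × 48 voxels at 3 mm isotropic — a torso-like field of
  view at a typical reconstructed PET resolution.
* **Lesions**: 1–4 per subject, base radius 10–30 mm with mild anisotropy,
  so that cohort TMTV₂.₅ spans roughly 10–700 cm³ with a median near
  120 cm³, matching the scale of published staging cohorts; 9% of subjects
  carry a bulky mass (base radius 40–55 mm).
* **Uptake**: one patient-level plateau SUV ~ U(4, 15) with a per-lesion
  U(0.75, 1.25) factor. Same-patient lesions of one lymphoma have correlated
  uptake; with independent uptakes a cooler plateau lesion would often sit
  between 41% and 50% of the hottest lesion's SUV and flip discontinuously
  in or out of the relative-threshold mask — an artifact of
  piecewise-constant phantoms that smoothly graded real lesions do not show.
* **Physiological structure**: one cardiac analogue (radius 14–22 mm),
  present in 80% of subjects, placed near the lesions' in-plane centroid and
  within their axial extent, the way the heart sits between nodal stations —
  so the prism tends to capture it while slice-wise editing avoids it. Its
  uptake is bimodal, reflecting dietary myocardial suppression: suppressed
  U(1.2, 2.4) (blood-pool level, invisible to every threshold) with
  probability 0.5, otherwise intensely avid U(14, 20), which typically
  exceeds nodal uptake and then hijacks the SUVmax reference of any VOI that
  captures it.
* **Reconstruction**: 6.0 mm FWHM blur (a typical clinical Gaussian
  post-filter; 4.8 mm is the common alternative), noise SD 0.2 SUV.
* **Outcomes**: progression-free survival from an exponential event-time
  model whose rate grows with true total lesion volume
  (`rate = 3e-4 · volume` per month by default, or a step at a stated
  volume), censored uniformly over a 3–104 month follow-up window.

## What the phantoms do and do not emulate

They emulate: blur-induced partial-volume bias, threshold-dependent volume
recovery, physiological contamination of careless VOIs, SUVmax hijack of
relative thresholds, outcome dependence on tumor burden. They do **not**
emulate: intra-lesion uptake gradients or necrosis, respiratory motion,
scatter/attenuation artifacts, reconstruction-algorithm differences between
scanners, or elevated peri-lesional background. Consequences worth spelling
out:

* With a clean low background, a fixed 2.5 cutoff **under**-segments
  low-avidity lesions: a blurred edge between background *b* and plateau *u*
  crosses 2.5 inside the true boundary whenever (u + b)/2 < 2.5 (e.g. u = 4,
  b = 0.3). The clinical observation that SUV 2.5 *over*-estimates volumes
  rests partly on elevated real-tissue background around lesions, which the
  phantom does not model. The overestimation direction is therefore asserted
  for avid lesions (u ≳ 6), where the blurred edge midpoint genuinely sits
  above 2.5.
* Plateau lesions make relative-threshold masks change more abruptly with
  the reference SUVmax than graded real lesions would; within-strategy
  41%-vs-50% agreement in an arm whose SUVmax is hijacked by the cardiac
  analogue is accordingly more fragile in the phantom world than the
  clinical literature suggests for carefully supervised contours.

# Agreement statistics

Paired method comparisons use the natural-log transform (burden metrics are
right-skewed; the base changes bias values but not t, p or r), a paired
two-tailed Student t test (degenerate zero-variance differences yield p = 1
if the arms are identical, otherwise p = 0 with a warning), Pearson
correlation (emitted on both log and raw scales; log is the analysis
default), and Bland–Altman analysis with fixed 1.96·SD normal-approximation
limits. Pairs outside the limits are flagged and **retained** — flags are
report annotations, never exclusions. No multiple-testing correction is
applied; the reports carry n so downstream users can correct as they see
fit.

# Prognostic analysis

`roc_with_youden()` uses candidate cutoffs at midpoints between consecutive
distinct scores plus ∓∞ sentinels, calls a subject positive when its score
is strictly above the cutoff, integrates AUC by trapezoid (equal to the
rank-sum form with ties counted ½), and picks the Youden-index maximiser
with ties broken toward the **smallest** cutoff (the more sensitive split;
the tie-break is echoed in every report). The ROC label is "event observed
during follow-up"; subjects censored very early can optionally be excluded
from the ROC via a horizon (never from the survival curves) — with no
horizon, early-censored subjects count as negatives, a stated limitation of
short follow-up. Kaplan–Meier estimation and the log-rank test are delegated
to the `survival` package (product-limit convention: subjects censored at an
event time remain at risk at that time); the package's own tests pin the
hand-worked closed forms.

# The study runner

`run_study()` executes the full grid: phantom cohort → three automated
contouring strategies (convex-hull prism, slice-wise editing with
physiological erasure, per-lesion dilation) → three thresholds → agreement
rows for every within-strategy threshold pair and every between-strategy
pair per threshold → a prognostic report per arm. The automated "reader"
derives contours from ground truth with a 6 mm safety margin: the prism
footprint is the margin-grown convex hull of the projected lesions (grown
via an 8-direction ring so it contains the true Minkowski offset), which
guarantees the prism VOI is a superset of the per-lesion union — hence
prism TMTV at an absolute threshold can never undercut the per-lesion sum.
All randomness derives from one root seed (per-subject sub-seeds are drawn
up front), outputs are byte-identical across reruns, and every CSV carries
the configuration hash in a leading comment.

Problem sizes used by the shipped analyses: the default comparison cohort is
50 phantoms on the 64³-scale grid; the threshold-ordering cohort is 20
phantoms restricted to uptake 6–15 without the physiological structure (the
direction under test concerns thresholds against clean ground truth, not
contouring); cutoff recovery uses 20 cohorts of 30 subjects with a step
hazard at 120 cm³ — near the sampler's median burden, so the two risk
classes stay populated — plus one 200-subject cohort for discrimination.

# Numerical choices and degenerate inputs

* Blur kernels are renormalised after truncation, so flat fields stay flat
  away from edges.
* The SUVpeak sphere uses voxel-center membership and edge clipping; its
  volume (1.0 cm³) and the scope are explicit parameters.
* Relative thresholds on an all-zero VOI are an error (the reference would
  be 0); empty VOIs are an error everywhere.
* `log_transform` refuses nonpositive values and names the offending
  subjects.
* A log-rank comparison with no events in either group warns and returns
  p = 1; an empty side of a cutoff split warns but proceeds — both occur
  legitimately in small cohorts.
* Ties: polygon-edge voxel centers follow the even-odd arithmetic; score
  ties at a cutoff go to the low group (strict >); Youden ties go to the
  smallest cutoff.

# Known limitations

The generator's realism boundaries above are the main caveat: conclusions
about *mechanisms* (which threshold is robust to which contouring failure)
transfer; absolute numbers (volumes, cutoffs, correlation magnitudes) are
properties of the synthetic conditions. The CLI is a thin wrapper over the
documented functions and does not attempt batch scheduling. DICOM input,
adaptive/iterative thresholds and partial-volume correction are out of
scope.
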