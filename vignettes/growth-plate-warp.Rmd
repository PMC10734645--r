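---
title: "Modelling the dorsal warp of the trochanteric growth plate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the dorsal warp of the trochanteric growth plate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trochwarp)
```

## The scientific problem

The apophyseal growth plate of the greater trochanter is one of very few
warped growth plates in the human skeleton. In frontal MRI slices its
ventral portion runs roughly parallel to the femoral neck (about 50 deg to
the body horizontal) while its dorsal portion lies almost flat (under
20 deg). Growth plates align perpendicular to the forces acting on them, so
the warp is a readable record of the regional loading: somewhere between the
middle and dorsal thirds the force resultant acting on the trochanter must
rotate toward vertical.

trochwarp implements this chain of reasoning as a tested pipeline. It

1. generates synthetic proximal-femur *phantoms* whose plate carries a
   planted per-layer inclination (*warp profile*);
2. emulates the MRI measurement protocol — frontal/axial slice stacks,
   calibration-slice selection, layer indexing, per-slice line fits and the
   *AY angle* (plate inclination to the body horizontal);
3. computes straight-line muscle trajectories from origin/insertion pairs;
4. combines trajectories with literature physiological cross-sectional
   areas (PCSA) in a tension-band force model that predicts the regional
   plate angle.

Because the underlying patient images are not public, the package's
validation strategy is planted-parameter recovery: every measured quantity
can be checked against the value that was planted in the phantom.

## Coordinate conventions

All geometry lives in a right-handed frame with x lateral (toward the
measured hip), y ventral, z cranial; millimetres and degrees throughout.
The body frame is built from two midline landmarks: the vertical axis runs
from the center of the anus to the center of the sacral vertebrae, and the
horizontal axis is its orthogonal within the frontal plane. Slice stacks
are always cut along the scanner axes; a tilted landmark pair therefore
shifts every measured angle by exactly the tilt, which the test suite uses
as an equivariance check.

Frontal layers are labelled 1 (most ventral) to 12 (most dorsal) around the
calibration slice — the slice of maximal plate extent, fixed at label 6.
Axial stacks use the analogous scheme around label 5 (largest trochanter
diameter), following the published index functions f(x) = 5 − x cranially
and f(y) = 5 + y caudally. The measurement protocol's wording would also
admit an 11-layer reading (five slices to each side of the calibration
slice); we adopt the 12-layer reading used by the published layer plots.

## The default warp profile is a constrained reconstruction

The study that motivates this package published six constraints on the mean
12-layer profile but not the individual layer means (they appear only
graphically): ventral-third mean 51.64 deg, dorsal-third mean 18.6 deg,
calibration-layer angle 43.7 deg, a +2 deg rise from layer 1 to layer 2, a
total layer-1-minus-layer-12 decrease of 33.44 deg, and the largest
inter-layer jump between layers 8 and 9, with angles non-increasing from
layer 2 on. `build_default_warp_profile()` solves this under-determined
system once, by a fixed interpolation rule:

* layer 1 is anchored at 51.5 deg. Monotonicity makes the choice tight:
  because layer 12 = layer 1 − 33.44 must not fall below the dorsal-third
  mean of 18.6, layer 1 cannot exceed 52.04; 51.5 keeps the ventral plate
  close to the ~52 deg femoral-neck inclination reported for its ventral
  portion.
* layers 3–4 continue linearly from layer 2 with the step fixed by the
  ventral-third mean; layer 5 is the midpoint of layers 4 and 6; layers 7–8
  continue at the layer-4-to-6 rate, which leaves the 8-to-9 jump as the
  dominant drop;
* the dorsal third is linear with slope fixed by its mean and the total
  decrease.

```{r}
p <- build_default_warp_profile("pooled")
round(unclass(p), 2)
c(ventral = mean(p[1:4]), dorsal = mean(p[9:12]),
  calibration = p[[6]], decrease = p[[1]] - p[[12]])
```

The interpretation is deliberate: this profile *satisfies* the published
constraints; it is not the study's raw data. The "total decrease of
33.44 deg" is read as the endpoint difference layer 1 − layer 12 (the
thirds-mean difference would give 33.04, inconsistent with the printed
value), and the AY angle is unsigned in [0, 90] because the manual protocol
measures an acute angle to the horizontal.

The adult default equals the pooled reconstruction. Juveniles show a
smaller dorsal decline; since no juvenile layer values were printed, the
juvenile default keeps the ventral and middle thirds and raises the dorsal
third so the total decrease is 8 deg smaller. The exact offset is
configurable, and the group-comparison machinery never assumes it.

## What the phantoms emulate — and what they do not

`generate_phantom()` realizes a spec as (i) twelve plate-trace segments,
one per layer, inclined exactly at the planted warp angle and tapering in
length away from the calibration layer (2% per squared layer distance, so
the calibration slice is a stable argmax); (ii) an ellipsoidal trochanter
point cloud for axial slicing, placed by the CCD angle and rotated by the
anteversion; (iii) midline landmarks; (iv) muscle attachment point pairs
copied from the attachment map. Noise, when enabled, is isotropic Gaussian
on every trace and surface point (default cohort SD 0.5 mm — no
measurement-error model was published, so this is a conventional choice for
manual point placement on 3 mm MRI slices). Cohorts additionally draw each
member's warp with a configurable angle jitter (biological variation) and
its CCD angle around the group mean, juveniles (145 deg, coxa valga) above
adults (130 deg).

The phantoms are geometric, not radiological: no grayscale synthesis, no
cartilage-thickness model, no growth over time, and the plate is ruled
(straight within each slice), which is exactly the assumption of a
per-slice line fit. Passing the recovery tests therefore shows that the
measurement chain is unbiased for geometry of this class; it cannot show
robustness to segmentation error on real images.

Determinism is a contract: identical `(spec, seed)` give bitwise-identical
phantoms; cohort members get child seeds derived from the master seed by a
fixed increment.

## Measurement chain and numerical choices

`measure_profile()` composes slicing, calibration selection, line fitting
and the AY angle:

* trace lengths are polyline arc lengths and trochanter diameters maximal
  pairwise distances — the natural readings of "extent" and "diameter";
  ties break toward the more ventral/cranial slice (arbitrary but fixed);
* line fits are total least squares (principal axis of the in-plane
  scatter), with points first projected into the slice plane so
  out-of-plane noise cannot tilt the fit; directions are signed toward
  lateral. A degenerate symmetric trace (a balanced V) yields the
  principal axis of its scatter — documented rather than rejected;
* with all 12 layers present, `summarize_profile()` reports the thirds
  means (layers 1–4 / 5–8 / 9–12), the calibration angle, the endpoint
  decrease, and the transition pair: the largest consecutive-layer jump
  among pairs (k, k+1) with k >= 2. The ventral 1-to-2 rise is excluded so
  the detector reports the dorsal jump, not the ventral bend. Missing
  layers surface as NA fields, never as imputed values.

`compare_groups()` reports the adult-minus-juvenile difference in the
total decrease with a patient-level bootstrap percentile interval (1000
replicates, seeded); the published comparison reported a group difference
without naming a test, so a distribution-free interval is supplied.

```{r}
ph <- generate_phantom(default_phantom_spec("pooled"), seed = 1)
summarize_profile(measure_profile(ph))
```

## Muscle trajectories

Straight-line trajectories connect origin and insertion; the direction
points from the femoral attachment toward the other attachment, which makes
abductor frontal angles positive as published (the convention itself was
not stated there). Frontal angles are signed elevations above the
horizontal (negative = caudomedial); transverse angles are taken to the
frontal plane (negative = dorsomedial). The two planar angles determine a
direction up to reflection; reconstruction resolves toward medial.

The default attachment map is reverse-engineered from the published mean
angles: femoral points sit on the trochanter, offset per region, and the
paired point lies along the reconstructed direction. It is a modelling
fixture that reproduces the published angles exactly — not anatomy. Where a
muscle was measured in only one plane, the other plane's angle falls back
to the muscle's middle-region value or 0; the map records the targets it
was built from, and the tests assert the round trip.

A centroid-method oracle (`centroid_direction()`, the chord of the
section-centroid polyline) is included because the two methods coincide
exactly for straight prismatic muscles — the stated rationale for using
the straight-line method — and the equality is a test, not an assumption.

## The tension-band force model

Three systems act on the trochanter: the internal band (gluteus medius and
minimus, vastus lateralis), the external band (gluteus maximus, tensor
fasciae latae, iliotibial band) and the posterior system — the external
rotators (piriformis, triceps coxae as the gemelli/obturator-internus unit,
obturator externus, quadratus femoris), which attach exclusively to the
dorsal third. Muscle forces are `sigma * PCSA * direction`; the specific
tension `sigma` cancels in every angle. The split gluteus maximus
contributes its two frontal parts at half its area each.

The rotators have no opposing muscle; their loop is closed by passive
periosteal tension over the trochanter tip. We model this counterforce as a
vector of magnitude `beta * |rotator resultant|` directed caudally and
tilted laterally by `phi`. The published sketch of this parallelogram is
qualitative, so the defaults are fixed by an inspectable calibration
rather than by eye:

* `phi = 75 deg` (mostly lateral, slightly caudal) encodes a loop that
  "initially runs at a slight angle to the lateral side and then turns to
  the caudal side";
* `beta` (default `NULL`) is solved from frontal-plane horizontal
  equilibrium at the tip: the counterforce's lateral component cancels the
  rotators' medial pull (`calibrate_periosteal_beta()`, beta ~ 0.46 for
  the Lube areas). With that closure the posterior resultant is vertical
  in the frontal projection — the "almost vertical" dorsal vector — and
  stays near-vertical under parameter perturbation.

A smaller `phi` would make the counterforce mostly caudal; the balanced
resultant then loses its cranial component and the model can no longer
order the regions correctly, which is why the caudal-dominant reading of
the sketch was rejected during design.

`warp_prediction_profile()` assembles the regions: the ventral third sees
the lateral systems at their ventral-region trajectories, the middle third
at their middle-region trajectories, and the dorsal third adds the
posterior system (rotators at dorsal/caudal trajectories plus counterforce)
to the middle-third lateral load. The dorsal prediction thus differs from
the middle one exactly by the system that attaches only there — zeroing
the rotator areas collapses the two, a property the tests exercise as an
ablation. The iliotibial band and the vastus fascial coupling have no PCSA
of their own and enter as configurable equivalent areas (default 0).

```{r}
res <- warp_prediction_profile("lube")
res
```

Predicted angles are read from the perpendicularity principle:
`90 - elevation` of the regional resultant. The model is directional, not
calibrated in newtons: it reproduces the *ordering* ventral > middle >
dorsal and the near-vertical dorsal resultant for each of the three
per-muscle PCSA sources, which is the qualitative claim at stake. The
printed per-muscle table carries one suspected decimal-typo (obturator
externus 3795 in the Brand column) which is stored as printed with a
correction flag; the force model uses the corrected 3.795 by default, and
the Brand column's missing quadratus femoris contributes zero area with a
warning. Grouped-sum arithmetic keeps a hard error instead, so a sum over
an incomplete column cannot silently disagree with the published table.
The published grouped table also lists obturator *internus* as a rotator
group member, but only obturator *externus* reproduces its printed sums
from the per-muscle areas; the consistent reading is implemented and both
printed and recomputed ratios are reported.

## Problem sizes and reproducibility

The validation suite runs entirely on synthetic data built at test time:
single phantoms for exact recovery (12 layers, 9 points per trace), 100
random specs for the round-trip property, and Monte-Carlo studies of 200
seeded reruns with cohorts of 20 (layer-mean recovery at 1 deg warp
jitter, 3-SE criterion per layer; the per-layer nominal coverage of a 3-SE
band is 99.7%) and of 5 + 5 (sign recovery of a planted 10 deg group
difference). These sizes give stable statistics while keeping the full
suite under a minute on a single core. `scripts/acceptance.R` re-runs the
deterministic chain — default pooled phantom, full measurement, summary,
and the attachment-map angle recovery — and writes the headline numbers as
JSON.

## Known limitations

* The default pooled profile is one member of the constraint set's solution
  family; layer-level values between the anchors are interpolation, and any
  statistic not pinned by the six constraints inherits that uncertainty.
* The phantoms' ruled-plate geometry matches the per-slice line-fit
  assumption by construction; real plates curve within slices.
* The force model ignores gait-phase dynamics, absolute magnitudes and the
  whole-hip resultant; it is a static directional argument.
* Juvenile defaults (CCD 145 deg, 8 deg smaller decrease) are plausible
  settings, stated as configurable parameters, not estimates.
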