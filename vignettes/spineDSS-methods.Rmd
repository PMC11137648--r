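---
title: "spineDSS: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spineDSS: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spineDSS)
```

## The clinical problem and the pipeline

Lumbar disc herniation (LDH) — displacement of nucleus pulposus through the
annulus fibrosus beyond the disc margin — is evaluated on T2-weighted MRI.
Two established grading schemes summarize what a surgeon needs: the **MSU
classification** (herniation size 1/2/3 by posterior extent relative to the
intra-facet line; location A/B/C from central to lateral, on an axial
slice), and the **Pfirrmann grade** (I–V degeneration severity from T2
signal, nucleus/annulus distinction and disc height, on a sagittal slice).

spineDSS implements a fully automatic pathway over these schemes:

1. **Localization** — detect vertebral bodies on a sagittal slice (bones,
   not discs, carry the more reliable features), then repair the resulting
   landmark chain with anatomical constraints.
2. **Diagnosis** — crop the posterior half of each intervertebral disc into
   an oriented ROI and classify it herniated / normal.
3. **MSU classification** — on the matching axial slice, build the region
   grid from six marker points, segment the herniated area, and assign
   (size, zone) from the region containing the herniation apex.
4. **Pfirrmann grading** — for surgically relevant discs (MSU size 2/3 in
   the pipeline gating; the library grades any disc on request), extract a
   texture/shape descriptor from an oriented disc crop and grade I–V with a
   multi-layer perceptron.
5. **Advice** — a deterministic rule table converts the assessment into
   management advice with a full rule trace.

Every stage that would be a learned network at clinical scale (vertebra
detector, axial marker detector, mask segmenter, classifiers) sits behind a
pluggable function interface with a classical reference implementation, so
the geometric and statistical substance of the pipeline is testable without
GPU training.

## Anatomical constraint repair

With vertebra centers $P_1..P_n$ ordered cranial→caudal and segment lengths
$V_i = \lVert P_{i+1}-P_i \rVert$, a chain is anatomically plausible when

* **distance**: $\lambda_1 < V_i / V_{i-1} < \lambda_2$ at every interior
  vertex, and
* **angle**: $\theta_1 < \angle(P_{i-1},P_i,P_{i+1}) \le \theta_2$,

with defaults $\lambda_1 = 0.6$, $\lambda_2 = 1.25$, $\theta_1 = 140°$,
$\theta_2 = 180°$. Two numerical choices deserve note:

* The angle bound is applied with an **inclusive upper limit**: a perfectly
  straight chain measures exactly 180°, which is the anatomical ideal, not
  a violation.
* A violated constraint at vertex $i$ implicates $P_i$. Endpoints have no
  vertex constraint; they are flagged when their single segment departs
  from the **median** segment length by more than the $\lambda$ band —
  except when the adjacent interior vertex is itself implicated, in which
  case the anomalous segment is already explained and the endpoint is
  trusted. Without this exception an interior outlier near the chain end
  drags the (correct) endpoint into repair from long-range extrapolation,
  which is exactly the failure the repair step exists to prevent.

**Replacement estimator.** Deviant points are re-estimated linearly in
chain index from the nearest non-deviant anchors: interpolation between the
flanking clean points where both sides have one (the midpoint of the
immediate neighbors in the common case), extrapolation from the two nearest
clean points on one side otherwise. Because a single displaced landmark
perturbs the ratios evaluated at its neighbors, the trusted anchors can be
two or three indices away; linear interpolation across that span commits a
sagitta error of roughly $L^2/8R$ against the true lordotic arc — about
1–3 mm at typical lumbar curvature, comfortably inside the 4-mm acceptance
threshold used for localization sensitivity. Sweeps repeat (default at most
5) until clean; if every interior landmark is deviant the chain is declared
unrepairable, since the method requires a core of correct reference points.

**Known limitation.** A chain *endpoint* displaced parallel to its segment
direction barely changes any constraint and cannot be detected by this
rule set; the closed-loop validation therefore injects outliers at interior
positions, and detector quality at the chain ends matters more than
elsewhere.

## Posterior ROI and diagnosis

The diagnosis ROI is an oriented rectangle whose long side is the segment
between two adjacent vertebra centers and whose short side extends a fixed
44 px from that line toward the dorsal side, i.e. over the posterior disc
half where herniations protrude. The short side is taken perpendicular to
the segment (the supplied dorsal vector only chooses the side), so the
crop is a true rectangle; pixels outside the image read 0, and the patch is
resampled bilinearly to 64×44. The reference classifier feeds the shared
572-dimensional descriptor (below) into a two-class softmax head — the same
interface a CNN would implement.

## MSU grid geometry

From disc center $D$ and dorsal canal point $Q$ the grid frame is
$\hat u = (Q-D)/\lVert Q-D \rVert$ (anteroposterior, dorsal positive) and
$\hat v = \hat u$ rotated +90° (lateral, left negative). The six marker
points contribute per-side intra-facet reference points (midpoint of the
superior and inferior facet apices on each side); the intra-facet line
joins them and crosses the AP axis at $s_{if}$, the size-3 boundary. The
posterior disc margin $M$ — carried as an explicit seventh annotation point
because the size-1 band needs an origin that the disc center cannot supply —
gives $s_0$; the size-1/2 boundary sits halfway between $s_0$ and $s_{if}$.
Lateral zone boundaries lie at half (A/B) and at the full (B/C) lateral
coordinates of the intra-facet reference points.

The apex is the mask pixel with maximal $s$ (ties: smallest $|t|$, then
raster order). Size boundaries are inclusive downward except $s_{if}$
(size 3 requires strictly beyond); lateral boundary ties go to the more
lateral zone. These tie-breaks make labels deterministic; on phantoms they
are unobservable because apexes are planted with a ≥ 2 px margin from every
boundary. Compound zones (e.g. "2-AB") are not emitted: assignment is by a
single apex point.

The reference segmenter is intensity thresholding restricted to the band at
and dorsal of the posterior margin ($s \ge s_0$), largest connected
component, hole filling (connected components and hole filling via
EBImage). An `identitySegmenter` adapts a manual mask to the same
interface.

## Pfirrmann descriptor and MLP

The grading crop is an oriented rectangle centered between two vertebra
centers: width and orientation follow the inter-center line, the long axis
spans the disc laterally (1.5× the inter-center distance, resampled to
96×48). Three blocks are concatenated, each normalized to sum 1:

| block | length | captures |
|---|---|---|
| HPI, 64 equal-width bins over [0, 255] | 64 | global darkening from disc water loss |
| LBP, 8-neighbor radius-1 codes (ties ≥), border excluded | 256 | local texture |
| PHOG, 12 unsigned orientation bins × pyramid levels 0–2 (1+4+16 cells), magnitude-weighted | 252 | shape/edges |

Total 572. Only the total is externally fixed; the 64 + 256 + 252 split and
the LBP/PHOG hyperparameters are this package's convention and are recorded
in every serialized model's metadata. A gradient-free PHOG input returns
the uniform vector $1/252$ so the descriptor is defined on degenerate
patches.

The grader is a fixed 572–300–150–5 MLP: ReLU hidden layers, softmax
output, trained by mini-batch SGD with momentum (defaults: learning rate
0.01, momentum 0.9, 200 epochs, batch 32 — configurable; these
hyperparameters are package choices). Features are standardized per
dimension with training statistics stored in the model. Training is a pure
function of (data, config, seed); He-normal initialization and batch
shuffling are both seeded. Grades render as Roman numerals I–V in reports.

## The phantom generator

Real, annotated lumbar MRI at study scale is not redistributable, so the
package ships a procedural phantom generator whose geometry is simple
enough to carry *exact* ground truth:

* **Sagittal** (512×512 default, 0.2646 mm/px): bright rounded-rectangle
  vertebral bodies along a lordotic arc (default 15° of subtended
  curvature), elliptical discs between them. Grade $g$ maps to mean disc
  intensity $230 - 35(g-1)$, nucleus/annulus contrast $1-(g-1)/4$ and
  height factor 0.6 at grade 5 — a separable encoding of the Pfirrmann
  criteria (signal loss, lost nucleus/annulus distinction, collapse).
  Herniated discs carry a posterior half-elliptical protrusion beyond the
  disc margin, sized to stay inside the 44-px diagnosis strip.
* **Axial**: vertebral body, disc, canal, four facet blobs, the six marker
  points, and — when a target (size, zone) is requested — a half-elliptical
  herniation blob attached to the posterior disc margin. The apex is placed
  by inverting the grid transform, with a ≥ 2 px margin from every region
  boundary, and the planted label is verified against `classifyMsu()`
  before the phantom is returned, so closed-loop label recovery is exact by
  construction.
* Noise is additive Gaussian (default σ = 8 on the 8-bit scale) with
  clipping to [0, 255]; identical configuration + seed reproduce every
  output byte.

**What phantoms do and do not show.** Passing the closed-loop suites
demonstrates that the geometry, the constraint logic, the descriptor
plumbing and the optimization are implemented correctly and that the
pipeline is self-consistent at realistic pixel scales. It does **not**
demonstrate clinical performance: phantom classes are separable by
construction (held-out accuracies near 1 are expected and observed),
whereas real discs exhibit overlapping appearance, partial voluming,
coil-shading and anatomy the generator does not model. Clinical-scale
accuracy claims require real annotated data and learned detectors plugged
into the same interfaces.

## Problem sizes and numerical choices

The validation experiments use sizes chosen to exercise each property
thoroughly at desk scale: 200 phantoms for the repair closed loop
(one interior outlier of 12 mm each, scored at the 4-mm threshold), 1000
axial phantoms at 256 px (geometry scales with image size) for the MSU
oracle-equivalence sweep, 100 discs per grade for Pfirrmann training
(stratified 80/20 split), and about 200 ROIs per class for diagnosis.
Permutation nulls rerun the same training with shuffled labels and are
expected at chance (0.2 / 0.5). Undefined metric denominators raise typed
errors rather than returning 0, because silent zeros corrupt averages.
All boundary conventions (strict λ bounds, inclusive 180° angle, MSU
tie-breaks) are stated at their definitions above.

## Other design decisions

* Coordinates everywhere are 0-based pixels, x = column, y = row
  (y increases caudally on sagittal slices, dorsally on axial ones);
  physical units enter only through `pixelSpacingMm`.
* Images are read from 8/16-bit grayscale PNG; pixel spacing comes from the
  annotation/configuration (default 0.2646 mm).
* The advice engine treats MSU sizes 2 and 3 identically (both "surgical
  consideration"), reads "grade > 3" as IV–V for the fusion flag, and lets
  size dominate zone (size 1 is conservative whatever the zone). Every
  advice lists the rule ids that fired and reports carry a fixed advisory
  disclaimer.
* The per-slice diagnosis is exposed as-is; fusing the three mid-sagittal
  slices of a study into one per-disc decision is left to the caller, as is
  the choice of axial slice per disc.

## A worked example

```{r example, eval = FALSE}
ph <- generateSagittal(phantomConfig(seed = 7),
                       discSpecs(c(1, 2, 3, 4, 5),
                                 herniated = c(FALSE, FALSE, TRUE, FALSE, FALSE)))
det <- detectVertebrae(phantomImage(ph))
rep <- repairChain(det$chain)
ctr <- chainPoints(rep$chain)

roi <- cropDiscRoi(phantomImage(ph), ctr[3, ], ctr[4, ], levelIndex = 3)
fit <- diagnosisClosedLoop(nPerClass = 50, seed = 1)   # reference model
classifyHerniation(roi, fit$model)

ax <- generateAxial(phantomConfig(), list(size = 2, zone = "B"))
classifyMsu(phantomMarkers(ax), phantomMaskTruth(ax))[c("size", "zone")]

advise(discAssessment(3, TRUE, msuSize = 2, msuZone = "B", pfirrmann = 4))
```
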