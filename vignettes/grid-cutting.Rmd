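---
title: "Grid-cutting: automated soft-tissue removal from 3D dental scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-cutting: automated soft-tissue removal from 3D dental scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridcut)
```

## The problem

Intraoral 3D photo scanners record the dentition as a triangle mesh in
millimetre coordinates, and they record everything else the light reaches:
gingiva, vestibular mucosa, parts of the cheek and lips, and the retromolar
area. For automated comparison of dentitions — the use case this package
targets is forensic identification, where an *ante mortem* scan from a dental
record is matched against a *post mortem* scan — that soft tissue is noise.
Its shape varies between scans of the same mouth far more than the teeth do,
so it must be removed or at least limited before shape comparison.

Boundary-tracing segmentation methods and supervised deep-learning tooth
segmenters exist, but they degrade on dentitions with missing teeth and on
scans taken directly in the mouth rather than from plaster models — exactly
the conditions a forensic workflow must tolerate. Grid-cutting takes the
opposite stance: it does not try to find the tooth/gingiva boundary at all.
It is a purely height-based, per-vertex filter whose goal is to *limit* soft
tissue while guaranteeing, as far as possible, that no tooth surface is lost.

## The method

The pipeline has four stages, driven by three user parameters: the grid size
$G$ (mm), the inclusion criterion $I$ (mm) and the ratio of inclusion
$R \in (0, 1]$.

**1. Orientation and occlusal-plane approximation.** The user declares the
jaw side. Mandibular scans are taken as occlusal-side-up; maxillary scans are
rotated 180° about the x-axis through the mesh centroid, so both jaws are
processed identically. (A rigid rotation, not a z-mirror: mirroring would
swap the patient's left and right anatomy. The paperless choice between the
x- and y-axis is immaterial to the algorithm; x is used and recorded in the
run report.) A least-squares plane $z = ax + by + c$ is fitted to all
vertices — ordinary least squares with $z$ as the response, since the whole
method reasons in $z$ after orientation. Vertices strictly below this fitting
plane are set aside; over the survivors' xy-bounding box, two section planes
at thirds of the x-extent and one at half the y-extent define six sections.
Each non-empty section contributes the vertex farthest above the fitting
plane; of these section representatives, the four with the largest $z$ are
fitted (same least-squares routine) to give the **approximated occlusal
plane** with upward unit normal $N_o$. Fewer than four populated sections is
an error naming the empty ones. Ties — equal distance within a section, equal
$z$ among representatives — go to the lowest vertex index, so the procedure
is order-stable and fully deterministic.

**2. Grid splitting.** An xy-grid of $G \times G$ mm squares is anchored at
the bounding-box minimum. Intervals are half-open with the last column/row
closed, so every vertex belongs to exactly one square; a vertex exactly on an
interior grid line belongs to the higher-indexed square. The scan's total
z-range is computed once here, before any removal.

**3. Square analysis.** Each square is analysed independently. Its
**evaluation point** $E_p$ is the member vertex with the highest $z$. If the
perpendicular distance from $E_p$ down to the occlusal plane exceeds
$R \cdot z\mathrm{-range}$ (strict comparison), the square's highest point is
far below the dentition — it holds no teeth — and all its vertices are
excluded. Otherwise an inclusion threshold is placed $I$ mm from $E_p$ along
$N_o$, on the side away from the plane (i.e. at $E_p - I \cdot N_o$), and
every member vertex whose $z$-value is at least the threshold's $z$-value is
kept. The displacement direction deserves a note: with $N_o$ normalised to
point upward and $E_p$ the square's *highest* vertex, a threshold above
$E_p$ would keep nothing, while the method's stated intent is to keep the
surface *near the occlusal plane*; the threshold therefore lies $I$ mm below
$E_p$. The keep rule is non-strict, so $E_p$ itself always survives, even at
$I = 0$.

**4. Collection.** Vertices kept by no square are deleted; any face touching
a deleted vertex is dropped (dropping only fully-dead faces would leave
dangling indices); the remainder is reindexed and returned — in the oriented
processing frame, so maxillae stay flipped and downstream scan-to-scan
comparison is uniform. The command-line interface can restore the original
pose with `--restore-frame`.

Monotonicity falls out of the construction: the occlusal plane and the
exclusion verdicts do not depend on $I$, so growing $I$ only grows every
square's kept set; growing $R$ only turns excluded squares into cropped ones.
Both nestings are asserted in the test suite.

## Parameters

| parameter | unit | default | effect |
|---|---|---|---|
| $G$ | mm | 1 | square edge length; granularity of the crop |
| $I$ | mm | 7 | depth of kept surface below each square's highest point |
| $R$ | — | 0.33 | fraction of the total z-range beyond which a square is discarded |

The defaults are the method's standard settings; `crop_params()` and the CLI
use them bit-exactly. For difficult arches (low-lying third molars) the
coarser setting $G = 5$, $I = 5$, $R = 0.4$ keeps more: a larger square has a
taller evaluation point that pulls low neighbours back inside the ratio
check, and the larger $R$ tolerates squares that sit further below the plane.
`scripts/acceptance.R` demonstrates exactly this rescue on the synthetic
ectopic-molar arch.

## The synthetic arch generator

No clinical scans ship with the package, so every claim is exercised on
`make_arch()` fixtures: a band surface swept along a parabolic arch
centreline (defaults: 50 mm wide, 45 mm deep, 10 mm band), with a flat ridge
crest and a gingival skirt falling `gingiva_drop` (default 6 mm) towards the
band edges, and a truncated Gaussian crown bump (sd 1.8 mm, cut at 3 sd,
height 8 mm) at each present tooth position. The band continues 8 mm beyond
the last tooth position at both ends, providing the retromolar surface on
which two optional pathologies live: an **ectopic, partly erupted third
molar** (a crown bump of height `eruption_fraction` × 8 mm placed 4 mm
distally) and a **retromolar flap** (a broad soft-tissue mound, sd 3 mm, of
chosen height placed 6 mm distally). Seeded uniform jitter of ±0.05 mm
emulates scanner noise; generation is byte-deterministic given the seed and
leaves the caller's random stream untouched.

Vertices in the upper half of a crown bump (contribution ≥ half that crown's
height) are labelled `tooth`; everything else is `soft`. The crown-only label
is deliberately conservative: the method's success criterion is tooth
preservation, not gingival-margin accuracy, and a label reaching into the
gingival margin would penalise legitimate near-margin cropping. These
dimensions were chosen once, as plausible adult-arch values, and the defaults
are the conditions under which all tooth-preservation results are reported.

What the generator does *not* emulate: real crown morphology (cusps,
fissures), scan holes and boundary noise, malocclusion beyond a lateral tilt
of the ectopic molar, and soft tissue that overhangs teeth. Passing tests
therefore show that the implementation realises the method faithfully under
realistic height relationships — not that any particular clinical success
rate transfers.

With the defaults the geometry gives the method honest margins rather than
guaranteed success: the lowest tooth-labelled surface sits ≈ 4 mm above the
gingival base and ≈ 4.1 mm below the occlusal plane, while the exclusion
radius is $R \cdot z\mathrm{-range} \approx 4.6$ mm — about half a millimetre
of slack, comparable to the method's real sensitivity to low-lying teeth. An
ectopic molar erupted to 30% sits ≈ 5.5–6.8 mm below the plane and is
correctly (from the method's blind perspective: incorrectly) discarded.

## Numerical choices and degenerate inputs

* Plane fits use QR on the normal-equations design matrix; a rank-deficient
  xy-configuration (collinear points) is a hard error.
* Comparisons follow the stated strictness everywhere: below-plane removal
  in stage 1 is strict (on-plane vertices survive), the $R$-exclusion is
  strict, the keep rule is non-strict.
* The distance used in the $R$-check is the perpendicular point-plane
  distance (the quantity is a distance to a plane); for the near-horizontal
  occlusal planes the method produces, it differs from the vertical distance
  by under $10^{-3}$ relatively. If $E_p$ lies on or above the plane the
  distance is ≤ 0 and the square always passes.
* STL files are welded at 10⁻⁶ mm — scanner exports repeat corner
  coordinates bit-identically, and a larger tolerance could fuse fine
  occlusal detail. Facet normals in the file are ignored. Zero-area
  triangles are kept; only faces that collapse to a repeated index under
  welding are dropped (counted in an attribute). ASCII output is written at
  17 significant digits so write→read is exact in doubles; binary STL is
  float32 by definition of the format.
* An all-excluded scan returns an empty mesh with a warning flag, not an
  error; an STL written from a crop omits vertices that lost all their faces
  (the format stores facets only).
* Nothing in the pipeline is randomised; no seed is consumed by
  `grid_cut()`.

## Problem sizes in the shipped tests

The test suite generates everything at run time: 20 random triangle-soup
meshes of 300–2000 vertices plus five synthetic arches are compared
vertex-for-vertex against an independently coded brute-force
reimplementation of the whole pipeline; 20 seeded arches (11–14 teeth, 0–3
missing) check tooth preservation at the defaults; the monotonicity ladders
run at $I \in \{0, 2, 5, 7, 10\}$ and $R \in \{0.1, 0.33, 0.4, 1.0\}$.
Default arches mesh at 0.8 mm resolution (≈ 2200 vertices); several unit
tests use 1.1–1.2 mm. These sizes keep the whole suite under a minute on one
CPU while leaving every geometric regime (empty squares, excluded squares,
partial squares) populated.

## Limitations

Inherited from the method by design: teeth are not traced, so gingiva
adjacent to crowns is retained; a third molar erupted far below the occlusal
plane is indistinguishable from soft tissue and will be cropped (the
parameter retry helps moderately erupted cases only); a tall retromolar flap
can enter the section representatives and tilt the approximated occlusal
plane. Both failure modes are reproduced, on purpose, in
`test-acceptance.R` and `scripts/acceptance.R`. Specific to this
implementation: no mesh repair or hole filling, no PLY/OBJ input, no
automatic jaw detection, and the synthetic fixtures are height-realistic
rather than anatomically realistic.
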