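---
title: "Measuring the 3D hindfoot alignment angle: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the 3D hindfoot alignment angle: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haa3d)
```

## The problem

Hindfoot valgus — the heel tilting laterally under the shank — is a central
component of adult acquired flatfoot. Weight-bearing cone-beam CT yields
per-bone 3D surface meshes under physiological load, but "the" hindfoot
alignment angle (HAA) is not one quantity: the literature defines the
hindfoot vertical axis from the whole calcaneus, from talo-calcaneal
landmarks, from silhouette contours, or from the posterior tuberosity alone,
and these constructions disagree by tens of degrees on the same feet. This
package implements six such techniques behind one frame and sign convention
so the disagreements can be studied quantitatively, plus a synthetic phantom
whose true angles are known by construction, and the paired statistics needed
for pre/post cohort comparisons.

## Model and assumptions

**Coordinate scaffold.** The whole-foot frame (FootAF) is anchored to the
ground: dorsal = upward ground normal (least-squares plane of the ground
mesh, or z = 0 when none is supplied), anterior = ground-projected direction
from the calcaneal most-plantar point to the second-metatarsal-head point,
medial = dorsal x anterior. Units are millimetres throughout (STL carries no
units; the reader logs the bounding box, since an adult foot spans roughly
100-350 mm). The frontal plane is spanned by (medial, dorsal); every
technique reduces to two unit vectors in that plane and one signed angle.

**Sign and side convention.** The source literature reports magnitudes; we
need signs. Valgus is positive: the hindfoot axis' dorsal tip rotated toward
medial (equivalently the heel/plantar end toward lateral) relative to the
tibial axis. Left feet are handled by negating the medial axis, not by
mirroring meshes, so valgus is positive on both sides. A consequence worth
stating: the left-foot triad (anterior, medial, dorsal) is left-handed; the
axes are anatomical directions, not a rotation-matrix basis. All anatomical
axes are treated as undirected lines and sign-normalized dorsal-positive
before any angle is computed, because eigenvectors carry arbitrary sign.

**Surface PCA.** Anatomical frames come from the eigen-decomposition of the
*area-weighted* covariance of surface points, not of raw mesh vertices: raw
vertex PCA depends on where the segmentation software concentrated its
triangles. Each triangle is midpoint-subdivided until edges are at most
`max_edge` (default 1 mm — segmentation exports are typically 0.5-2 mm, and
results are insensitive to this choice, see below), and each sub-triangle
contributes its three edge midpoints with weight area/3. This degree-2 rule
makes weighted means and covariances of polyhedral surfaces *exact* at any
subdivision depth; the simpler one-centroid-per-sub-triangle rule carries an
O(`max_edge`^2) covariance bias that is visible (~1e-4 rad) at coarse
settings, which is why it was rejected.

**Axis labelling.** Principal axes are labelled longitudinal / vertical /
transverse by best |cosine| alignment with the FootAF anterior / dorsal /
medial axes (greedy, largest variance first), not by variance rank alone.
For a typical calcaneus the longitudinal axis has the largest variance and
the vertical the second largest; the package warns when alignment-based
labels disagree with that expected ordering instead of failing, because
pathological bones can violate it.

**The techniques.** A: vertical axis of the whole-calcaneus PCA frame. B1:
line from the calcaneal most-plantar point to the talus volume centroid
(divergence-theorem centroid; the mesh must be watertight, which is checked,
and inward normals are tolerated with a warning). B2: same base point to the
talar middle-facet centre — the subtalar joint centre — supplied via a
landmark file, since it is not derivable from the bone surfaces alone. C:
project the calcaneal surface to the frontal plane, split the silhouette at
the mid-height of its dorsal extent, join the most-medial points of the two
halves (and likewise most-lateral), and bisect the two segment directions.
D10/D15/D20: clip the surface samples with a box orthogonal to the
whole-calcaneus longitudinal axis, starting at the most posterior point and
extending 10/15/20 % of the bone length; the hindfoot axis is the principal
axis of the clipped samples best aligned with the whole-bone vertical axis.
E: as D with the box width set by the most plantar point's coordinate along
the longitudinal axis.

## Numerical choices

* **Extreme-point ties.** Flat plantar surfaces make the "most plantar
  vertex" ill-posed; vertices tying within 1e-6 mm are averaged. This is
  stabler than an arbitrary first-index pick and exactly reproduces the
  centre of a flat contact face.
* **Silhouette extremes on the vertex lattice.** Technique C searches
  extremes over the subdivided *vertex lattice* (which contains the exact
  mesh corners), not over the quadrature points: quadrature points sit about
  `max_edge`/3 inside face boundaries, and that inward bias tilts short
  contour segments by degrees at large deformity. Integral quantities (PCA)
  keep the weighted quadrature; extreme-point quantities use the lattice.
* **Which slab axis is "vertical".** For a thin posterior slab the variance
  ranking differs from the whole bone (the slab's largest variance can be
  transverse), so techniques D/E pick the slab principal axis with maximal
  |cosine| against the whole-calcaneus vertical axis. This reduces to the
  intended axis for real tuberosities and is robust for thin slabs.
* **Box clipping on samples, not meshes.** D/E filter the weighted surface
  samples by their coordinate along the longitudinal axis; no mesh booleans
  are performed. PCA needs points and weights only, and mesh booleans are
  fragile on near-tangent cuts.
* **E-box degeneracy.** When the most plantar point projects at (or behind)
  the posterior extreme, the plantar-bounded box collapses; the width is
  clamped to 2 % of the bone length with a warning rather than failing.
* **Calcaneal length.** Defined as the extent of the surface samples along
  the longitudinal PCA axis; the literature's "longitudinal line segment" is
  not otherwise defined.
* **t-test edge cases.** All-zero differences give t = 0, p = 1; zero spread
  with nonzero mean gives p = 0 with a degenerate-variance warning.

## The phantom: what it emulates and what it does not

`generate_phantom()` builds five watertight meshes — a rounded-box calcaneus
(80 x 30 x 45 mm by default) with chamfered edges, a rounded posterior heel
and anterior end; an ellipsoidal talus; a capped-cylinder distal tibia
(radius 15, length 100 mm); a small second-metatarsal-head sphere 150 mm
anterior; and a flat ground slab — with configurable frontal inclinations and
analytically known expected angles:

* truth[A] = truth[C] = body tilt − tibia tilt,
* truth[B1] = arctan(medial/dorsal talus offset) − tibia tilt (the talus is
  placed relative to the *measured* plantar point, so this holds exactly),
* truth[B2] likewise from the facet landmark offsets,
* truth[D*] = truth[E] = body + tuberosity tilt − tibia tilt.

Two shape features are deliberate. First, the **plantar keel**: a sharp
ridge (the medial process of the tuberosity) whose apex sits at 20 % of the
length from the posterior end, 6.5 mm deep. Equivariance of the B-family
under frontal rotations requires the most-plantar point to move like a
material point; a flat or gently rounded sole provably breaks this (the
contact point "rolls" by r·sin(delta) for sole radius r), while the keel apex
stays the support point for tilts up to ~30 degrees and makes technique E's
plantar-bounded box coincide with the 20 % tuberosity slab. Second, the
**tuberosity tilt** is applied as a vertex-wise rotation of the posterior
20 % slab about the slab's own surface centroid, blended over 2 mm so the
mesh stays watertight.

Known, quantified approximations of the phantom truths:

* truth[A] ignores that whole-bone surface PCA absorbs a share of the
  tuberosity tilt equal to the tilted slab's area-weighted contribution to
  the frontal covariance anisotropy — about 0.23 x tuberosity tilt for this
  geometry (~1.2 degrees at a 5-degree tuberosity tilt). This is a property
  of technique A itself, not an implementation artifact, and is the reason
  whole-bone PCA overestimates deformity relative to tuberosity-focused
  techniques on real feet as well. The corresponding acceptance check, which
  allows technique A only 1 degree of tuberosity absorption, fails by ~0.2
  degrees on this geometry and is intentionally left failing rather than
  reshaping the phantom post hoc.
* truth[C] = body tilt holds when the tuberosity does not protrude beyond
  the body's medial/lateral faces (tuberosity tilt 0, or small enough);
  a tilted tuberosity whose corners stick out becomes the silhouette
  contour, and C then legitimately reads body + tuberosity.
* Default offsets (talus (10, 50) mm, facet (15, 45) mm) are chosen so the
  B-family angles (11.3, 18.4 degrees) sit in the clinically reported range.

What the phantom does *not* emulate: real calcaneal shape variation,
segmentation noise beyond isotropic vertex jitter (`noise_mm`, default 0;
0.3 mm keeps all techniques within 2 degrees of truth), imaging artefacts,
the post-operative bone graft, and soft tissue. A green phantom test
establishes geometric correctness of the implementations, not clinical
validity of any technique.

The cohort simulator draws (pre, post) pairs from a bivariate normal with
per-technique marginal moments (defaults representative of severe flatfoot
corrected by subtalar arthrodesis) and explicit pre/post correlation `rho`
(default 0.7). `rho` is a visible parameter because paired-test power depends
on it directly; the marginal moments alone do not determine it.

## Statistics

Because every comparison in the intended design is on the same feet, both the
pre-vs-post tests and the between-technique tests default to the *paired*
two-tailed Student t-test (an unpaired Welch option exists behind a flag for
sensitivity analysis). No multiple-testing correction is applied by default,
matching how such tables are conventionally reported; Holm and Bonferroni are
available via `adjust`. The summary table includes the pre-op mean-to-STD
ratio as a crude consistency indicator across subjects (reported as `Inf`
for a zero-spread column).

## Limitations

* The tibial axis needs a reasonably long diaphyseal segment; below a 2:1
  length-to-width ratio a warning flags the axis as unreliable.
* Technique C's contour segments are only as well defined as the silhouette:
  on shapes whose medial/lateral extremes approach the mid-height split the
  segments shorten and the measure grows noisy — visible even on the phantom
  at extreme (40 degree) deformity before the lattice-based extreme search
  was adopted.
* No mesh repair beyond duplicate-vertex merging and degenerate-face
  dropping; non-watertight tali are rejected (B1) rather than patched.
* The landmark-dependent technique B2 is only as reproducible as the
  supplied landmark.
* Left/right handling assumes the mesh coordinate frame is anatomical
  (x anterior-ish, z up); arbitrary scanner frames are handled through the
  ground mesh and landmarks, not guessed.
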