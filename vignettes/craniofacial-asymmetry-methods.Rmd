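---
title: "Methods: landmark anthropometry and symmetric-template asymmetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark anthropometry and symmetric-template asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniosym)
```

## The measurement model

The package analyses triangulated head-surface scans of children with
class I, II or III dental occlusion. Each subject contributes a mesh (mm
units) and 37 manually digitised soft-tissue landmarks from a closed
vocabulary (15 midline points such as nasion N, subnasale Sn, pogonion Pg,
gnathion Gn; 11 bilateral pairs such as gonion Go-r/Go-l and otobasion
inferius OBi-r/OBi-l). Two analyses are built on these inputs.

**Linear/angular anthropometry.** Fourteen parameters summarise the
vertical, anteroposterior and angular configuration of the face: five
vertical distances (N-Gn, N-Sn, Sn-Sto, Sto-Gn, N-Sto), two perpendicular
offsets to profile lines (Sn to the N-Pg line; Pg to the N-B line), the
mandibular body length Go-Gn, and six angles (nasolabial ∠Cm-Sn-Ls,
labiomental ∠Li-B-Pg, lower lip to submental plane ∠B-Pg : Cer-Gn, gonial
∠OBi-Go-Gn, facial convexity ∠N-Sn-Pg, full soft-tissue convexity
∠N-PRn-Pg). All distances are Euclidean; angles come from the clamped
normalised dot product and live in (0, 180]. Two conventions needed fixing
where the published descriptions are magnitude-only:

* the two line offsets are computed **signed**, positive anterior (along
  canonical +z), so a retrusive subnasale or chin remains representable;
  cohort tables use the signed values directly (published group means are
  positive throughout, so signs only matter in the tails);
* the gonial angle and Go-Gn exist per side; we compute each side with its
  ipsilateral OBi/Go and report the left/right mean alongside the per-side
  values. The columella symbol Cm is identified with the columella
  landmark C.
* whether the subnasale offset uses the infinite N-Pg line or the segment
  is unstated in the source material for such analyses; we use the
  infinite line, the standard in profile analysis.

## The canonical head frame

All asymmetry quantities presuppose a midsagittal plane and an origin.
Neither is observable directly, so the package estimates a canonical frame
from the landmarks:

* **plane normal**: leading eigenvector of the scatter of the 11 unit
  right-minus-left bilateral difference vectors — a closed-form,
  rotation-equivariant estimator that degrades gracefully when individual
  pairs are noisy;
* **plane anchor**: the centroid of the 11 pair midpoints and the 15
  midline landmarks;
* **axes**: +x along the normal toward the anatomical left; +z the
  in-plane component of PRn − Op (anterior); +y completes the right-handed
  triad. The sign conventions y(V) > y(Gn) and z(PRn) > z(Op) are
  asserted. Anchoring z on PRn-Op (rather than deriving y from V-Gn) keeps
  the vertical axis independent of chin position, which varies with
  occlusion class;
* **origin**: the OBi-r/OBi-l midpoint projected onto the fitted plane —
  near the cranial centre and insensitive to facial deformation, which
  matters because the asymmetry statistic measures distances *from the
  origin*.

Distances and angles are rigid-motion invariant, so the frame affects only
the signed offsets and the asymmetry origin; `applyFrame()` is an exact
isometry and invertible to 1e-9 mm.

## Symmetric template, TPS, closest point

Asymmetry is scored against a perfectly mirror-symmetric reference. The
template is an analytic head surrogate: a superellipsoid cranium (exponent
2.5; width 160.98 mm, height and depth from the canonical mean
configuration) blended with Gaussian radial protrusions through the
pronasale and gnathion. The mesh is built as a half lat-long grid plus an
*exact* x-negated mirror copy, so the mirror pairing m(i) satisfies
position(m(i)) = x-negated position(i) bit-for-bit and midline vertices
have x = 0 exactly. Default resolution is 40 azimuthal × 32 vertical bands
(1242 vertices); the mesh is watertight by construction. Anchors map every
anatomical label (and 40 constructed cranial-layer labels, 4 evenly spaced
scalp rings × 10 azimuths between the OBs level and the vertex) to
template vertices, mirror-consistently.

Per subject the template is (1) anisotropically sized — width from the
Go-r/Go-l span, height from V-Gn, depth from PRn-Op; (2) warped by a 3D
thin-plate spline fitted to the 77 paired landmarks; (3) matched to the
subject by closest-point projection.

**TPS details.** Kernel U(r) = r (the 3D biharmonic spline); bordered
linear system with exact interpolation at λ = 0 and a configurable ridge
λ ≥ 0. Duplicate or coplanar control sets are rejected with the offending
controls named. Note that U(r) = r is conditionally *negative* definite on
the zero-sum weight subspace, so the bending energy is −WᵀKW (clamped at
zero); it vanishes exactly on affine control relations, and large λ
shrinks the fit to the least-squares affine map rather than tracing a
monotone energy path.

**Closest point.** For every template vertex the globally nearest point on
the subject's triangulated surface (point-to-triangle projection via
Voronoi-region classification). The search is pruned with the bound
d(q, centroid) − R(triangle) ≤ current best, seeded by the nearest-vertex
distance; the bound cannot discard the minimiser, so the result is
identical to an exhaustive scan (this is asserted against a brute-force
scan in the tests). One pass is the default, matching the published
two-step procedure; an opt-in iteration count re-matches after moving the
template onto its matched points.

## Asymmetry scoring

For each mirror pair (i, m(i)) with the left member (template x > 0) as
representative, the asymmetry is |‖p_i − o‖ − ‖p_m(i) − o‖| where p are
the matched subject surface points and o the canonical origin; midline
vertices are excluded. A point-to-point alternative (|p_L − mirror(p_R)|)
is available behind a flag for sensitivity analysis. The facial region is
the set of vertices at least as close to the pronasale as to the gnathion
(boundary included in the face; the boundary is the perpendicular bisector
plane of PRn-Gn). AF and AH are the arithmetic means over facial and all
pairs. Head metrics: H = y(V) − y(Gn) from landmarks; L, W the mesh z/x
extents; V by signed-tetrahedron summation. Published head-volume tables
print values near 3 500 with a mm³ label, which is physically a litre-scale
quantity for a child's head; the package reports cm³ and documents the
unit discrepancy rather than propagating it. Heat maps write the pair
value to both pair members (0 on the midline) with an 8-bit colour ramp on
a fixed 0–5 mm scale so group maps are comparable across subjects; four
orthographic views (facial frontal, craniofacial frontal, left/right
lateral) can be rendered to PNG.

Where published per-class figures disagree between the running text and
the summary table (e.g. head height 226.85 vs 228.6; skull asymmetry 2.49
vs 2.32), the table values are used for calibration throughout; the
discrepancy is inherited from the source and left unresolved.

## The synthetic cohort generator

No scans are distributed with the study this design follows, so the
generator is a first-class module: it must produce cohorts whose measured
statistics match the published calibration tables, and single subjects
whose measured parameters equal the drawn targets *exactly* (the
round-trip contract, asserted at 1e-6 for every class × sex cell).

**Parameter draws.** Each of the 14 parameters has a configured normal
(mean, SD) per class × sex (defaults = the published group tables), drawn
truncated at ±4 SD; angles are additionally confined to (5°, 179.5°), the
representable range of a vertex angle. Two structural facts force mild
departures from fully independent draws:

* The published means are nearly additive along the vertical chain
  (N-Sn + Sn-Sto ≈ N-Sto + 0.23 mm; N-Sto + Sto-Gn ≈ N-Gn + 3.4 mm).
  Independent draws therefore violate the triangle inequality — a
  geometric impossibility for any landmark configuration — roughly half
  the time. The chain is instead drawn coherently: N-Sn, Sn-Sto and Sto-Gn
  are independent; N-Sto and N-Gn are derived through positive
  Gamma-distributed slack variables whose means are set so **every
  configured mean is reproduced exactly**. The realised SDs of the two
  derived parameters are then √(σ²_b + σ²_d + σ²_s) rather than the
  printed values (a few tenths of a millimetre of shrinkage) — the price
  of metric consistency.
* In the distribution tails, a facial convexity near 180° is incompatible
  with a normal-sized subnasale offset (the offset is bounded by
  b·sin ∠N-Sn-Pg). Infeasible combinations redraw **only the implicated
  component** (the offset, not the angle), keeping the angle marginals
  unbiased; the conditional truncation leaves a small (≲ 1 SEM) downward
  bias on the subnasale offset in the class III cells where the collision
  is common.

**Constructive placement.** Midline chain first (Gn at the origin, N at a
fixed 8° anterior tilt, Sto and Sn by two-circle intersection), then the
profile points: Pg from the convexity angle and offset (ray rotation + a
quadratic in the ray parameter, branch chosen by offset sign and proximity
to Gn), PRn on the inscribed-angle arc of the N-Pg chord at the preferred
nasal height, B from the submental-plane angle and the pogonion offset
(1-D root solve), Li/C/Ls by angle construction. Bilateral landmarks are
placed as exact mirror pairs; Go and OBi realise the drawn mandibular
length and gonial angle per side. The cervical point sits 40 mm inferior
and 10 mm posterior to Gn — with this placement both signs of the pogonion
offset are constructible at the published submental-plane angles.

**Meshes and asymmetry injection.** The subject mesh is the template
TPS-warped to the subject's 37 landmarks plus 40 layer targets on a
cranial ellipsoid of the drawn head dimensions (centred on the canonical
vertical axis so layer rays always intersect). Configured AF/AH are
*regional means of the pipeline-measured origin-distance asymmetry* — the
same definition the published values have, being pipeline outputs. The
injection pushes the left surface along its outward normal by g/cos φ (φ
the normal-vs-radial obliquity): a naive radial vertex offset of δ would
be read back as only δ·cos²φ by closest-point matching. The gain field g
is tapered to zero over 60 mm at the midline seam and blended over 80 mm
across the face/skull boundary (hard steps are under-read at facet
scale), and normalised per region so the expected regional mean equals the
configured level; offsets are capped at 25 mm against self-intersection.
Residual faceting under-read is about 5 % at the default template
resolution and shrinks as resolution grows. Landmarks stay exactly
symmetric: carrying them with the injected surface would tilt the fitted
midsagittal plane toward the asymmetry and cancel the signal — the same
reason the measurement uses a symmetric template in the first place.

**What the generator does not emulate.** Real scan noise and holes,
landmark digitisation bias (rater noise is available separately and is
isotropic Gaussian), correlations between parameters beyond the metric
constraints above (a correlation hook exists but is off by default),
asymmetric landmark positions, hair/ear artefacts, and any longitudinal
structure. Passing tests therefore demonstrate the correctness of the
geometry and statistics machinery under the calibrated population model,
not robustness to scanner artefacts.

**Rater emulation.** `simulateRaters()` perturbs every landmark with
isotropic Gaussian noise and re-measures. The reliability emulation
follows the published design — 31 subjects from *each* occlusal class, two
raters — with rater error at 25 % of the realised between-subject SD per
parameter (the only reading under which "25 % of the between-subject SD"
is well defined per parameter); with true ICC ≈ 1/(1 + 0.0625) ≈ 0.94 and
n = 93, the per-parameter ICC(2,1) estimates fall inside the published
0.75–0.97 band with high probability. With only 31 subjects the
estimator's upper tail crosses 0.97 too often for a 14-parameter joint
band, which is why the pooled design matters.

## Statistics layer

Pooled-variance Student t is the default two-sample test (Welch by flag);
both reproduce the published class-I upper-lip sex contrast within table
rounding (0.007 pooled, 0.008 Welch from the printed summary statistics).
One-way fixed-effects ANOVA over the three classes (F = t² for two groups,
asserted); no multiple-testing correction, matching the source analysis;
significance flagged at p ≤ 0.05. ICC form is ICC(2,1) — two-way random
effects, absolute agreement, single measurement — with ICC(3,1) by flag;
both come from the explicit mean-squares decomposition and are tested
against an independently fitted two-way ANOVA. Group tables report
means/SDs to 2 decimals with Total rows computed from raw per-subject
values, never from rounded subgroup summaries.

## Numerical choices and problem sizes

* Template 40 × 32 at ~1242 vertices: one subject's full analysis
  (frame, layers, scaling, TPS, closest point, scoring) runs in well under
  a second; the faceting error this induces in asymmetry recovery is ~5 %.
  The radial-offset recovery property is checked on a sphere centred at
  the origin, the geometry in which a radial offset is exactly what
  closest-point matching should read back and faceting is the sole error
  source; on a head-shaped surface a radial *vertex* offset is
  intrinsically attenuated by cos²φ, which no resolution cures.
* Monte-Carlo sizes: 2 000 null replicates for the ANOVA type-I check,
  100 seeds for the reliability band, 1 000 draws for the
  law-of-large-numbers check on the generator, 12 class-I mesh subjects
  in the acceptance run's asymmetry stage.
* Tolerances: exact-arithmetic identities (mirror symmetry, null
  asymmetry, brute-force equality) are asserted at 0 or 1e-9; TPS
  interpolation at 1e-9; generator round-trip at 1e-6; file round-trips at
  1e-6; stochastic recoveries at 10 %.
* Ties and degenerate inputs: closest-point ties resolve to the
  lowest-index face (identical under pruning and brute force); zero
  variance in both t-test groups with equal means returns p = 1;
  constant ratings make the ICC undefined (error); watertightness is a
  precondition for volume and checked by edge counting.

## Known limitations

The template is an analytic surrogate, not a statistical atlas; its
face/skull pair fractions (not the published ones, which are unknown)
enter the AH decomposition used at injection time. Head L/W metrics are
mesh extents and track the drawn dimensions only to a few percent in mesh
mode. Enclosed volume is not calibrated to the published table (whose
units are ambiguous). The generator's parameter correlations are limited
to the metric constraints; real faces correlate more broadly. ICC
emulation operates at parameter level for the reliability band; the
landmark-level path propagates noise nonlinearly and its per-parameter
ICCs are not individually calibrated.
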