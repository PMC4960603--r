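---
title: "Reconstructing pseudo whole-mount sections from tissue quadrants: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing pseudo whole-mount sections from tissue quadrants: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Large histological specimens — prostate cross-sections are the motivating
case — are often too big for a standard slide, so each axial section is cut
into four quadrants that are mounted and digitized separately.  Annotating
disease or registering pathology to in-vivo imaging then requires a
*pseudo whole-mount histological section* (PWMHS): a digital reassembly of
the four fragments into one cross-section.  Reassembly is hard because the
fragments violate every assumption of photo stitching and puzzle solving:
they do not overlap (they were cut from one object), they are incomplete
(tissue is destroyed along the cuts and during processing), and their
boundaries do not interlock (processing warps them independently).

`quadstitch` reconstructs a PWMHS by estimating one rigid-body transform
(x-translation, y-translation, rotation) per quadrant, three quadrants
moving relative to a fixed fourth — a nine-dimensional search.

## The cost function

Stitching minimizes a two-component cost over the transform set
$\mathbf{T}$:

$$C(\mathbf{T}) = w_1 D_{tot} + w_2 M_{tot}, \qquad w_2 = 1 - w_1 .$$

Both components are evaluated on the four adjacent quadrant pairs
(ul, ur), (ur, lr), (lr, ll), (ll, ul) and averaged.

**Tissue dissimilarity $D$.**  Each quadrant carries two detected *cut
edges* (the boundaries that face a neighbour).  For a pair of facing
edges, corresponding edge pixels are found in the common frame; for each
correspondence, square patches of side $p$ centred on the two pixels are
reduced to $b$-bin intensity histograms over tissue pixels only,
normalized to discrete probability densities, and compared with the L1
norm.  The maximum possible dissimilarity is $\phi = 2$ for two
normalized histograms and $\phi = 1$ when patches collapse to single
pixels at the coarsest resolution (the patch has constant physical size,
so its pixel footprint shrinks with downsampling).  Non-corresponding
edge pixels — $m$ of them, against $n$ correspondences — contribute
$\phi$ each:

$$D_{pair} = \frac{\sum_{k=1}^{n} \lVert V^1(k) - V^2(k)\rVert_1 + m\,\phi}{n + m}.$$

**Boundary misalignment $M$.**  Each edge's robust best-fit line has an
inner endpoint $C_{in}$ (toward the section center) and an outer endpoint
$C_{out}$ (toward the outer boundary).  For facing edges,

$$M_{pair} = w_3 \lVert C^1_{in} - C^2_{in}\rVert + w_4 \lVert C^1_{out} - C^2_{out}\rVert, \qquad w_4 = 1 - w_3,$$

in base-resolution pixels at every pyramid level, so the weights transfer
across levels.

### Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `w1` | dissimilarity weight ($w_2 = 1 - w_1$) | 0.989 | empirically optimal operating point |
| `w3` | inner-endpoint weight ($w_4 = 1 - w_3$) | 0.4 | binds to the *inner* pair by the conventional (inner, outer) ordering; the alternative binding is one config call away |
| `patch_px` | patch side, base px | 81 | constant physical size across the pyramid |
| `bins` | histogram bins | 16 | coarse enough that histograms are not sparse |
| `tau_px` | correspondence cutoff, current-level px | patch radius | pairs farther apart than this are non-corresponding |
| `preprocess.target_max_dim` | working resolution | 1024 px | inputs already at or below it are untouched |
| `ga.population` / `ga.stall` | GA population / stall window | 20 / 25 | see below |
| `pyramid.factors` | hierarchy | 8, 4, 2, 1 | see below |

## The pipeline

1. **Standardize** — downsample so the larger dimension equals the working
   resolution, apply user flips (fragments are sometimes scanned mirror
   side up), convert to grayscale, rescale intensities to $[0,1]$.
2. **Segment** — Otsu's threshold on inverted intensity (tissue is darker
   than the near-white background), morphological closing (5-px disc),
   hole filling, largest connected component.  The recipe is exposed in
   the configuration.
3. **Edge geometry** — minimum-area bounding box by rotating calipers on
   the convex hull; the box corner pointing away from the section center
   is *external* (by anatomic label) and defines no edge; contour points
   nearest the other three corners delimit two boundary arcs that face
   the section interior.  Arcs are resampled at 1-px arc length and
   cropped to a corridor around the cut (8 px about the Theil–Sen line,
   then 3 px about a robust local-regression follow of the cut's
   waviness), so both sides of one physical cut end at consistent
   positions.  Theil–Sen lines (median of all pairwise slopes; vertical
   edges fit with axes swapped; >500-pixel edges subsampled on a
   deterministic stride) give each edge its endpoints.
4. **Initialize** — at low resolution (default 4x downsampling), rotate each quadrant so its
   horizontal-facing edge is level ($-\arctan$ of the fitted slope about
   the tissue centroid), translate so the facing best-fit lines coincide, and
   push quadrants apart until pairwise mask overlap is at most 1% of the
   smaller quadrant.  The result is re-expressed relative to the fixed
   ul quadrant.
5. **Optimize** — an elitist genetic algorithm (population 20; stop after
   25 consecutive generations without a relative improvement above
   `1e-4`) refines the nine-vector within a coarse-to-fine hierarchy:
   the coarsest level searches translation bounds of ±25% of the coarse
   image size and ±20°, each finer level re-centers a ±(2 × previous
   factor) px / ±3° window on the upscaled previous solution.

## Correspondence: the detailed rule

The correspondence definition is the one place where reasonable readings
diverge, so the implemented rule is spelled out.  Edge pixels of both
facing edges are mapped into the common frame.  A pixel *corresponds* to
the facing edge iff the foot of its perpendicular projection onto that
edge's polyline is interior — a projection falling beyond a terminal
endpoint by more than half a pixel of chain order is an *overhang* and
has no correspondent — and the foot distance is at most `tau`.  Partners
(the chain pixel nearest the foot) are claimed injectively, with a
±2-pixel fallback when the nearest partner is taken, so the matching
cannot collapse many-to-one; every unmatched pixel of either edge counts
toward $m$.  A plain discrete mutual-nearest-neighbour rule was tried
first and rejected: between two 1-px chains it sheds 10–30% of true
pairs to tie collisions, and that noise in $m$ (each worth $\phi = 2$)
dominates the histogram signal.  An optional displacement-direction
filter (`normal_cone_deg`) can additionally require matches to cross the
cut; it is disabled by default because at lossless cuts the direction of
1–3-px displacements is contour jitter, not geometry.

Patches whose window holds no tissue are counted in $m$ (maximally
dissimilar); an adjacency with no items at all scores $\phi$.

## Optimizer details

Within the specified population size and stall rule, the operator suite
is chosen for a cost surface that is cheap to evaluate, non-smooth at the
pixel scale, and has coherent soft directions:

* tournament selection (k = 3) and uniform blend crossover;
* multi-scale Gaussian mutation — per-gene σ drawn log-uniformly between
  0.3% and 30% of the bound half-width — so basin hops and sub-pixel
  polish coexist in one population;
* half the initial population scattered around the seed solution
  (σ = 5% of half-width), the rest uniform in the box, plus two random
  immigrants per generation;
* a coordinated move applied to a quarter of offspring: a small random
  global rigid motion of the three moving quadrants about the section
  center.  The softest directions of the cost are coherent (sliding a
  hemisphere along a cut, twisting the configuration), and escaping a
  coherently displaced local minimum requires all three poses to change
  together — single-gene mutations cannot do it.

Elitism makes the per-level best-cost trace non-increasing; with a fixed
seed the whole run, including the serialized transform JSON, is
bit-reproducible.

All edge geometry (chains, endpoints) is detected once at base
resolution and shared by every pyramid level; only patch appearance
follows the level.  Re-detecting geometry per level was tried first and
rejected: corner and endpoint bias of 1–2 coarse pixels (8–16 base px at
factor 8) corrupted exactly the coarse solution that seeds the finer
search windows.

## Evaluation measures

Against a reference reconstruction the package reports, in μm and as a
percentage of the average of the reference's width and height:

* **ASF** — ten anchors on the stitch edges of the reference (inner
  endpoint, midpoint, outer endpoint per edge, coincident central
  endpoints merged, outermost points preferred when truncating); each
  anchor is carried into both adjacent quadrants' local frames through
  the reference transforms and re-mapped through the test transforms;
  the error is the mean distance between the two re-mapped copies.
* **MSF** — the same mean-distance formula over supplied fiducial rows
  (`ref_x, ref_y, test_x, test_y`): one row per landmark, its position
  per the reference and per the test reconstruction.  The synthetic
  generator provides ≥9 landmark pairs per cut for this purpose.
* **Hausdorff** — convex hulls of both tissue masks, resampled at 1-px
  arc length, aligned by centroid translation, a 0.5°-step rotation grid
  over 360° (the grid runs on chains subsampled to ~400 points; the
  refinement — golden-section on the angle, coordinate descent on the
  translation, 0.1-px convergence — uses the full chains), then the
  symmetric chain Hausdorff distance.  If alignment ever ends worse than
  the centroid-only pose, the centroid pose is kept, so aligned never
  exceeds unaligned.

## The synthetic phantom

Real quadrant scans cannot ship with the package, so a generator builds
pseudo-sections with known ground truth.  A phantom is a dark tissue
ellipse on a near-white background carrying: bright elliptical blobs
(gland lumina, radii 2–11 px), concentric elliptical intensity bands
around the section center (wavelengths 20–45 px, the analogue of
prostate zonal anatomy), a very-long-wavelength intensity drift, and
i.i.d. Gaussian texture noise (σ = 0.05).  Two wavy cuts through the
tissue centroid quarter it; a kerf-wide band is destroyed along each
cut; each quadrant is cropped, independently perturbed by a random rigid
transform (the recorded inverse is ground truth), and optionally
mirrored or bitten.  Landmark pairs straddling each cut (≥9 per cut)
support MSF-style scoring.  Difficulty presets: `easy` (kerf 0, ±5 px,
±3°), `medium` (kerf 5 px, ±10 px, ±8°), `hard` (kerf 12 px plus bites,
±20 px, ±15°).

The banding deserves a note, because it is what makes the phantom a fair
test of *this* cost function.  Patches facing each other across a cut
are disjoint half-windows offset by roughly a patch radius; isotropic
mid-scale texture therefore decorrelates them and leaves the histogram
term with no signal along the cut (this was measured: with isotropic
texture the mean matched-pair L1 is flat in tangential lag).  Texture
that is informative for tangential alignment must vary *along* the cuts
while staying constant *across* them — and since both cuts run radially
from the section center, concentric bands do exactly that, as zonal
anatomy does in real prostate sections.  What the phantom deliberately
does not emulate: staining variation, nonlinear warping, scaling between
quadrants, out-of-plane sectioning differences.  Passing recovery tests
on phantoms therefore demonstrates the geometry and optimization
machinery, not robustness to every real-data artifact.

## Problem sizes used by the test suite

The suite exercises the full pipeline at a working resolution of 512 px
(phantom canvas 512 × 448, ~80 μm/px, so a section spans ≈ 40 mm as in
adult prostate): pose recovery on ten `easy` fixtures (seeds 0–9;
success means every moving quadrant within 3 px / 2° of ground truth and
ASF-style error ≤ 3%, required for at least 8 of 10), a cost-basin check
(ground truth beats ≥95 of 100 random ±15 px / ±10° perturbations on a
lossless fixture), byte-identical reruns under a fixed seed, and the
degradation ordering easy ≤ medium ≤ hard of the median recovered ASF
error over five seeds per preset.  These sizes keep a full run in the
tens of minutes on one core while leaving the conclusions unchanged at
larger n.

## Numerical choices and degenerate inputs

* Coordinates are 1-based `(x, y)` with pixel centers at integers and y
  increasing downward; rotation is about the quadrant's tissue centroid,
  which nearly decouples the translation and rotation parameters.
* Intensities interpolate bilinearly, masks by nearest neighbour;
  pyramid images reduce by exact block averaging, masks by block
  majority.
* Composite overlap resolves by fixed draw order ul, ur, ll, lr.
* Theil–Sen on a perfectly vertical point set automatically refits with
  axes swapped; an all-identical point set is an error.
* Segmentation of a constant image, an empty foreground, masks with
  fewer than 3 foreground pixels, and contours shorter than 10 px raise
  informative errors rather than propagating garbage.
* An all-unmatched adjacency scores exactly $\phi$; GA bounds must be
  finite and non-inverted; a non-finite cost aborts with the offending
  solution printed.

## Known limitations

* Rigid transforms only — no per-quadrant scaling or nonlinear warp, so
  differential tissue deformation shows up as residual error.
* Re-segmenting rendered fixtures (Otsu + closing) rounds the cut
  corners and can degrade pose recovery relative to the generator's
  exact masks; with real scans the same mechanism makes results
  sensitive to the segmentation recipe near the cuts.
* Tangential localization inside a long straight cut rests on the
  appearance term; tissue with no intensity structure along a cut leaves
  that direction determined only by the edge endpoints.
* The MSF table semantics here score per-landmark displacement between
  the two reconstructions; an expert marking coincident pairs on a
  reference workstation is emulated, not reproduced.
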