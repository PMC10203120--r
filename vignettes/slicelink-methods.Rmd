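---
title: "SliceLink: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SliceLink: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SliceLink)
```

# The problem

High-resolution 3D stacks from serial-section electron microscopy (and
increasingly from optical microscopy) are typically processed in two
stages: a semantic stage that classifies each pixel as cell or non-cell
(usually a 2D network applied slice by slice), and an instance stage
that separates the touching cells and gives each one an ID that is
consistent across slices. The instance stage is where mistakes
concentrate: boundaries are locally missing, the axial (z) resolution is
several-fold coarser than the in-plane resolution, and slices can be
mutually displaced. No automatic method survives these conditions
untouched, so a practical tool must combine a strong automatic pass with
cheap, reversible manual corrections.

SliceLink implements that combination headlessly: an automatic
slice-wise watershed + cross-slice linking pass, and a full proofreading
toolkit over two complementary stores. Everything is scriptable; a GUI
could wrap the same operations but none is included.

# Automatic pass

## Per-slice instance segmentation

`segmentSlice()` converts one binary prediction slice into instances:

1. Euclidean distance transform of the foreground.
2. Gaussian blur of the distance map (`gaussianSigma`, default 2 px).
3. h-maxima transform of the blurred map (`hMaxima`, default 2, in
   distance units): regional maxima shallower than `h` relative to
   their surroundings are suppressed, so a convex cell contributes one
   seed even when its distance map is noisy.
4. Marker-controlled watershed on the negated blurred map, restricted
   to the foreground.

Design choices worth knowing:

* The blurred map feeds **both** seed detection and the watershed
  elevation, so the two stages cannot disagree about plateau shapes.
* A foreground component with no h-maximum (a flat line, a few pixels)
  still receives exactly one seed at its distance-map argmax, first
  pixel in reading order on ties. Every foreground pixel is therefore
  labelled: the output partitions the prediction exactly.
* Seeds — and hence output labels — are numbered by the reading-order
  (row-major) position of each seed plateau's first pixel, and the
  flood queue breaks elevation ties first-come-first-served. Identical
  inputs give bit-identical outputs on any platform.
* In-plane connectivity defaults to 4 so that the one-pixel boundaries
  a proofreader draws during division reliably separate regions.
* `gaussianSigma` and `hMaxima` are the two knobs that matter. The
  defaults suit convex-ish cells roughly 10–50 px across: sigma much
  larger than 2 starts rounding away thin necks; `h` much smaller than
  the typical cell "height" in the distance map re-admits spurious
  seeds and over-segments.

When a region-of-interest mask is supplied, `applyMask()` computes each
cell's in-ROI proportion and deletes cells whose proportion is
*strictly below* the threshold (default 0.8); a cell exactly at the
threshold is kept. The rule is idempotent.

## Cross-slice linking

From the second slice on, `linkSlice()` transfers identity from the
resolved previous slice using the overlap coefficient

$$\mathrm{overlap}(X, Y) = \frac{|X \cap Y|}{\min(|X|, |Y|)}$$

between a previous-slice cell $Y$ and a current-slice region $X$.
Normalising by the smaller area makes the coefficient 1 for nested
regions, so a cell tapering towards its tip still links. Pairs whose
coefficient *strictly exceeds* the threshold (default 0.5; a tie at the
threshold does not link) become edges of a bipartite graph, and
connected components of that graph define identity:

* every current region in a component adopts the smallest previous ID
  in the component;
* several previous IDs joined through a shared current region are
  merged — and the merge is applied backwards through all earlier
  slices, which is also what makes one manual merge on slice $i$
  propagate automatically to slice $i+1$ and beyond;
* regions with no edge get fresh IDs in ascending label order.

The maximal-matching alternative (each current region links only to its
best partner) was considered and rejected: component union gives one
semantics for both linking and merge propagation, and is what makes
corrections pay forward. It is deliberate that no image registration is
attempted — slice displacement surfaces as linking mistakes that the
correction tools (not the linker) resolve.

## The 3D watershed baseline

`watershed3D()` is the same pipeline run volumetrically (3D distance
transform, blur, h-maxima, 6-connected flood), the classic
distance-transform-watershed post-processing that other tools apply to
cell/non-cell predictions. It is included as the comparison baseline.
On anisotropic stacks its weakness is structural: a cell's 3D distance
ceiling is set by its short z extent (a handful of voxels), so genuine
seeds fall below `h` or merge through dropout gaps, while the slice-wise
pipeline sees the full lateral radius of every section. The baseline
deliberately treats voxels as isotropic, as the classic implementation
does; `spacing` can override this.

# The two stores

## Slice-wise store (`LinkedStack`)

Each slice holds an immutable base label image (the raw watershed
output) plus a label list: groups of base labels, each carrying one
final cell ID, and a set of deleted IDs. Merging, deleting and linking
edit only the label list — an edit costs a few list entries rather than
a dense relabel, and autosaving a slice costs one grid plus the lists.
`resolveSlice()` materialises final IDs on demand, and
`renderWindow()` resolves only ±`displayWindow` slices (default 100)
around the working slice, the economy that keeps display latency flat
in thousand-slice stacks.

Undo history holds up to 10 steps by default (configurable); deltas are
symmetric before/after snapshots of the affected slices' label lists
(they share the base grids by reference, so they stay small). Division
is the one operation that must rewrite a base grid; it is restricted to
the current working slice in this store — earlier slices are corrected
in the volumetric store, which exists for exactly that purpose.
Division keeps the user's erased pixels as background (the drawn
boundary stays visible), and the largest piece keeps the original ID so
downstream references stay stable; ties go to the piece first in
reading order. `divideRelink()` then lets each piece adopt the
qualifying previous-slice ID of maximal coefficient, with the rule that
one previous ID can capture only its best piece — otherwise the relink
would undo the division.

`saveProject()`/`resumeProject()` serialise the store to a single
versioned archive (base grids + label lists + ID counter). Undo/redo
history is intentionally not persisted; a resumed session starts clean.
`runSeg2DLink()` autosaves after every slice, so an interrupted run
resumes at the first unsegmented slice and provably produces the same
volume as an uninterrupted one.

## Volumetric store (`LabelVolume`)

For whole-volume inspection the slice-wise indirection is the wrong
trade, so Module-2-style proofreading runs on a dense 3D grid plus two
caches: per-cell tight bounding boxes and voxel counts, built in one
pass by `buildVolume()`. Localization (`locateCell()`, which reports
the floor of the bbox z midpoint as the central slice) and every
correction then search only inside the relevant boxes, so cost follows
cell size, not image size. All corrections keep the caches coherent
incrementally; the test suite checks them against a from-scratch
rebuild after random operation sequences.

Undo here stores sub-region voxel diffs (indices, old values, new
values — always inside the union of the affected cells' boxes) plus the
small stats tables; the default depth is 5 because volumetric diffs are
heavier than label-list snapshots. Additional operations:
`divide3D()` (3D connected components, 26-connectivity by default so
anisotropic sampling does not split cells spuriously; largest component
keeps the ID), `insertCell()` (paint a missed cell onto background
only), `sortByVolume()` (largest cell becomes ID 1, ties by ascending
old ID) and `removeSmall()` (strictly-below threshold).

# I/O conventions

Arrays are `(y, x, z)`, 0 is background, indices are 1-based inside R;
exported slice filenames are 0-based and zero-padded
(`seg_00000.tif`). Directories of per-slice TIFFs are read in natural
(numeric-aware) filename order, so `s2.tif` precedes `s10.tif`;
multi-page TIFFs and RDS-serialised arrays are also accepted. 16-bit
samples are written until an ID exceeds 65535, then 32-bit float
samples scaled by $2^{32}-1$ (exact for IDs up to about $2^{23}$).
Round trips are bit-exact and tested.

# The phantom generator

`generatePhantom()` produces the synthetic study conditions with known
ground truth. Cells are grown from dart-thrown nuclei: a voxel belongs
to the nearest nucleus in the anisotropy-scaled metric (default z step
= 5 × the xy pixel, the regime of serial-section EM), restricted to
that nucleus's radius, which yields touching, convex, hole-free cells.
Predictions are then degraded exactly the way real inputs are: 1-px
in-plane inter-cell boundaries are erased from the foreground,
re-flipped to foreground with probability `boundaryDropout`
(missing-boundary failure), and each slice can be rigidly shifted by up
to `displacement` pixels (misalignment failure). The shift is applied
to predictions and ground truth jointly, because in a real stack the
annotation is displaced along with the image; scoring therefore
measures segmentation quality, not registration.

Two generator constraints are deliberate and worth stating plainly.
First, nuclei may be close in xy only if they are far apart along
scaled z, and vice versa; second, each cell's polar cap (the last z
step at each end) is trimmed. Together these keep distinct cells from
meeting across a single z step — a boundary parallel to the cutting
plane, which a per-slice binary prediction cannot represent at all. No
overlap-based linker (nor any method consuming only these predictions)
could separate such cells; on real data that failure mode exists and is
exactly what `divide3D()` is for. The clean-phantom conditions are thus
the conditions under which the automatic pass can be *exact*, which is
what the acceptance checks assert; they do not claim exactness on real
EM data, where boundary evidence is weaker and the expected workflow is
automatic pass + proofreading.

`scoreSegmentation()` reports detection-style error fractions over
ground-truth cells: a GT cell is undersegmented when its best-matching
segmented cell also best-matches another GT cell (or when nothing
overlaps it), and oversegmented when more than one segmented cell
claims at least `minFraction` (default 0.1) of its voxels. The scores
are invariant to relabelling. These definitions are one reasonable
operationalisation of "cells with mistakes"; absolute percentages
depend on them and on the phantom, so only directions and exact-zero
claims are asserted anywhere.

# Problem sizes and determinism

The shipped checks use a 64×256×256 phantom with 50 cells of radius
30–45 px for the clean-pipeline claim, five 32×128×128 phantoms with 14
cells and 30 % boundary dropout for the baseline comparison, and
hundreds of small random stacks/volumes for the data-structure
invariants — sizes chosen so a laptop CPU runs the whole suite in well
under a minute while every mechanism (appearing/disappearing cells,
dropout bridges, anisotropic z extents) is still exercised. All
randomness is seeded; phantoms restore the caller's RNG state, and the
segmentation path contains no randomness at all, so end-to-end runs are
bit-reproducible.

# Known limitations

* The volumetric store holds the dense grid in memory; stacks beyond
  memory would need tiled processing, which is out of scope.
* Linking consumes binary predictions only; probabilistic predictions
  or registration-aware linking are out of scope.
* The phantom generator emulates geometry and the targeted failure
  modes, not microscope contrast; it is not a physically realistic EM
  simulator, and conclusions from phantoms transfer to real data only
  in direction, not in absolute error rates.
* 32-bit TIFF export is exact for IDs up to ~8.3 million; beyond that
  use the RDS route.
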