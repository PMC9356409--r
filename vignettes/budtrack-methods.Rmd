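---
title: "Tracking, pedigree and quantification methods in budtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking, pedigree and quantification methods in budtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(budtrack)
```

budtrack operates on *label movies*: stacks of 2D integer masks in which
each segmented cell carries one label per frame, with 0 reserved for
background. This vignette explains the models and procedures behind each
operation, the parameters that matter, the numerical choices made where
the design was open, and what the synthetic test bed does and does not
demonstrate about real data.

## Frame-to-frame tracking

Budding yeast in a microfluidic device barely moves between frames, but
it grows, and buds appear abruptly. The tracker therefore uses an
*asymmetric* overlap score, intersection-over-area: current object
`y_i` against previous object `x_j` is scored by their overlap divided
by the area of `x_j` alone. A cell that merely grew keeps a score near
1; a fresh bud overlaps nothing substantial and scores near 0. The
assignment rule is:

1. every current object whose best score over all previous objects is
   **strictly below** `new_object_threshold` (default 0.4; a score of
   exactly 0.4 is kept) is declared new;
2. each remaining object is assigned to its best-overlap predecessor,
   *unless* that predecessor overlaps a different current object
   strictly better — in that case the loser is **not** retried against
   its second choice but joins the new-object pool. This single-pass
   reading avoids chains in which one deferred object displaces another;
3. new objects receive labels one above the maximum ever used in the
   movie, so identities are never recycled and pedigree links made at
   any frame stay valid.

Ties are broken deterministically (lower previous label among equal
candidates; lower current label among equal competitors). Note that a
sub-threshold object can never block an assignment: its score against
the contested predecessor is below 0.4 while the assignee's is at least
0.4, so the blocking clause only ever involves surviving objects.

Tracking changes label values only — the foreground pixel set of every
frame is untouched.

## Separation of merged objects

Segmentation models often fuse a mother with its small bud into one
object. The separation routine assumes such an object shows a waist: two
concave corners facing each other where the two cell outlines meet.

1. The outer boundary of the object (largest 8-connected component;
   holes ignored) is traced as an ordered polygon.
2. The polygon is simplified with Ramer–Douglas–Peucker. Simplification
   suppresses raster irregularities that would otherwise create spurious
   concavities.
3. Convexity defects of the simplified polygon are computed against its
   convex hull: per hull edge, the deepest interior vertex, kept if its
   depth is at least `min_depth` (default 1 px — below one pixel a
   "defect" is raster noise).
4. **Iff exactly two defects remain**, the object is cut by the straight
   chord through the two defect points: each pixel goes to the side of
   the chord it lies on, pixels exactly on the chord to the larger side,
   and the larger fragment keeps the original label. Any other defect
   count returns a no-split signal and leaves the frame unchanged — a
   convex object has nothing to cut, and a three-lobed object is
   ambiguous.

The one genuinely open numerical choice is the simplification
tolerance. A single fixed tolerance cannot serve all geometries: at 10%
of the contour length the waist of a wide-overlap pair is itself
smoothed away (its depth, 2–4 px, is far below the tolerance), while
very fine tolerances keep noise concavities that inflate the defect
count. budtrack therefore ladders the tolerance: it starts at
`epsilon_fraction` × contour length (default 0.10) and halves it until
some level shows exactly two defects, giving up below 1/64 of the
starting fraction. The defect *positions* are then refined to the
deepest raw-contour points within the hull gaps found at that level,
because the simplified polygon locates the waist only to within a few
pixels and the cut is sensitive to that offset when the bud is small.

## Mother–bud pairing

When new objects appear at frame *n*, each is a candidate bud and every
cell annotated G1 at that frame is a candidate mother (a budded cell
cannot take a second bud). The cost of pairing new cell `a_i` with G1
cell `b_j` is the single-linkage distance — the minimum Euclidean
distance between their contour pixels — and the assignment minimizing
total cost is the solution of the linear sum assignment problem
(solved by `clue::solve_LSAP`; the test suite checks it against
exhaustive enumeration, so it can never do worse than brute force). A
bud emerges attached to its mother, so the true pair's cost is
essentially zero; failures arise when a bud emerges equally close to an
unrelated G1 cell.

Pairing uses the emergence frame only — no look-ahead — matching how an
analyst annotates frame by frame. With more new cells than G1 cells,
only as many pairs as there are G1 cells are formed (the lowest-cost
subset) and an `insufficient_G1` warning is raised; the unpaired
newcomers are recorded as cells of unknown history.

## The annotation table and its state machine

Cell-cycle state is one row per (frame, cell): stage (`G1` or
`S/G2/M`), generation number (completed divisions; a bud carries 0
until its first division, then 1), relative ID (the paired cell, −1 if
none), relationship (`mother`/`bud`), emergence and division frames
(−1 = unknown), and three flags (history known, excluded, dead; the
latter two are analyst marks stored as optional trailing CSV columns).
A validator enforces the structural invariants — unique keys, enum
values, the one-bud rule (an S/G2/M mother has exactly one reciprocated
bud row per frame), bud generation 0, lifetime continuity — and returns
violations as data rather than raising, so tables can be inspected and
repaired.

Corrections propagate so that one click's worth of information never
has to be applied frame by frame:

* `annotate_division(frame, cell)` ends the pair's S/G2/M stretch from
  that frame on: the mother returns to G1 with generation +1 and the
  division frame recorded; the bud becomes a G1 mother of generation 1,
  keeping its relative ID as the pedigree link. Propagation stops where
  the stretch ends.
* `undo_division` reverts the G1 stretch the division created — forward
  until each cell re-enters S/G2/M (a later re-budding stops the
  reversion for that cell), backward to the division frame — restoring
  each field from the last pre-division frame, which makes it the exact
  inverse of `annotate_division`. A division at frame 0 has no
  pre-division state and is reported as not undoable.
* `correct_mother(bud, new_mother)` first checks eligibility (the new
  mother must be G1 at the pairing frame and have no other reciprocated
  bud anywhere in the bud's lifetime), then rewrites the whole lifetime:
  the wrong mother returns to its pre-assignment state, the new mother
  is linked reciprocally.

Headless propagation runs to the end of the table; the interactive
notion of a "last visited frame" has no meaning here. A bud whose label
vanishes from the movie while still a bud (washed out of the trap
before division) is closed with `is_history_known = FALSE` at its last
frame, its mother reverts to G1 with the link cleared, and a
`washed_away_bud` warning is emitted.

Cells present at frame 0 start as G1 mothers with unknown history,
generation 2 and emergence −1: their past is unobserved, and the
convention marks them distinctly from first-generation daughters
(generation numbers of unknown-history cells are comparable only within
a cell's own trajectory).

## Volume and fluorescence

Volume is estimated from the 2D mask assuming rotational symmetry about
the major axis: the pixel-center coordinates are rotated so the
second-moment major axis is vertical, binned into 1-px-high slices, and
each slice contributes `π (w/2)²` where `w` is its pixel count. Rotating
coordinates rather than resampling the image conserves the pixel count
exactly and removes interpolation artifacts; using the slice pixel count
as its width is robust to small boundary concavities. With an isotropic
pixel size in µm, `volume_fl = volume_vox × pixel_size_um³`. On smooth
shapes of radius ≥ 10 px the estimate is within ~2% of the sphere /
cylinder closed forms, scales as k³ under mask scaling within 5%, and is
rotation-invariant within 3%; single-pixel and 1-px-wide masks reduce to
stacks of width-1 disks.

Fluorescence background is the per-frame median intensity over all
pixels outside every mask — the median is insensitive to the bright
cells' tails — and: corrected mean = in-mask mean − background median;
amount = corrected mean × area (exactly invariant under adding any
constant to the whole image); concentration = amount / volume, emitted
both per voxel volume and per fL (they differ by the constant
`pixel_size_um³`). Reported quantiles of the raw in-mask signal are
0.05/0.25/0.5/0.75/0.95. A frame with no background pixels is an error
asking for an explicit background region. Mother+bud combination sums
amounts (and volumes) over reciprocated pairs per frame and passes G1
frames through, so whole-cell traces are continuous across bud
emergence; traces are aligned at the first frame the (first) bud exists,
and cells that never bud are excluded with a log entry.

## Tracking benchmarks

Predicted and ground-truth movies are compared frame by frame: objects
match one-to-one when their IoU exceeds 0.5 (above 0.5 the match is
provably unique, so no assignment search is needed). Unmatched truth is
a false negative, unmatched prediction a false positive. An identity
switch is counted when a truth trajectory's matched predicted identity
differs from its previous one — but each (trajectory, new identity)
transition only the first time, so a permanent swap costs one switch
regardless of duration; the frames spent matched to a non-original
identity are reported separately as the switch duration. Then
`MOTA = 1 − (ΣFN + ΣFP + ΣIDSW) / ΣGT`. Link precision/recall/F treat
every pair of consecutive frames of one identity as a link: with `G`
truth links, `R` predicted links and `c` truth links whose endpoints
match the same predicted identity in both frames, precision = c/R and
recall = c/G; 0/0 ratios are reported as 0.

## The synthetic colony generator

The generator emulates exactly the geometry the algorithms consume:
ellipse-shaped cells (aspect 1.02–1.25, fixed random orientation) that
grow exponentially (default 3% area per frame), bud, and divide, on a
background-0 integer canvas, with the complete pedigree recorded in a
ground-truth annotation table. Defaults sketch a yeast cycle imaged
every few minutes: 4 frames of G1, 8 frames budded, buds emerging at
15% of the mother's area and growing at twice the base rate, founder
radius 8 px, centroid jitter 0.3 px. Two mechanisms keep the geometry
trackable, both with biological analogues:

* *Size control at Start*: a cell buds only once its area reaches
  `mother_min_area_frac` (default 0.8) of the founder area, and
  under-sized daughters grow at the doubled rate until then. Without
  this, second-generation mothers bud while tiny and their few-pixel
  buds cannot be followed by overlap — as in real data, where
  sub-resolution objects are untrackable.
* *Outward budding with damped collisions*: buds point away from the
  colony centroid (with ±0.7 rad jitter), and collision resolution
  (iterative pairwise repulsion, 50 iterations, displacement per frame
  capped at half a cell radius) spreads residual contact over several
  frames instead of teleporting cells.

Identical seeds give bit-identical datasets; the RNG state of the
caller is saved and restored. Overcrowding (a cell pushed off the
canvas or fully occluded) raises an error suggesting a larger frame.

`perturb_dataset` injects controlled errors while keeping the truth:
dropped object-frames (exact false negatives), small background blobs
(exact false positives), permanent relabelings of single trajectories
from a random mid-life frame (exactly one first-time identity switch
each — note a pairwise label *swap* would touch two trajectories and
count twice), and mother–bud merges that are exact unions of the two
truth masks (inputs for the splitter). The injected sets are disjoint,
so the benchmark module must return the injected counts exactly.

What passing on this test bed does **not** show: robustness to
segmentation noise (masks here are clean ellipses), to large cell
displacement (flow, stage drift), to texture-dependent intensity
(fluorescence fixtures are plateaus plus constant background), or to
3D effects — real performance depends on upstream segmentation quality
in ways the generator deliberately does not model.

## Problem sizes and defaults used in the shipped checks

The test suite and `scripts/acceptance.R` use colonies of 1–3 founders
over 10–30 frames on 96–160 px canvases (≈ 200–260 object-frames), 100
random merged geometries for the splitter, 200–500 random assignment
problems up to 6×6 against exhaustive enumeration, and 1000 random
state-machine operations — sizes at which every oracle is exact and the
whole suite runs in well under a minute on one core.

## Known limitations

* Labels above 65535 cannot be written to the 16-bit TIFF output (an
  error says so); floating-point TIFFs are rejected as label input.
* The splitter cuts along a straight chord; a strongly curved
  mother–bud interface is approximated, and objects whose waist is
  shallower than 1 px of hull depth are declared unsplittable.
* Pairing considers the emergence frame only; evidence from later
  frames (bud growth direction) is not used.
* `annotate_movie` treats every newly appearing object as a candidate
  bud; debris entering the field is paired if a G1 cell is nearby, and
  must be fixed with `correct_mother` or exclusion flags.
* Generation numbers of unknown-history cells start at the frame-0
  convention (2) and are not comparable across such cells.
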