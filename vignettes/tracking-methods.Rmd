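---
title: "Cell tracking by coupled minimum-cost flow: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell tracking by coupled minimum-cost flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mcftrack)
```

`mcftrack` links instance-segmentation masks of migrating cells over
time and repairs false-negative, over-segmentation and
under-segmentation errors along the way. This vignette explains the
models the package implements, the tunable parameters and their
defaults, the numerical choices made where the method leaves room, and
what the bundled synthetic data can and cannot show.

## Assumptions

Two assumptions underpin everything:

* **Small motion.** Cell displacement between consecutive frames is
  small relative to the image, so a local region of interest around an
  object contains its plausible continuations.
* **Mostly correct segmentation.** The majority of masks segment single
  cells correctly; errors are the exception to be repaired, not the
  rule. A mask is therefore treated as a *segmented object* — it may be
  a cell, part of a cell, or several cells.

## Stage 1: candidate discovery

Each object gets an axis-aligned ROI of per-axis size `roi_scale` (2 by
default) times the mean bounding-box extent over all objects of the
sequence. When raw images are available, the ROI is moved along the
translation estimated by phase correlation of equally sized crops
around the propagated position, chained frame by frame up to `delta_t`
frames ahead; without raw images the displacement is zero. Objects
whose bounding box intersects the propagated ROI become matching
candidates. Bounding-box intersection (instead of mask-level overlap)
is deliberately conservative: a superset of candidates costs solver
time, a missed candidate is unrecoverable.

Phase correlation details: crops are mean-subtracted and tapered with a
Hann window before the cross-power spectrum is formed; on small, noisy
crops the raw pure-phase normalisation occasionally produces a spurious
global peak, and a single bad displacement estimate can push the ROI
off the true continuation. The shift is the integer argmax of the
inverse transform (no sub-pixel refinement; candidate discovery only
needs ROI-level accuracy), with a zero-vector fallback for degenerate
(constant) crops. The crop extent is the ROI size — the smallest window
that still contains the content whose motion matters.

## Stage 2: the coupled minimum-cost flow model

A typed directed graph per time window:

* object nodes `o(i,t)` — one per segmented object;
* skip nodes `x(i,t+1) … x(i,t+Δt−1)` — a track may bridge up to
  `delta_t` frames of missing masks;
* split nodes `s(i,t+1)` after every object/skip node — one object at
  `t` explained by two or more masks at `t+1` (mitosis *or*
  over-segmentation);
* merge nodes `m(i,t)` in front of every object node — two or more
  objects at `t` explained by one mask at `t+1` (under-segmentation);
* appear node `a(t)` and delete node `d(t)` per frame, plus a global
  source and sink.

Unit flow is forced through every object node; appear nodes receive a
fixed inflow equal to the next frame's object count, with a free drain
to the delete node, so any object *may* appear. Ordering inequalities
on merge and split nodes quantise their throughput to zero or at least
two units. Daughter pairs of a split node are coupled: one binary
variable stands for both daughter edges, at most one pair per mother
may be active (a mother produces at most two daughters), and an active
pair excludes over-segmentation flow at the same node. Pairs are ranked
by the mitosis cost and capped at `n_max_pairs = 10` per object.

Costs are purely positional. With displaced position
`p̂ = p + d` (cumulative phase-correlation shift):

* movement: `‖p̂(i,t+1) − p(j,t+1)‖`;
* skip steps: the displacement magnitude, unless the propagated
  centroid falls inside any bounding box at the target frame — then a
  missing mask is implausible and the edge costs `θ`;
* mitosis pair `(j,l)`: `c1 + c2` where `c1` is the distance of the
  mother centroid to the daughters' midpoint and `c2` the asymmetry of
  the two mother–daughter distances, admissible only when the daughters
  lie within 1.5 mother bbox diagonals of each other (`c3` gate); the
  mother's position is deliberately *not* displacement-corrected, since
  phase correlation is unreliable exactly when one crop shows one cell
  and the other two. The pair cost enters the objective once per
  realized division, which keeps one division cheaper than the
  move-plus-appear or over-segmentation explanations of the same
  picture.
* over-segmentation (`s → o`): minimal distance from the mother's
  propagated interior mask points to the daughter centroid, gated by
  the propagated bounding box;
* under-segmentation (`o/x → m`): minimal distance from the merged
  object's interior mask points to the propagated centroid of the
  contributing object, gated by the merged object's bounding box;
* appearance / disappearance: distance of the centroid to the nearest
  image border, capped at `α` (the largest default ROI edge).

Interior mask points are the pixels whose Euclidean distance-transform
depth reaches at least half the mask's maximum, subsampled by uniform
stride to at most 50 points — stable representatives of the mask's
core with bounded cost-evaluation work. `θ = 1000·α` marks implausible
hypotheses, and edges whose cost reaches `θ` are pruned before solving
(structurally required edges — source/sink plumbing, appearance,
disappearance — are kept regardless). A split or merge node that loses
a structural edge in pruning is removed entirely; a partially
connected split node would otherwise act as an unconstrained flow
source.

Windows of `window_length = 10` frames overlapping by
`window_overlap = delta_t` frames keep the integer programs small; the
earlier window is authoritative up to the overlap midpoint, and
cross-window disagreements about a mask's predecessor (rare; counted in
the run manifest) are resolved in favour of the earlier window. A
consequence of the minimal overlap is that a gap link issued in the
last `delta_t` frames of a window can be truncated at the window
border; increasing `window_overlap` trades solver time for fewer
truncations.

### The solver

The pre-installed R stack offers no exact integer-programming solver,
so the package bundles one: a dense bounded-variable two-phase primal
simplex (Devex pricing, upper bounds handled by the flip substitution
`x → u − x`, Bland's rule on stalls) with depth-first branch and bound.
Flow polytopes of this family are nearly integral, so branching is
rare; typical windows solve at the root. The solver is validated in the
test suite against exhaustive enumeration on hundreds of random integer
programs and against an independent LP implementation on relaxations.

## Stage 3: untangling and gap filling

After matching, a track may have several predecessors (under-
segmentation, or several windows voting differently) or more than two
successors. Untangling selects operations — remove a predecessor link
(cost `γ`), split a track `n` into `z+1` parts (cost `span(n)·z`),
merge a candidate set `r` (cost `span(r)·(|r|−1)`) — minimising total
cost subject to one predecessor / two successors per track. Mergeable
sets must share predecessors and successors (with the stated
relaxations for tracks that begin later or end earlier than the
link-bearing member); all subsets of size ≥ 2 of each maximal group are
candidate sets, and a track may join at most one merge. The split
variable counts *additional* tracks: splitting into `K` parts costs
`span·(K−1)`, exactly the cost of merging `K` tracks over the same
span, so the two inverse repairs are priced symmetrically.
`γ = 2·⌈q30(track length) · q99(links per track)⌉` puts edge removal
above routine split/merge repairs but below modifications of long
tracks, computed over the preliminary graph.

Applying a split partitions every mask of the track around seed points
— the deepest distance-transform maxima, selected greedily with a
minimum separation, matched across frames by centroid continuity — and
distributes the predecessor/successor links among the parts by
proximity. Merges concatenate masks per frame. A final sweep guarantees
the structural post-condition (≤ 1 predecessor, ≤ 2 successors) even if
cost interactions left a residual violation, dropping the farthest
links and logging the fact; in all tested scenarios this sweep is a
no-op.

Remaining interior gaps are filled by translating the last mask before
the gap to centroid positions interpolated linearly between the two
anchors (rounded half-up per axis; the shape is *not* morphed toward
the post-gap mask — a literal reading of "place the last available
mask"). Gaps at a track's start or end have only one anchor and stay
unfilled. Pixels claimed by two masks go to the nearer centroid, ties
to the lower track id; only contested pixels are reassigned.

## Error simulation

The simulator degrades a ground truth so that exactly `⌊n% · masks⌋`
mask instances are modified: false negatives remove uniformly drawn
masks; over-segmentation splits uniformly drawn masks in two along a
random hyperplane through the centroid; under-segmentation repeatedly
draws neighbouring pairs (centroid distance below twice the default ROI
edge) with weights `1/(d+1)` — favouring close pairs, as in real
segmentation failures — and merges them with a morphological closing
(ball radius half the boundary gap), allowing chains of three or more
cells; the mixed mode applies the three mechanisms in equal shares on
disjoint selections, remainder to false negatives. Under-segmentation
stops short only when no eligible pair remains, recording the
shortfall. All simulators are pure functions of (sequence, seed).

## Evaluation measures

`SEG` is the mean, over ground-truth masks, of the Jaccard index with
the matched result mask, where matching requires the result mask to
cover more than half of the ground-truth mask (unmatched masks score
0). `DET` and `TRA` compare lineage graphs (nodes = mask instances,
edges = temporal links within tracks and mother–daughter links) via a
normalised edit cost: missing nodes must be added (weight 10), spurious
nodes deleted (1), multiply-matched nodes split (5), edges added (1.5),
deleted (1) or re-labelled between track and parent semantics (1);
`DET` zeroes the edge weights. Scores are 1 minus the edit cost over
the cost of building the ground-truth graph from nothing, floored at 0.
Descriptions of these measures fix only the ordering of the penalties
(adding nodes costs most); the numeric weights follow the published
AOGM convention, so absolute `DET`/`TRA` values here are comparable
to, but not bit-identical with, the official benchmark executable.

## Synthetic data: what it shows and what it does not

`generate_sequence()` produces elliptical (2D) or ellipsoidal (thin 3D)
cells of radius 7–11 px on a 256² canvas by default, moving with an
isotropic Gaussian step plus a constant per-cell drift (step norm
clamped at three standard deviations; reflective boundaries;
non-overlap enforced at placement and by step rejection). Divisions
replace a mother by two daughters of radius `r/√2` (area conservation),
just touching and symmetric about the mother's position, with a small
separating drift; newborn cells wait ten frames before dividing again —
successive divisions of the same lineage within a couple of frames are
biologically implausible and untrackable from positions alone. Raw
images are blurred mask intensities with Gaussian noise.

Defaults mirror the regime the tracker targets: per-frame displacement
(1.5 px) far below cell spacing, cell counts comparable to the lower
range of public benchmark sequences. The test suite's exact-recovery
check (30 frames, 15 cells, 3 divisions) and correction-direction
checks (20 frames, 20 cells, 5% degradation, five seeds, compared on
seed means) use these conditions; problem sizes are chosen so the full
suite runs in minutes on one core.

Passing them shows the machinery is sound — it does **not** show
benchmark-level performance on real microscopy: synthetic cells have no
appearance variation, no contact deformation, no photobleaching, and
their motion model is exactly the one the costs assume. Known
limitations carry over from the positional costs: two cells swapping
positions between frames are indistinguishable, persistent
under-segmentation (the same pair merged over many consecutive frames)
presents no one-predecessor signature and may even be "repaired" by
merging the clean upstream tracks when that is cheaper, and mask-shape
errors that leave less than half of a ground-truth mask covered cannot
be recovered by any relabelling.

## Parameter summary

| parameter | default | unit | role |
|---|---|---|---|
| `delta_t` | 3 | frames | max gap bridged by skip nodes |
| `roi_scale` | 2 | × mean mask extent | candidate search region |
| `alpha` | max default ROI edge | px | appearance/disappearance cap |
| `theta_factor` | 1000 | × `alpha` | implausibility cost and pruning threshold |
| `n_max_pairs` | 10 | pairs/object | mitosis pair cap |
| `window_length` | 10 | frames | ILP window |
| `window_overlap` | `delta_t` | frames | window stitching overlap |
| `gamma` | `2⌈q30·q99⌉` | cost units | edge-removal cost (untangling) |

Only `delta_t` and `roi_scale` are meant to be touched; everything else
derives from the data or from these two.
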