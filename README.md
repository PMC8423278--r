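# mcftrack

Graph-based cell tracking for 2D and 3D time-lapse microscopy with
automatic correction of segmentation errors.

`mcftrack` is a tracking-by-detection tool: it takes a time-ordered
sequence of instance-segmentation label images (Cell Tracking Challenge
layout: one TIFF label image per frame, 0 = background) and links the
segmented objects into a cell lineage. It is designed for the situation
every segmentation pipeline faces — masks that are sometimes missing
(false negatives), split in two (over-segmentation) or fused with a
neighbour (under-segmentation) — and repairs those errors automatically,
with only two manually chosen parameters (the temporal bridging span
`Δt` and the search-region scale).

## Method

Tracking proceeds in three stages.

1. **Tracklet stage.** Every segmented object gets a rectangular region
   of interest (ROI) whose per-axis size is twice the mean mask extent.
   The ROI is propagated over up to `Δt` frames using translation
   estimates from phase correlation of raw-image crops; objects whose
   bounding boxes intersect the propagated ROI become matching
   candidates.

2. **Matching stage — coupled minimum-cost flow.** Objects and their
   candidates become nodes of a typed directed graph: object nodes,
   skip nodes (a hypothesised missing mask, bridging up to `Δt` frames),
   split nodes (mitosis *or* over-segmentation), merge nodes
   (under-segmentation) and per-frame appear/delete nodes. Integer flow
   variables `z(u,v)` on the edges are optimised,

   min Σ c(u,v) · z(u,v)

   subject to flow conservation, unit flow through every object node,
   capacity bounds and ordering constraints that force flow through any
   split or merge node to be 0 or ≥ 2. Pairs of daughter candidates are
   coupled so that at most one mitosis pair per mother can be active and
   mitosis excludes over-segmentation at the same node. All costs are
   positional: centroid displacement for movement, distance-transform
   mask points for the merge/split hypotheses, a mother-midpoint
   criterion for mitosis pairs, and the distance to the image border
   (capped at `α`, the largest default ROI edge) for appearance and
   disappearance; implausible hypotheses cost `θ = 1000·α`. Long
   sequences are solved in overlapping windows and stitched by object
   identity. The integer programs are solved exactly by a bundled
   bounded-variable simplex with branch and bound.

3. **Post-processing.** The preliminary lineage graph may still contain
   tracks with several predecessors or more than two successors. An
   *untangling* integer program chooses the cheapest combination of
   edge removals (cost `γ`), track splits (cost = track span) and track
   merges (cost = merged span × (set size − 1)) such that every track
   ends up with ≤ 1 predecessor and ≤ 2 successors; splits partition
   the masks around distance-transform seed points, merges concatenate
   masks. Finally, interior gaps left by false negatives are filled
   with the last available mask translated along the linear
   interpolation between the anchor centroids, and overlapping pixels
   are assigned to the nearest centroid.

The package also bundles a synthetic ground-truth generator (moving
elliptical cells with divisions), a segmentation-error simulator
(FN / over / under / mixed degradation of a ground truth at a chosen
rate) and SEG / DET / TRA evaluation measures (mean Jaccard of matched
masks and normalised lineage-graph edit scores), so the entire system
can be exercised and validated without external data.

## Worked example

```r
library(mcftrack)

# synthesise a ground truth: 15 cells, 30 frames, 3 divisions
cfg <- simulation_config(shape = c(256L, 256L), n_frames = 30L,
                         n_cells = 15L, n_divisions = 3L, seed = 1)
sim <- generate_sequence(cfg)

# degrade it: remove / split / merge 5% of the masks
deg <- simulate_mixed(sim$gt, error_spec("mixed", 5, seed = 7))

# track the degraded segmentation
res <- track_sequence(labeled_sequence(deg$frames), raw = sim$raw)
res$graph
#> <tracking_graph> 45 track(s) over 30 frame(s)

# score against the ground truth
evaluate_tracking(sim$gt, res$result)
#>         SEG      DET       TRA
#> 1 0.9796092 0.984493 0.9789136
```

The scores mean: matched masks overlap the ground truth with a mean
Jaccard index of 0.98 (`SEG`), 98.4% of the detection edit cost was
avoided (`DET`), and 97.9% of the full lineage edit cost including
track and parent links was avoided (`TRA`) — starting from a
segmentation in which 5% of all masks had been removed, split or
merged. On the clean input
(`track_sequence(sim$gt, raw = sim$raw)`) all three scores are exactly
1. The run manifest (`res$manifest`) records the configuration, stage
timings and every untangling operation and interpolated mask.

Command-line use (thin wrapper over the same functions):

```sh
Rscript inst/scripts/mcftrack.R make-fixture fix --preset mitotic --seed 1
Rscript inst/scripts/mcftrack.R track <seg_dir> <out_dir> --raw <raw_dir>
Rscript inst/scripts/mcftrack.R evaluate <gt_dir> <res_dir>
Rscript inst/scripts/mcftrack.R simulate-errors <gt_dir> <out_dir> --type under --fraction 10
```

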