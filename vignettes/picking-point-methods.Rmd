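---
title: "Geometric picking-point localization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric picking-point localization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pickpoint)
```

## The problem

Selective harvesting of terminal flowers such as marigold (*Tagetes
erecta*) needs a cutting coordinate on the stem, just below the flower
head, where an end-effector can sever the corolla without damaging it.
Instance segmentation gives two masks per plant — the corolla (the petal
whorl, class 0) and the slender stem (class 1) — and the remaining task is
purely geometric: turn those two rasters into one pixel coordinate at the
calyx, the whorl of sepals where corolla and stem join.

`pickpoint` implements that geometric stage, its evaluation metrics, a
seeded synthetic-scene generator that supplies ground truth without any
external data, and a static complexity audit of the lightweight
segmentation architecture family the pipeline is designed around.

## The localization procedure

For one corolla/stem pair, `locate_picking_point()` runs four steps.

1. **Binarization and contour.** Masks are reduced to strict 0/1 rasters
   (`binarize()`; foreground is always 1 internally, whatever the on-disk
   encoding). The external boundary of the largest 8-connected corolla
   component is traced (`largest_contour()`).

2. **Constrained ellipse fit.** A direct least-squares conic fit with the
   ellipse constraint (Fitzgibbon's method in the numerically stable
   Halir–Flusser form) is fitted to the contour; a second-moments fallback
   covers conics the direct fit cannot resolve. The fitted ellipse is then
   *optimized into a picking ellipse*: the minor semi-axis is multiplied by
   1.4 as a safety margin (covering the calyx region below the visible
   corolla and reducing the risk of cutting too close), and the
   orientation is **forced to a fixed 30° inclination**, reflecting the
   typical tilted pose of the flower heads. Orientation here is measured
   counter-clockwise from the +x image axis, modulo 180°; that reference
   is a documented package convention, chosen because the procedure needs
   orientation to be a controlled parameter (see the fallback below).

3. **Stem skeletonization.** The stem mask is cleaned with one
   morphological opening and one closing (3×3 square structuring element —
   the smallest kernel that removes single-pixel speckle and fills
   single-pixel holes), thinned to a 1-pixel-wide skeleton with the
   Zhang–Suen two-subpass algorithm (simultaneous deletion within each
   sub-pass, iterated to a fixed point), and pruned: endpoint branches
   shorter than 10 pixels are deleted, then connected fragments smaller
   than 10 pixels are dropped (never emptying the skeleton entirely).

4. **Intersection and selection.** The filled picking ellipse is
   rasterized and intersected pixel-wise with the skeleton. Among the
   common pixels the one with **minimum y** (uppermost in image
   coordinates, i.e. nearest the corolla) is the picking point. If the
   30° ellipse meets no skeleton pixel, the ellipse is rotated once by
   90° (to 120°) and the comparison repeated; a point found then is
   flagged `used_fallback`. If the rotated pass also fails the procedure
   terminates with `no_intersection`.

Multi-plant frames are handled by `process_image()`: corolla and stem
instances are paired greedily by the distance from each corolla centroid
to each stem's topmost pixel (nearest pair first), which encodes the
"stem hangs below its corolla" geometry without assuming an instance
ordering.

### Tunable parameters

| key | default | unit | role |
|---|---|---|---|
| `initial_angle_deg` | 30 | degrees | forced picking-ellipse inclination |
| `minor_scale` | 1.4 | — | minor-axis safety margin |
| `fallback_rotation_deg` | 90 | degrees | single retry rotation |
| `morph_kernel` | 3 | px | opening/closing structuring element |
| `prune_min_len` | 10 | px | minimum surviving branch / fragment |
| `min_contour_points` | 5 | points | ellipse-fit feasibility threshold |
| `match_radius` | 10 | px | evaluation tolerance radius |
| `ellipse_fill` | `"filled"` | — | intersect filled ellipse or outline ring |

The first five are the method's published operating point. `match_radius`
is not specified anywhere as a number: the accuracy metric is defined over
"the calyx and its adjacent regions", so the package exposes the radius
explicitly and defaults to 10 px — the same scale as the pruning
threshold. Results quoting AP/WP should state the radius used.

`ellipse_fill` exists because a filled picking region and an outline-only
ring are both defensible readings of intersecting "the ellipse mask" with
the skeleton. Filled is the default; with a filled ellipse the minimum-y
rule selects the skeleton pixel closest to the corolla top, which on the
synthetic benchmark lands within a few pixels of the calyx either way.

## Numerical and geometric conventions

* **Coordinates.** 0-based `(x, y)` with x rightward, y downward; a pixel
  index addresses the centre of a unit square. All rasterizers evaluate
  membership at pixel centres.
* **Polygon rasterization** (`fill_polygon_mask()`) uses half-open
  even-odd scanline filling: an edge spans scanlines `[min(y), max(y))`
  and a span fills centres `[x_enter, x_exit)`. Two polygons sharing an
  edge therefore never double-fill a pixel. Normalized label coordinates
  map to continuous pixel coordinates as `x * width - 0.5`, so the unit
  square covers the full image extent.
* **Ellipse fits carry a half-pixel boundary margin.** Contours traced on
  rasters pass through boundary-pixel centres, which lie about half a
  pixel inside the underlying region; fitted semi-axes are therefore
  inflated by 0.5 px (`boundary_margin`, settable to 0 for exact
  sub-pixel contours). Without the margin, fit-then-rasterize shrinks
  regions by one pixel ring, which for a 10-pixel axis is a 10% bias.
* **Degenerate inputs.** Collinear contours raise a degenerate-fit error;
  fewer than `min_contour_points` points raise an insufficient-points
  error; empty masks are reported through the `status` field
  (`no_corolla`, `no_stem`) rather than as exceptions.
* **Ties** in the minimum-y rule are broken by distance to the ellipse
  centre, then by minimum x — an arbitrary but deterministic completion
  of the published rule, which only specifies minimum y.

### Two notions of "junction"

`classify_skeleton_pixels()` uses the classical definitions: an endpoint
has exactly one foreground 8-neighbour, a junction three or more. On thin
8-connected paths this flags not only a true branch point but also its
diagonally adjacent arm pixels, so a T of two meeting lines exposes a
tight *cluster* of junction pixels around the meeting point.

Pruning needs something sharper. Zhang–Suen fixed points contain
*staircase corners* — an L-shaped pixel pair the algorithm cannot delete
(its transition count is 2) even though the path could step diagonally.
Such corners have three neighbours but only two emanating branches, and
treating them as junctions would truncate every curved path at its first
corner. `prune_skeleton()` therefore detects branch points by **crossing
number** — the count of distinct 0→1 transitions around the pixel — which
is 2 at corners and ≥ 3 exactly where the skeleton genuinely branches.

### A Zhang–Suen caveat

With the published simultaneous-update semantics, an isolated 2×2 square
is deleted entirely in one sub-pass (all four pixels satisfy the deletion
conditions at once). Thinning therefore preserves the number of
8-connected components *except* for such squares, which vanish. The test
suite asserts exactly this corrected property, alongside pixel-exact
agreement between the production (vectorized) implementation and a
literal per-pixel transcription of the two sub-passes.

## The synthetic scene generator

No public dataset exists for this task, so `generate_scene()` builds
scenes with known ground truth: per plant, a filled elliptical corolla
(semi-major axis 25–60 px at the default 640×640 frame, axis ratio
0.55–0.9, tilt 10–50° with a random mirror flip) and a quadratic-Bézier
stem of width 2–8 px and length 90–200 px descending from the corolla
base, with mild lean and lateral bow. The ground-truth calyx is the
intersection of the stem centreline with the corolla boundary — the
attachment point a human annotator would mark. The default ranges were
chosen once as plausible proportions for close-range field imagery of
flowering plants scaled to a 640-pixel frame (corolla diameters roughly
an eighth to a fifth of the frame, stems an order of magnitude thinner);
they are deliberately broad rather than matched to any specific camera
geometry.

Stems are rasterized by *pixel-footprint coverage*: a pixel is stem
whenever the tube overlaps its unit square (distance to the centreline ≤
width/2 + 0.5). Centre-point sampling would under-represent structures
thinner than 3 px, which the 3×3 opening then provably erases — a
rasterization artifact, not a property of the method under study.
Footprint coverage also matches what human annotation and soft-mask
thresholding produce for slender structures.

Two stressors are available: `speckle_density` sprinkles salt noise on
both masks (removed by the opening, by design), and `occlusion_gap` cuts
a gap of the given length into the stem near its top — emulating the
dominant real failure mode, a leaf or the corolla itself hiding the stem
below the flower. The gap begins at a random arc position in the upper
portion of the stem, so a short stub may remain below the calyx; when
that stub falls under the 10-px pruning threshold the skeleton loses its
upper end and the intersection fails, which is exactly the degradation
the benchmark measures.

What the generator does **not** emulate: photometric appearance (it
produces masks, not images), segmentation errors of a real model (ragged
boundaries, false splits/merges), leaves and weeds as distractor classes,
and perspective foreshortening. Passing the synthetic benchmark therefore
validates the geometry stage in isolation; it says nothing about upstream
segmentation quality on real imagery.

Benchmark sizes used by the test suite — 200 clean scenes plus 40
occluded scenes at 640×640 for end-to-end recovery, 1000 random 32×32
masks for the thinning oracle, 100 random convex polygons for the
rasterization oracle — were chosen as the smallest populations that
exercise the relevant variability while keeping the default suite quick
on a laptop.

```{r recovery, eval = FALSE}
# end-to-end recovery on one clean scene
sc <- generate_scene(scene_params(seed = 1))
locate_picking_point(sc$seg$corolla_instances[[1]],
                     sc$seg$stem_instances[[1]])
```

## Evaluation metrics

`match_points()` pairs predictions with ground truth greedily in
ascending distance order, one-to-one; a truth point within
`match_radius` of its match counts as accurately detected. The accuracy
rate AP = 100·Point_a/Point_all and wrong-point rate WP =
100·Point_e/Point_all are complements summing to 100. Greedy matching
equals optimal assignment whenever the within-radius relation is
unambiguous (no point lies within the radius of two counterparts); in
ambiguous configurations greedy can differ from optimal, which the test
suite demonstrates and excludes by construction. Unmatched truths count
as undetected whether the corresponding prediction was missing or merely
misplaced — the stricter of the two possible readings.

## The architecture audit

The segmentation model family the pipeline is designed around is audited
statically: each variant is a graph of layer records carrying exact
parameter and FLOP formulas plus output strides, and "running" the model
is shape propagation through that graph. Building the five ablation
variants (`baseline`, `starnet`, `starnet_c2fstar`,
`starnet_segmarigold`, `full`) and summing gives the published
complexity figures exactly; no tensor arithmetic, weights or training are
involved, which is all a complexity audit needs.

Conventions, stated once and used everywhere:

* **Parameters are deployment-time counts.** Batch normalization folds
  into the preceding convolution at inference (net effect: one bias per
  conv), and the published tables in this field report the fused model.
  Group normalization cannot fold and keeps its 2C affine parameters;
  the distribution-focal box-decoding weights are counted with the model.
* **FLOPs** count convolutions and linear maps as 2·k²·C_in·C_out·H·W/g
  (multiply-add = 2), at 640×640 unless stated; normalization,
  activations and element-wise products are excluded. `estimate_flops()`
  also reports MACs for transparency.
* The StarNet-style backbone uses a stride-2 stem to 16 channels and four
  stages (widths 16/32/64/160, depths 1/4/6/1), each entered through a
  depthwise-separable stride-2 downsampler and built from Star blocks:
  depthwise 3×3, two parallel 1×1 expansions (ratio 3) fused by
  element-wise multiplication, 1×1 re-projection, depthwise 3×3,
  residual. The last three stages feed the neck at strides 8/16/32. The
  width/depth schedule is pinned by the published parameter counts of the
  ablation grid, which function as the schedule's specification; where
  prose descriptions of the backbone conflict with those counts, the
  counts win.
* The neck keeps the YOLOv8 C2f split/concat topology; the lightweight
  variant replaces each bottleneck with a Star block (7×7 depthwise,
  expansion ratio 3).
* The lightweight head shares one stack of three 3×3 Conv-GN layers
  across the three scales (parameters once, compute per scale), with
  per-scale 1×1 Conv-GN projections in, two sibling 1×1 Conv-GN outputs
  (box distribution over 8 bins + 2 class logits; 32 mask coefficients),
  one learnable scalar per scale and output branch (the Scale units that
  let a shared stack adapt per resolution), and a prototype-mask branch
  with parameter-free upsampling. The baseline head is the standard
  decoupled YOLOv8-seg head with its YOLACT-style prototype branch.

```{r audit, eval = FALSE}
glance(build_model(arch_config("full")))
model_summary(build_model(arch_config("baseline")))
```

Model file size depends on serialization and is reported informationally
as parameters × 2 bytes (fp16); it is never asserted.

## Known limitations

* The pipeline trusts its input masks; with heavily fragmented stems the
  pruning stage can remove the calyx-side fragment, and no temporal or
  depth information is available to recover it (failure statuses make
  this visible rather than silent).
* One fallback rotation only: corollas whose pose defeats both the 30°
  and 120° ellipses yield `no_intersection` by design.
* The audit counts structure, not learned behaviour: it cannot validate
  accuracy claims, only complexity ones.
* Greedy instance pairing is quadratic in instances per frame; fine for
  field scenes (a handful of plants), not for dense imagery.
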