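# pickpoint

Geometric localization of harvesting points for terminal flowers from
instance segmentation masks, in R.

Robotic harvesting of flowers such as marigold needs one pixel
coordinate per plant: the point on the stem at the calyx — the base of
the flower head — where the end-effector should cut. Upstream, a
segmentation model delivers a *corolla* mask (the flower head, class 0)
and a *stem* mask (class 1). `pickpoint` implements the downstream
geometry that turns those masks into a picking point, the metrics used
to score it, a seeded synthetic-scene generator with ground truth, and
an analytic complexity audit of the lightweight segmentation
architecture family the pipeline is built around.

## The method

For each corolla/stem pair:

1. **Corolla ellipse.** Fit an ellipse E(c, a, b, θ) to the corolla
   boundary by direct least squares (Fitzgibbon/Halir–Flusser), then
   build the *picking ellipse*: b ← 1.4·b (safety margin) and θ ← 30°
   (the fixed picking inclination).
2. **Stem skeleton.** Morphological opening + closing (3×3), Zhang–Suen
   thinning to a 1-px skeleton, pruning of branches and fragments
   shorter than 10 px.
3. **Intersection.** Rasterize the filled picking ellipse and intersect
   it with the skeleton; the pixel with minimum y (closest to the flower)
   is the picking point. If empty, rotate the ellipse once by 90° and
   retry; report `no_intersection` if that fails too.

Accuracy is scored as AP = 100·Point_a/Point_all and
WP = 100·Point_e/Point_all, where Point_a counts ground-truth calyx
points matched by a prediction within a tolerance radius (greedy
one-to-one matching, 10 px default) and Point_e = Point_all − Point_a.

The architecture audit builds layer graphs of five ablation variants of
a YOLOv8n-seg-derived segmentation family (StarNet backbone, Star-block
neck, shared group-normalized head) and counts deployment-time (fused)
parameters and forward-pass FLOPs (multiply-add = 2, 640×640)
analytically.

## Worked example

```r
library(pickpoint)

sc  <- generate_scene(scene_params(seed = 42))   # one synthetic plant
res <- process_image(sc$seg)
res
#>   instance_id   x   y status used_fallback
#> 1           1 437 161  found         FALSE

sc$truth[, c("calyx_x", "calyx_y")]
#>    calyx_x  calyx_y
#> 1 437.1843 160.1127

evaluate_points(res[res$status == "found", c("x", "y")],
                data.frame(x = sc$truth$calyx_x, y = sc$truth$calyx_y))
#> Picking-point evaluation
#>   Point_all: 1   Point_a: 1   Point_e: 0
#>   AP: 100.00%   WP: 0.00%
```

The located point (437, 161) sits within 1.2 px of the generated calyx,
and the evaluation table reports it as an accurate detection. On 200
clean seeded scenes the pipeline recovers every picking point with a
median error around 1 px; cutting an occlusion gap into the stems makes
the failure rate rise, mirroring the stem-occlusion failure mode of real
field imagery (see the methods vignette).

The complexity audit:

```r
glance(build_model(arch_config("full")))
#>   variant num_classes input_size total_params   gflops    gmacs size_mb_fp16
#> 1    full           2        640      1507349 8.057843 4.028922      2.87504

model_summary(build_model(arch_config("baseline")))
#>     module  params    gflops
#> 1 backbone 1270144  3.155558
#> 2     head 1003350  6.850099
#> 3     neck  984960  1.966080
#> 4    total 3258454 11.971738
```

The full lightweight variant audits at 1,507,349 parameters and
8.1 GFLOPs against the 3,258,454-parameter, 12.0-GFLOP baseline — a
53.7% parameter reduction.

A thin CLI wraps the same functions
(`inst/cli/pickpoint {locate|evaluate|simulate|audit-arch}`), e.g.

```sh
Rscript inst/cli/pickpoint simulate --n 20 --seed 7 --out fixtures/
Rscript inst/cli/pickpoint locate --input fixtures --input-format png --out points.csv
Rscript inst/cli/pickpoint audit-arch --variant full
```

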