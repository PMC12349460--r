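test_that("mask intersection returns common foreground in row-major order", {
  a <- matrix(0L, 10, 10); a[2:4, 2:4] <- 1L
  b <- matrix(0L, 10, 10); b[7:9, 7:9] <- 1L
  expect_equal(nrow(intersect_masks(binary_mask(a), binary_mask(b))), 0L)

  # vertical skeleton line through a filled ellipse: candidates hug the line
  sk <- matrix(0L, 100, 100); sk[, 51] <- 1L
  em <- rasterize_ellipse(ellipse(50, 50, 30, 14, 90), c(100, 100))
  got <- intersect_masks(binary_mask(sk), em)
  expect_true(all(got[, "x"] == 50))
  oracle <- which(sk == 1L & unclass(em) == 1L)
  expect_equal(nrow(got), length(oracle))
  expect_true(all(diff(got[, "y"]) >= 0))       # row-major ordering

  # all-ones ellipse mask returns exactly the skeleton pixels
  ones <- binary_mask(matrix(1L, 100, 100))
  expect_equal(nrow(intersect_masks(binary_mask(sk), ones)), sum(sk))

  expect_error(
    intersect_masks(binary_mask(a), binary_mask(matrix(0L, 5, 5))),
    "shape"
  )
})

test_that("point selection prefers minimum y with deterministic tie-breaks", {
  expect_equal(
    unname(select_point(rbind(c(5, 10), c(7, 8)))),
    c(7, 8)
  )
  expect_equal(unname(select_point(rbind(c(3, 4)))), c(3, 4))
  expect_null(select_point(matrix(numeric(0), 0, 2)))

  # tie on y: nearer to the centre wins, then smaller x
  cands <- rbind(c(2, 5), c(9, 5), c(6, 5))
  expect_equal(unname(select_point(cands, center = c(6.2, 20))), c(6, 5))
  expect_equal(unname(select_point(rbind(c(4, 5), c(2, 5)), center = c(3, 5))),
               c(2, 5))
})

test_that("locate_picking_point reports failure modes in status", {
  empty <- binary_mask(matrix(0L, 64, 64))
  blob <- rasterize_ellipse(ellipse(32, 20, 12, 8, 0), c(64, 64))
  stem <- matrix(0L, 64, 64); stem[30:60, 33] <- 1L

  expect_equal(locate_picking_point(blob, empty)$status, "no_stem")
  expect_equal(locate_picking_point(empty, binary_mask(stem))$status, "no_corolla")

  far <- matrix(0L, 64, 64); far[48:63, 58:60] <- 1L
  res <- locate_picking_point(blob, binary_mask(far))
  expect_equal(res$status, "no_intersection")
})

test_that("clean synthetic scenes localize the calyx without the fallback", {
  sc <- generate_scene(scene_params(seed = 1))
  res <- locate_picking_point(sc$seg$corolla_instances[[1]],
                              sc$seg$stem_instances[[1]])
  expect_equal(res$status, "found")
  expect_false(res$used_fallback)
  err <- sqrt((res$x - sc$truth$calyx_x)^2 + (res$y - sc$truth$calyx_y)^2)
  expect_lte(err, 5)
})

test_that("found points lie on both the skeleton and the picking ellipse", {
  cfg <- pipeline_config()
  for (seed in c(2, 9, 17)) {
    sc <- generate_scene(scene_params(seed = seed))
    cm <- sc$seg$corolla_instances[[1]]; sm <- sc$seg$stem_instances[[1]]
    res <- locate_picking_point(cm, sm, cfg)
    expect_equal(res$status, "found")
    skel <- prune_skeleton(zhang_suen_thin(clean_mask(sm, cfg$morph_kernel)),
                           cfg$prune_min_len)
    expect_equal(skel$mask[res$y + 1, res$x + 1], 1L)
    pe <- make_picking_ellipse(fit_ellipse(largest_contour(cm)), cfg)
    if (res$used_fallback) pe <- rotate_ellipse(pe, cfg$fallback_rotation_deg)
    emask <- rasterize_ellipse(pe, dim(unclass(cm)))
    expect_equal(emask[res$y + 1, res$x + 1], 1L)
  }
})

test_that("identical inputs give identical outputs", {
  sc <- generate_scene(scene_params(seed = 21))
  r1 <- locate_picking_point(sc$seg$corolla_instances[[1]],
                             sc$seg$stem_instances[[1]])
  r2 <- locate_picking_point(sc$seg$corolla_instances[[1]],
                             sc$seg$stem_instances[[1]])
  expect_identical(r1, r2)
})

test_that("the 90-degree fallback fires exactly when the first pass is empty", {
  # corolla whose 30-degree picking ellipse misses a short skeleton segment
  # that the 120-degree rotation covers
  cm <- rasterize_ellipse(ellipse(60, 60, 30, 10, 0), c(120, 120))
  fitted <- fit_ellipse(largest_contour(cm))
  cfg <- pipeline_config()
  e30 <- make_picking_ellipse(fitted, cfg)
  e120 <- rotate_ellipse(e30, cfg$fallback_rotation_deg)
  m30 <- unclass(rasterize_ellipse(e30, c(120, 120)))
  m120 <- unclass(rasterize_ellipse(e120, c(120, 120)))
  only120 <- which(m120 == 1L & m30 == 0L)
  expect_gt(length(only120), 30)
  # build a stem (3 px wide, so it survives cleaning) whose skeleton is a
  # straight segment inside that area
  ys <- (only120 - 1L) %% 120L; xs <- (only120 - 1L) %/% 120L
  col <- as.integer(names(sort(table(xs), decreasing = TRUE))[1])
  yr <- range(ys[xs == col])
  yr <- yr + c(2L, -2L)   # stay clear of the region's rim
  stem <- matrix(0L, 120, 120)
  stem[(yr[1]:yr[2]) + 1L, col + (0:2)] <- 1L
  stopifnot(diff(yr) + 1 >= 12)
  stopifnot(all(m30[(yr[1]:yr[2]) + 1L, col + 1L] == 0L))
  res <- locate_picking_point(cm, binary_mask(stem), cfg)
  expect_equal(res$status, "found")
  expect_true(res$used_fallback)

  # monotone fallback: when the 30-degree pass succeeds the flag stays off
  stem2 <- matrix(0L, 120, 120)
  stem2[61:110, 60:62] <- 1L
  res2 <- locate_picking_point(cm, binary_mask(stem2), cfg)
  expect_equal(res2$status, "found")
  expect_false(res2$used_fallback)
})

test_that("process_image pairs instances and degrades gracefully", {
  sc <- generate_scene(scene_params(seed = 5))
  seg <- sc$seg
  res <- process_image(seg)
  expect_equal(nrow(res), 1L)
  one <- locate_picking_point(seg$corolla_instances[[1]],
                              seg$stem_instances[[1]])
  expect_identical(res, one)

  # two well-separated plants pair with their own stems
  sc2 <- generate_scene(scene_params(seed = 3, n_plants = 2))
  res2 <- process_image(sc2$seg)
  expect_equal(res2$status, c("found", "found"))
  for (i in 1:2) {
    err <- sqrt((res2$x[i] - sc2$truth$calyx_x[i])^2 +
                  (res2$y[i] - sc2$truth$calyx_y[i])^2)
    expect_lte(err, 5)
  }

  # corolla without any stem instance
  seg3 <- segmentation_result(
    seg$image_shape,
    corolla_instances = seg$corolla_instances
  )
  res3 <- process_image(seg3)
  expect_equal(res3$status, "no_stem")

  # no corollas: zero rows
  expect_equal(nrow(process_image(segmentation_result(c(64, 64)))), 0L)
})
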