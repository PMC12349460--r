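test_that("largest_contour follows the largest component's boundary", {
  m <- matrix(0L, 12, 12); m[6, 6] <- 1L
  expect_equal(largest_contour(binary_mask(m)), cbind(x = 5L, y = 5L))

  # two components: 100 px beats 9 px
  m <- matrix(0L, 30, 30)
  m[2:11, 2:11] <- 1L
  m[20:22, 20:22] <- 1L
  ct <- largest_contour(binary_mask(m))
  expect_true(all(ct[, "x"] <= 10 & ct[, "y"] <= 10))

  # filled 10x10 square at the origin: 36 perimeter pixels, each visited
  m <- matrix(0L, 20, 20); m[1:10, 1:10] <- 1L
  ct <- largest_contour(binary_mask(m))
  expect_equal(nrow(ct), 36L)
  expect_setequal(
    paste(ct[, "x"], ct[, "y"]),
    paste(boundary_pixels_oracle(m)[, 1L], boundary_pixels_oracle(m)[, 2L])
  )
  # consecutive contour points are 8-adjacent and the path closes
  d <- pmax(abs(diff(c(ct[, "x"], ct[1, "x"]))), abs(diff(c(ct[, "y"], ct[1, "y"]))))
  expect_true(all(d == 1))

  expect_error(largest_contour(binary_mask(matrix(0L, 4, 4))), "no foreground")
})

test_that("direct ellipse fit recovers generating circles and ellipses", {
  circ <- binary_mask(ellipse_raster_oracle(32, 32, 20, 20, 0, c(64, 64)))
  f <- fit_ellipse(largest_contour(circ))
  expect_lt(abs(f$center_x - 32), 1)
  expect_lt(abs(f$center_y - 32), 1)
  expect_lt(abs(f$semi_major - 20), 1)
  expect_lt(abs(f$semi_minor - 20), 1)

  ell <- binary_mask(ellipse_raster_oracle(40, 40, 30, 12, 0, c(80, 80)))
  f <- fit_ellipse(largest_contour(ell))
  expect_lt(abs(f$semi_major - 30), 1)
  expect_lt(abs(f$semi_minor - 12), 1)
  expect_lt(min(f$angle_deg, 180 - f$angle_deg), 2)

  expect_error(fit_ellipse(cbind(1:4, 1:4)), "at least")
  expect_error(fit_ellipse(cbind(1:9, (1:9) * 2)), "collinear")
})

test_that("ellipse fit is translation-equivariant", {
  set.seed(11)
  th <- seq(0, 2 * pi, length.out = 60)[-60]
  xs <- 25 * cos(th) * cos(0.4) - 11 * sin(th) * sin(0.4) + 50
  ys <- 25 * cos(th) * sin(0.4) + 11 * sin(th) * cos(0.4) + 48
  f0 <- fit_ellipse(cbind(xs, ys))
  for (shift in list(c(3.5, -2.25), c(-10, 20))) {
    f1 <- fit_ellipse(cbind(xs + shift[1], ys + shift[2]))
    expect_equal(f1$center_x, f0$center_x + shift[1], tolerance = 1e-6)
    expect_equal(f1$center_y, f0$center_y + shift[2], tolerance = 1e-6)
    expect_equal(f1$semi_major, f0$semi_major, tolerance = 1e-6)
    expect_equal(f1$semi_minor, f0$semi_minor, tolerance = 1e-6)
  }
})

test_that("picking-ellipse optimization scales the minor axis and forces the angle", {
  f <- ellipse(50, 50, 20, 10, 77)
  p <- make_picking_ellipse(f, pipeline_config())
  expect_equal(p$semi_minor, 14)         # x1.4 safety margin
  expect_equal(p$angle_deg, 30)          # forced inclination
  expect_equal(p$semi_major, 20)
  expect_equal(c(p$center_x, p$center_y), c(50, 50))

  # identity configuration
  cfg <- pipeline_config(minor_scale = 1, initial_angle_deg = 77)
  expect_equal(unclass(make_picking_ellipse(f, cfg)), unclass(f))

  # scaling past the major axis swaps the axes and keeps the invariant
  f2 <- ellipse(50, 50, 10, 9, 0)
  p2 <- make_picking_ellipse(f2, pipeline_config(minor_scale = 2))
  expect_equal(p2$semi_major, 18)
  expect_equal(p2$semi_minor, 10)
  expect_equal(p2$angle_deg, 120)        # 30 + 90 from the swap
})

test_that("rotate_ellipse adds the angle modulo 180", {
  e <- ellipse(10, 10, 5, 3, 30)
  expect_equal(rotate_ellipse(e, 90)$angle_deg, 120)
  expect_equal(rotate_ellipse(ellipse(10, 10, 5, 3, 120), 90)$angle_deg, 30)
  expect_equal(unclass(rotate_ellipse(e, 0)), unclass(e))
})

test_that("ellipse rasterization matches the per-pixel inequality", {
  # fully outside the frame
  e <- ellipse(200, 200, 10, 5, 45)
  expect_equal(sum(rasterize_ellipse(e, c(50, 50))), 0)

  # disc area close to pi r^2
  e <- ellipse(32, 32, 15, 15, 0)
  got <- sum(rasterize_ellipse(e, c(64, 64)))
  expect_lt(abs(got - pi * 15^2), 4 * 15)

  # pixel-exact against the generating inequality at an oblique angle
  e <- ellipse(30, 28, 21, 9, 37)
  expect_identical(
    unclass(rasterize_ellipse(e, c(60, 60))),
    ellipse_raster_oracle(30, 28, 21, 9, 37, c(60, 60))
  )

  # 180-degree symmetry
  expect_identical(
    unclass(rasterize_ellipse(rotate_ellipse(e, 180), c(60, 60))),
    unclass(rasterize_ellipse(e, c(60, 60)))
  )

  # outline mode is a subset ring of the filled mask
  ring <- rasterize_ellipse(e, c(60, 60), fill = "outline")
  full <- rasterize_ellipse(e, c(60, 60))
  expect_true(all(unclass(ring) <= unclass(full)))
  expect_gt(sum(ring), 0)
  expect_lt(sum(ring), sum(full))
})

test_that("minor-axis scaling multiplies raster area by the scale factor", {
  for (geom in list(c(20, 12, 0), c(25, 18, 60), c(15, 10, 140))) {
    e <- ellipse(64, 64, geom[1], geom[2], geom[3])
    p <- make_picking_ellipse(e, pipeline_config(initial_angle_deg = geom[3]))
    a0 <- sum(rasterize_ellipse(e, c(128, 128)))
    a1 <- sum(rasterize_ellipse(p, c(128, 128)))
    expect_lt(abs(a1 / a0 - 1.4), 0.05 * 1.4)
  }
})

test_that("fit-then-rasterize keeps high overlap with the generating raster", {
  set.seed(5)
  for (i in 1:8) {
    a <- runif(1, 10, 28); b <- runif(1, 10, a); ang <- runif(1, 0, 180)
    gen <- ellipse_raster_oracle(40, 40, a, b, ang, c(80, 80))
    f <- fit_ellipse(largest_contour(binary_mask(gen)))
    back <- unclass(rasterize_ellipse(f, c(80, 80)))
    jac <- sum(gen & back) / sum(gen | back)
    expect_gte(jac, 0.95)
  }
})
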