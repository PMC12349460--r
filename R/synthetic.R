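#' Synthetic scene parameters
#'
#' Controls the seeded generator of corolla / stem mask scenes. Each plant
#' is a filled, tilted elliptical corolla attached at its base to a slender
#' quadratic-curve stem rising from below; the ground-truth calyx point is
#' the intersection of the stem centreline with the corolla boundary.
#' Ranges are sampled uniformly per plant.
#'
#' @param image_shape frame `(height, width)` in pixels.
#' @param n_plants plants per frame.
#' @param corolla_a corolla semi-major-axis range, pixels.
#' @param corolla_axis_ratio minor/major axis ratio range.
#' @param corolla_tilt_deg corolla tilt range, degrees (a random mirror flip
#'   makes both tilt directions equally likely).
#' @param stem_width stem width range, pixels.
#' @param stem_length stem length range, pixels.
#' @param stem_curvature maximum lateral bow of the stem as a fraction of
#'   its length.
#' @param occlusion_gap length in pixels of a gap cut into the stem near its
#'   top (0 disables); emulates the corolla or a leaf hiding the stem.
#' @param speckle_density fraction of frame pixels flipped to foreground as
#'   salt noise on each mask (0 disables).
#' @param seed integer seed; every scene is fully deterministic given it.
#' @return a list of class `scene_params`.
#' @export
scene_params <- function(image_shape = c(640, 640),
                         n_plants = 1,
                         corolla_a = c(25, 60),
                         corolla_axis_ratio = c(0.55, 0.9),
                         corolla_tilt_deg = c(10, 50),
                         stem_width = c(2, 8),
                         stem_length = c(90, 200),
                         stem_curvature = 0.15,
                         occlusion_gap = 0,
                         speckle_density = 0,
                         seed = 1) {
  rng <- function(r) if (length(r) == 1L) c(r, r) else r
  p <- list(
    image_shape = as.integer(image_shape),
    n_plants = as.integer(n_plants),
    corolla_a = rng(corolla_a),
    corolla_axis_ratio = rng(corolla_axis_ratio),
    corolla_tilt_deg = rng(corolla_tilt_deg),
    stem_width = rng(stem_width),
    stem_length = rng(stem_length),
    stem_curvature = stem_curvature,
    occlusion_gap = occlusion_gap,
    speckle_density = speckle_density,
    seed = as.integer(seed)
  )
  stopifnot(
    all(p$image_shape >= 64L), p$n_plants >= 1L,
    p$stem_width[1L] >= 1, p$speckle_density >= 0, p$speckle_density < 1,
    p$occlusion_gap >= 0
  )
  class(p) <- "scene_params"
  p
}

# run code under a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

runif1 <- function(r) stats::runif(1L, r[1L], r[2L])

# radius of an ellipse boundary in direction phi (from centre), angles in rad
ellipse_radius <- function(a, b, theta, phi) {
  a * b / sqrt((b * cos(phi - theta))^2 + (a * sin(phi - theta))^2)
}

# rasterize a tube of the given width around a densely sampled centreline:
# a pixel is foreground when its centre lies within width/2 of some sample.
# working from the continuous sample positions keeps the tube edges smooth,
# so thinning recovers the centreline without spurious side spurs.
paint_tube <- function(m, px, py, width) {
  h <- nrow(m); w_ <- ncol(m)
  # footprint rasterization: a pixel is stem when the tube overlaps its unit
  # square (not merely its centre) -- slender structures would otherwise
  # fall below the sampling grid and be erased by morphological cleaning
  r <- width / 2 + 0.5
  ri <- ceiling(r) + 1L
  offs <- expand.grid(dx = -ri:ri, dy = -ri:ri)
  cx <- rep(px, each = nrow(offs))
  cy <- rep(py, each = nrow(offs))
  xs <- floor(cx) + offs$dx
  ys <- floor(cy) + offs$dy
  ok <- xs >= 0L & xs < w_ & ys >= 0L & ys < h &
    (xs - cx)^2 + (ys - cy)^2 <= r^2
  m[cbind(ys[ok] + 1L, xs[ok] + 1L)] <- 1L
  m
}

sample_plant <- function(p, h, w) {
  a <- runif1(p$corolla_a)
  b <- a * runif1(p$corolla_axis_ratio)
  tilt <- runif1(p$corolla_tilt_deg)
  if (stats::runif(1L) < 0.5) tilt <- 180 - tilt
  len <- runif1(p$stem_length)
  width <- runif1(p$stem_width)
  margin <- a + 5
  list(
    a = a, b = b, tilt = tilt,
    stem_length = len, stem_width = width,
    cx = stats::runif(1L, margin, w - 1 - margin),
    cy = stats::runif(1L, margin, max(margin + 1, h - 1 - len - margin)),
    attach_jitter = stats::runif(1L, -15, 15),
    lean = stats::runif(1L, -10, 10),
    bow = stats::runif(1L, -1, 1) * p$stem_curvature
  )
}

#' Generate a synthetic corolla / stem scene
#'
#' Fully deterministic given `params$seed`. Per plant the generator places a
#' tilted elliptical corolla, attaches a curved stem of the requested width
#' to the corolla base, optionally cuts an occlusion gap into the stem and
#' sprinkles speckle noise on both class masks. Plants are placed without
#' mutual overlap; an impossible placement after bounded retries is an
#' error.
#'
#' @param params a [scene_params()].
#' @return a list with elements `seg` (a [segmentation_result()] with one
#'   corolla and one stem instance per plant) and `truth` (a tibble of
#'   ground-truth calyx points and realized per-plant parameters).
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  h <- params$image_shape[1L]; w <- params$image_shape[2L]
  with_local_seed(params$seed, {
    plants <- list()
    for (i in seq_len(params$n_plants)) {
      placed <- FALSE
      for (try in 1:100) {
        cand <- sample_plant(params, h, w)
        clash <- any(vapply(plants, function(q) {
          sqrt((q$cx - cand$cx)^2 + (q$cy - cand$cy)^2) <
            1.4 * (q$a + cand$a) + 2 * max(q$stem_width, cand$stem_width) + 12
        }, logical(1)))
        # keep descending stems out of each other's column
        clash <- clash || any(vapply(plants, function(q) {
          abs(q$cx - cand$cx) < (q$a + cand$a) / 2 + 20
        }, logical(1)))
        if (!clash) { plants[[i]] <- cand; placed <- TRUE; break }
      }
      if (!placed) {
        stop("could not place all plants without overlap; ",
             "reduce n_plants or corolla size", call. = FALSE)
      }
    }

    corollas <- list(); stems <- list()
    truth <- vector("list", length(plants))
    for (i in seq_along(plants)) {
      q <- plants[[i]]
      th <- q$tilt * pi / 180
      e <- ellipse(q$cx, q$cy, q$a, q$b, q$tilt)
      cmask <- as_mask_matrix(rasterize_ellipse(e, c(h, w)))

      # calyx: boundary point of the (unscaled) corolla in the downward
      # direction, with a little angular jitter
      phi <- (90 + q$attach_jitter) * pi / 180
      r0 <- ellipse_radius(q$a, q$b, th, phi)
      x0 <- q$cx + r0 * cos(phi)
      y0 <- q$cy + r0 * sin(phi)

      # quadratic Bezier centreline from the calyx downwards
      lean <- q$lean * pi / 180
      x2 <- x0 + q$stem_length * sin(lean)
      y2 <- min(y0 + q$stem_length * cos(lean), h - 2)
      nx <- cos(lean); ny <- -sin(lean)   # unit normal to the descent
      xm <- (x0 + x2) / 2 + q$bow * q$stem_length * nx
      ym <- (y0 + y2) / 2 + q$bow * q$stem_length * ny
      tt <- seq(0, 1, length.out = max(64L, ceiling(2 * q$stem_length)))
      bx <- (1 - tt)^2 * x0 + 2 * tt * (1 - tt) * xm + tt^2 * x2
      by <- (1 - tt)^2 * y0 + 2 * tt * (1 - tt) * ym + tt^2 * y2
      arc <- c(0, cumsum(sqrt(diff(bx)^2 + diff(by)^2)))

      keep <- rep(TRUE, length(tt))
      if (params$occlusion_gap > 0) {
        gap_start <- stats::runif(1L, 3, max(4, 0.35 * max(arc)))
        keep <- arc < gap_start | arc >= gap_start + params$occlusion_gap
      }
      smask <- matrix(0L, h, w)
      smask <- paint_tube(smask, bx[keep], by[keep], q$stem_width)

      if (params$speckle_density > 0) {
        n_spk <- round(params$speckle_density * h * w)
        cmask[sample.int(h * w, n_spk)] <- 1L
        smask[sample.int(h * w, n_spk)] <- 1L
      }
      corollas[[i]] <- binary_mask(cmask)
      stems[[i]] <- binary_mask(smask)
      truth[[i]] <- tibble::tibble(
        plant_id = i, calyx_x = x0, calyx_y = y0,
        corolla_a = q$a, corolla_b = q$b, corolla_tilt_deg = q$tilt,
        center_x = q$cx, center_y = q$cy,
        stem_width = q$stem_width, stem_length = q$stem_length
      )
    }
    list(
      seg = segmentation_result(c(h, w), corollas, stems),
      truth = dplyr::bind_rows(truth)
    )
  })
}

#' Write a synthetic dataset to disk
#'
#' Emits, per scene, one PNG per instance mask, one YOLO-segmentation label
#' file, and appends the scene's ground truth to a CSV manifest. Scene `i`
#' uses seed `params$seed + i - 1`, so datasets are reproducible and
#' order-independent.
#'
#' @param n_scenes number of scenes.
#' @param params a [scene_params()]; its `seed` is the base seed.
#' @param out_dir writable output directory (created if missing).
#' @return the manifest tibble, invisibly; also written as `manifest.csv`.
#' @export
generate_dataset <- function(n_scenes, params = scene_params(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    p_i <- params
    p_i$seed <- params$seed + i - 1L
    sc <- tryCatch(generate_scene(p_i), error = function(e) {
      stop(sprintf("scene %d: %s", i, conditionMessage(e)), call. = FALSE)
    })
    stub <- sprintf("scene%04d", i)
    for (j in seq_along(sc$seg$corolla_instances)) {
      write_mask_png(sc$seg$corolla_instances[[j]],
                     file.path(out_dir, sprintf("%s_c0_i%02d.png", stub, j)))
    }
    for (j in seq_along(sc$seg$stem_instances)) {
      write_mask_png(sc$seg$stem_instances[[j]],
                     file.path(out_dir, sprintf("%s_c1_i%02d.png", stub, j)))
    }
    write_yolo_seg_labels(sc$seg, file.path(out_dir, paste0(stub, ".txt")))
    manifest[[i]] <- dplyr::mutate(sc$truth, scene = i, stub = stub,
                                   .before = 1L)
  }
  manifest <- dplyr::bind_rows(manifest)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
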