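#' Intersect a skeleton with an ellipse mask
#'
#' Returns every pixel that is foreground in both rasters, in row-major
#' order (top row first, left to right).
#'
#' @param skel a `skeleton` or binary mask.
#' @param ellipse_mask a [binary_mask()] of the same shape.
#' @return two-column `(x, y)` matrix, 0-based; zero rows when disjoint.
#' @export
intersect_masks <- function(skel, ellipse_mask) {
  sm <- as_mask_matrix(if (inherits(skel, "skeleton")) skel$mask else skel)
  em <- as_mask_matrix(ellipse_mask)
  if (!all(dim(sm) == dim(em))) {
    stop("skeleton and ellipse mask shapes differ", call. = FALSE)
  }
  h <- nrow(sm)
  idx <- which(sm == 1L & em == 1L)
  xy <- cbind(x = (idx - 1L) %/% h, y = (idx - 1L) %% h)
  # row-major: top row first, then left to right
  xy[order(xy[, "y"], xy[, "x"]), , drop = FALSE]
}

#' Select the picking point among intersection candidates
#'
#' The uppermost candidate (minimum y in image coordinates) wins; ties are
#' broken by distance to the ellipse centre, then by minimum x. `NULL` is
#' returned for an empty candidate set.
#'
#' @param candidates two-column `(x, y)` matrix.
#' @param center optional `(x, y)` used for the distance tie-break.
#' @return a named numeric `(x, y)` vector or `NULL`.
#' @export
select_point <- function(candidates, center = NULL) {
  if (is.null(candidates) || nrow(candidates) == 0L) return(NULL)
  y <- candidates[, 2L]
  top <- candidates[y == min(y), , drop = FALSE]
  if (nrow(top) > 1L && !is.null(center)) {
    d2 <- (top[, 1L] - center[1L])^2 + (top[, 2L] - center[2L])^2
    top <- top[d2 == min(d2), , drop = FALSE]
  }
  if (nrow(top) > 1L) top <- top[which.min(top[, 1L]), , drop = FALSE]
  c(x = as.numeric(top[1L, 1L]), y = as.numeric(top[1L, 2L]))
}

pp_row <- function(instance_id, x = NA_real_, y = NA_real_,
                   status, used_fallback = FALSE) {
  tibble::tibble(
    instance_id = as.integer(instance_id),
    x = x, y = y, status = status, used_fallback = used_fallback
  )
}

#' Locate the picking point for one corolla / stem pair
#'
#' Runs the full geometric chain: fit an ellipse to the corolla mask, build
#' the optimized picking ellipse (fixed inclination, scaled minor axis),
#' clean / thin / prune the stem into a skeleton, intersect the rasterized
#' ellipse with the skeleton and pick the uppermost pixel. When the first
#' pass finds no intersection the ellipse is rotated once by the fallback
#' angle (90 degrees by default) and the comparison repeated; a point found
#' only then is flagged `used_fallback`. All failure modes are encoded in
#' `status`: `no_corolla`, `no_stem`, `no_intersection` or `found`.
#'
#' @param corolla,stem [binary_mask()] rasters of identical shape.
#' @param cfg a [pipeline_config()].
#' @param instance_id identifier copied into the result row.
#' @return a one-row tibble: `instance_id`, `x`, `y`, `status`,
#'   `used_fallback`.
#' @export
locate_picking_point <- function(corolla, stem, cfg = pipeline_config(),
                                 instance_id = 1L) {
  cm <- as_mask_matrix(corolla)
  sm <- as_mask_matrix(stem)
  if (!all(dim(cm) == dim(sm))) {
    stop("corolla and stem mask shapes differ", call. = FALSE)
  }
  if (sum(cm) == 0L) return(pp_row(instance_id, status = "no_corolla"))
  if (sum(sm) == 0L) return(pp_row(instance_id, status = "no_stem"))
  contour <- largest_contour(cm)
  if (nrow(contour) < cfg$min_contour_points) {
    return(pp_row(instance_id, status = "no_corolla"))
  }
  fitted <- tryCatch(
    fit_ellipse(contour, cfg$min_contour_points),
    error = function(e) NULL
  )
  if (is.null(fitted)) return(pp_row(instance_id, status = "no_corolla"))
  pick <- make_picking_ellipse(fitted, cfg)

  skel <- prune_skeleton(
    zhang_suen_thin(clean_mask(sm, cfg$morph_kernel)),
    cfg$prune_min_len
  )
  if (sum(skel$mask) == 0L) return(pp_row(instance_id, status = "no_stem"))

  for (attempt in c(FALSE, TRUE)) {
    e <- if (attempt) rotate_ellipse(pick, cfg$fallback_rotation_deg) else pick
    emask <- rasterize_ellipse(e, dim(cm), fill = cfg$ellipse_fill)
    pt <- select_point(intersect_masks(skel, emask),
                       center = c(e$center_x, e$center_y))
    if (!is.null(pt)) {
      return(pp_row(instance_id, pt["x"], pt["y"], "found",
                    used_fallback = attempt))
    }
  }
  pp_row(instance_id, status = "no_intersection")
}

# topmost foreground pixel of a mask as (x, y); NULL when empty
topmost_pixel <- function(mask) {
  m <- as_mask_matrix(mask)
  idx <- which(m == 1L)
  if (length(idx) == 0L) return(NULL)
  ys <- (idx - 1L) %% nrow(m)
  xs <- (idx - 1L) %/% nrow(m)
  k <- order(ys, xs)[1L]
  c(x = xs[k], y = ys[k])
}

mask_centroid <- function(mask) {
  m <- as_mask_matrix(mask)
  idx <- which(m == 1L)
  c(
    x = mean((idx - 1L) %/% nrow(m)),
    y = mean((idx - 1L) %% nrow(m))
  )
}

#' Process every corolla instance of a segmentation result
#'
#' Corollas are paired greedily with stems: over all (corolla, stem) pairs,
#' the pair with the smallest distance from the corolla centroid to the
#' stem's topmost foreground pixel is fixed first, then the next among the
#' remaining instances, and so on. Unpaired corollas report `no_stem`. One
#' row is produced per corolla instance, ordered by `instance_id`.
#'
#' @param seg a [segmentation_result()].
#' @param cfg a [pipeline_config()].
#' @return a tibble with one [locate_picking_point()] row per corolla.
#' @export
process_image <- function(seg, cfg = pipeline_config()) {
  nc <- length(seg$corolla_instances)
  ns <- length(seg$stem_instances)
  if (nc == 0L) {
    return(pp_row(integer(0), numeric(0), numeric(0),
                  character(0), logical(0)))
  }
  pairing <- rep(NA_integer_, nc)
  if (ns > 0L) {
    cents <- lapply(seg$corolla_instances, function(m) {
      if (sum(as_mask_matrix(m)) == 0L) NULL else mask_centroid(m)
    })
    tops <- lapply(seg$stem_instances, topmost_pixel)
    pairs <- expand.grid(ci = seq_len(nc), si = seq_len(ns))
    pairs$d <- mapply(function(ci, si) {
      if (is.null(cents[[ci]]) || is.null(tops[[si]])) return(Inf)
      sqrt(sum((cents[[ci]] - tops[[si]])^2))
    }, pairs$ci, pairs$si)
    pairs <- pairs[is.finite(pairs$d), , drop = FALSE]
    pairs <- pairs[order(pairs$d), , drop = FALSE]
    used_stem <- logical(ns)
    for (k in seq_len(nrow(pairs))) {
      ci <- pairs$ci[k]; si <- pairs$si[k]
      if (is.na(pairing[ci]) && !used_stem[si]) {
        pairing[ci] <- si
        used_stem[si] <- TRUE
      }
    }
  }
  rows <- lapply(seq_len(nc), function(ci) {
    if (is.na(pairing[ci])) {
      if (sum(as_mask_matrix(seg$corolla_instances[[ci]])) == 0L) {
        pp_row(ci, status = "no_corolla")
      } else {
        pp_row(ci, status = "no_stem")
      }
    } else {
      locate_picking_point(
        seg$corolla_instances[[ci]],
        seg$stem_instances[[pairing[ci]]],
        cfg, instance_id = ci
      )
    }
  })
  dplyr::bind_rows(rows)
}
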