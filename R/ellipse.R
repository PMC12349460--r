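#' Ellipse record
#'
#' Centre, semi-axes and orientation of the corolla picking region. The
#' angle is measured in degrees counter-clockwise from the +x (rightward)
#' image axis and normalized to `[0, 180)`; `semi_major >= semi_minor > 0`
#' is enforced, swapping axes (and rotating the angle by 90 degrees) when
#' needed.
#'
#' @param center_x,center_y centre in 0-based pixel coordinates.
#' @param semi_major,semi_minor semi-axes in pixels.
#' @param angle_deg major-axis orientation in degrees.
#' @return an object of class `ellipse`.
#' @export
ellipse <- function(center_x, center_y, semi_major, semi_minor, angle_deg) {
  if (!is.finite(semi_major) || !is.finite(semi_minor) ||
      semi_major <= 0 || semi_minor <= 0) {
    stop("semi-axes must be positive and finite", call. = FALSE)
  }
  if (semi_minor > semi_major) {
    tmp <- semi_major; semi_major <- semi_minor; semi_minor <- tmp
    angle_deg <- angle_deg + 90
  }
  structure(
    list(
      center_x = as.numeric(center_x), center_y = as.numeric(center_y),
      semi_major = as.numeric(semi_major), semi_minor = as.numeric(semi_minor),
      angle_deg = as.numeric(angle_deg) %% 180
    ),
    class = "ellipse"
  )
}

#' @export
print.ellipse <- function(x, ...) {
  cat(sprintf(
    "<ellipse> centre (%.2f, %.2f), a = %.2f, b = %.2f, angle = %.2f deg\n",
    x$center_x, x$center_y, x$semi_major, x$semi_minor, x$angle_deg
  ))
  invisible(x)
}

#' Pipeline configuration
#'
#' Thresholds and angles of the picking-point pipeline. Defaults encode the
#' method's operating point: a fixed 30-degree picking inclination, a 1.4
#' safety scaling of the minor axis, a single 90-degree fallback rotation,
#' 3-pixel morphological cleaning, and pruning of skeleton branches shorter
#' than 10 pixels.
#'
#' @param initial_angle_deg picking-ellipse inclination in degrees.
#' @param fallback_rotation_deg rotation applied when the first intersection
#'   pass is empty; must lie strictly inside `(0, 180)`.
#' @param minor_scale multiplicative safety margin on the fitted minor axis.
#' @param prune_min_len minimum retained skeleton branch length, pixels.
#' @param morph_kernel odd side length of the square structuring element.
#' @param min_contour_points minimum boundary points for an ellipse fit.
#' @param match_radius tolerance radius used by the evaluation metrics.
#' @param ellipse_fill `"filled"` intersects the filled picking ellipse with
#'   the skeleton, `"outline"` only its one-pixel boundary ring.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(initial_angle_deg = 30,
                            fallback_rotation_deg = 90,
                            minor_scale = 1.4,
                            prune_min_len = 10,
                            morph_kernel = 3,
                            min_contour_points = 5,
                            match_radius = 10,
                            ellipse_fill = c("filled", "outline")) {
  stopifnot(
    minor_scale > 0, prune_min_len >= 0,
    fallback_rotation_deg > 0, fallback_rotation_deg < 180,
    morph_kernel >= 1, morph_kernel %% 2 == 1,
    min_contour_points >= 5, match_radius >= 0
  )
  structure(
    list(
      initial_angle_deg = initial_angle_deg,
      fallback_rotation_deg = fallback_rotation_deg,
      minor_scale = minor_scale,
      prune_min_len = prune_min_len,
      morph_kernel = morph_kernel,
      min_contour_points = min_contour_points,
      match_radius = match_radius,
      ellipse_fill = match.arg(ellipse_fill)
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path YAML file with [pipeline_config()] keys.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Fit an ellipse to boundary points
#'
#' Direct least-squares conic fit with the ellipse constraint
#' (Fitzgibbon's method in the numerically stable Halir-Flusser
#' formulation), minimizing algebraic distance to the contour. A
#' second-moments fallback covers conics that the direct fit cannot resolve
#' as an ellipse; genuinely degenerate (collinear) input is an error.
#'
#' @param contour two-column matrix of `(x, y)` points.
#' @param min_contour_points minimum number of points required.
#' @param boundary_margin added to both fitted semi-axes before returning.
#'   Contours traced on rasters run through boundary-pixel centres, which sit
#'   about half a pixel inside the underlying region; the default half-pixel
#'   margin makes fit-then-rasterize reproduce the region without a
#'   systematic one-ring shrink. Set to 0 for contours of exact
#'   (sub-pixel) boundary points.
#' @return an [ellipse()].
#' @export
fit_ellipse <- function(contour, min_contour_points = 5,
                        boundary_margin = 0.5) {
  contour <- as.matrix(contour)
  if (nrow(contour) < min_contour_points) {
    stop(sprintf("ellipse fit needs at least %d points", min_contour_points),
         call. = FALSE)
  }
  x <- contour[, 1L]; y <- contour[, 2L]
  # centre and scale for conditioning
  mx <- mean(x); my <- mean(y)
  sx <- x - mx; sy <- y - my
  sc <- max(stats::sd(sx), stats::sd(sy), .Machine$double.eps)
  if (qr(cbind(sx, sy))$rank < 2L) {
    stop("degenerate fit: contour points are collinear", call. = FALSE)
  }
  sx <- sx / sc; sy <- sy / sc
  D1 <- cbind(sx^2, sx * sy, sy^2)
  D2 <- cbind(sx, sy, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  sol <- tryCatch({
    Tmat <- -solve(S3, t(S2))
    M <- S1 + S2 %*% Tmat
    # premultiply by inv(C) for constraint 4AC - B^2 = 1
    M <- rbind(M[3L, ] / 2, -M[2L, ], M[1L, ] / 2)
    ev <- eigen(M)
    V <- Re(ev$vectors)
    cond <- 4 * V[1L, ] * V[3L, ] - V[2L, ]^2
    k <- which(cond > 0)
    if (length(k) == 0L) NULL else {
      a1 <- V[, k[1L]]
      c(a1, Tmat %*% a1)
    }
  }, error = function(e) NULL)
  if (!is.null(sol)) {
    e <- conic_to_ellipse(sol)
    if (!is.null(e)) {
      return(ellipse(e$cx * sc + mx, e$cy * sc + my,
                     e$a * sc + boundary_margin,
                     e$b * sc + boundary_margin, e$angle))
    }
  }
  m <- moments_ellipse(x, y)
  ellipse(m$center_x, m$center_y, m$semi_major + boundary_margin,
          m$semi_minor + boundary_margin, m$angle_deg)
}

# general conic (A,B,C,D,E,F) -> geometric parameters, NULL if not an ellipse
conic_to_ellipse <- function(p) {
  A <- p[1L]; B <- p[2L]; C <- p[3L]; D <- p[4L]; E <- p[5L]; FF <- p[6L]
  disc <- B^2 - 4 * A * C
  if (!is.finite(disc) || disc >= 0) return(NULL)
  cx <- (2 * C * D - B * E) / disc
  cy <- (2 * A * E - B * D) / disc
  # constant term of the conic re-expressed at its centre
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + FF
  lam <- eigen(matrix(c(A, B / 2, B / 2, C), 2L, 2L), symmetric = TRUE)
  ax2 <- -Fc / lam$values
  if (any(!is.finite(ax2) | ax2 <= 0)) return(NULL)
  axes <- sqrt(ax2)
  # the overall sign of the fitted conic is arbitrary, so associate each
  # semi-axis with its own eigenvector rather than with the eigenvalue order
  k <- which.max(axes)
  vmaj <- lam$vectors[, k]
  list(cx = cx, cy = cy, a = axes[k], b = min(axes),
       angle = atan2(vmaj[2L], vmaj[1L]) * 180 / pi)
}

# covariance-based ellipse of a point cloud (uniform-boundary scaling)
moments_ellipse <- function(x, y) {
  cx <- mean(x); cy <- mean(y)
  cv <- stats::cov(cbind(x - cx, y - cy))
  ev <- eigen(cv, symmetric = TRUE)
  if (any(ev$values <= 0)) {
    stop("degenerate fit: contour has no area", call. = FALSE)
  }
  # boundary points of an ellipse have second moments a^2/2, b^2/2
  a <- sqrt(2 * max(ev$values)); b <- sqrt(2 * min(ev$values))
  vmaj <- ev$vectors[, which.max(ev$values)]
  ellipse(cx, cy, a, b, atan2(vmaj[2L], vmaj[1L]) * 180 / pi)
}

#' Build the optimized picking ellipse
#'
#' Keeps the fitted centre and major axis, multiplies the minor axis by the
#' safety factor and forces the fixed picking inclination. If scaling makes
#' the minor axis exceed the major one the axes are swapped (with a
#' 90-degree angle correction) to preserve the `a >= b` invariant.
#'
#' @param fitted an [ellipse()] from [fit_ellipse()].
#' @param cfg a [pipeline_config()].
#' @export
make_picking_ellipse <- function(fitted, cfg = pipeline_config()) {
  ellipse(
    fitted$center_x, fitted$center_y,
    fitted$semi_major, fitted$semi_minor * cfg$minor_scale,
    cfg$initial_angle_deg
  )
}

#' Rotate an ellipse in place
#'
#' Adds `delta_deg` to the orientation modulo 180 degrees; nothing else
#' changes.
#'
#' @param e an [ellipse()].
#' @param delta_deg rotation in degrees.
#' @export
rotate_ellipse <- function(e, delta_deg) {
  ellipse(e$center_x, e$center_y, e$semi_major, e$semi_minor,
          e$angle_deg + delta_deg)
}

#' Rasterize an ellipse into a mask
#'
#' Pixel `(x, y)` is foreground when its centre satisfies the rotated
#' ellipse inequality
#' \deqn{((x-c_x)\cos\theta + (y-c_y)\sin\theta)^2/a^2 +
#'       (-(x-c_x)\sin\theta + (y-c_y)\cos\theta)^2/b^2 \le 1.}
#' An ellipse lying outside the frame yields an empty mask. With
#' `fill = "outline"` only the one-pixel boundary ring (filled ellipse minus
#' its erosion) is kept.
#'
#' @param e an [ellipse()].
#' @param shape integer `(height, width)`.
#' @param fill `"filled"` or `"outline"`.
#' @return a [binary_mask()].
#' @export
rasterize_ellipse <- function(e, shape, fill = c("filled", "outline")) {
  fill <- match.arg(fill)
  h <- as.integer(shape[1L]); w <- as.integer(shape[2L])
  stopifnot(h >= 1L, w >= 1L)
  th <- e$angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  xs <- matrix(rep(0:(w - 1L), each = h), h, w) - e$center_x
  ys <- matrix(rep(0:(h - 1L), times = w), h, w) - e$center_y
  u <- (xs * ct + ys * st) / e$semi_major
  v <- (-xs * st + ys * ct) / e$semi_minor
  m <- binary_mask(matrix(as.integer(u * u + v * v <= 1), h, w))
  if (fill == "outline" && sum(m) > 0L) {
    inner <- EBImage::erode(as_mask_matrix(m), EBImage::makeBrush(3L, "box"))
    m <- binary_mask(as_mask_matrix(m) - (as_mask_matrix(m) & inner))
  }
  m
}
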