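#' Morphological cleaning of a mask
#'
#' One opening (erosion then dilation) followed by one closing (dilation
#' then erosion) with a `kernel` x `kernel` square structuring element.
#' Opening removes speckle smaller than the kernel, closing fills holes of
#' the same scale.
#'
#' @inheritParams mask_shape
#' @param kernel odd structuring-element side length, pixels.
#' @return a [binary_mask()].
#' @export
clean_mask <- function(mask, kernel = 3) {
  stopifnot(kernel >= 1, kernel %% 2 == 1)
  m <- as_mask_matrix(mask)
  if (kernel == 1L) return(binary_mask(m))
  kern <- EBImage::makeBrush(as.integer(kernel), shape = "box")
  opened <- EBImage::dilate(EBImage::erode(m, kern), kern)
  closed <- EBImage::erode(EBImage::dilate(opened, kern), kern)
  binary_mask(matrix(as.integer(closed > 0), nrow(m), ncol(m)))
}

# shift a matrix by (dr, dc), zero-padding the border
shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# the eight neighbours in Zhang-Suen order P2..P9
# (N, NE, E, SE, S, SW, W, NW) for pixel-centre coordinates with y downwards
zs_neighbours <- function(m) {
  list(
    p2 = shift_mat(m, 1L, 0L),   # value of the pixel above lands on centre
    p3 = shift_mat(m, 1L, -1L),
    p4 = shift_mat(m, 0L, -1L),
    p5 = shift_mat(m, -1L, -1L),
    p6 = shift_mat(m, -1L, 0L),
    p7 = shift_mat(m, -1L, 1L),
    p8 = shift_mat(m, 0L, 1L),
    p9 = shift_mat(m, 1L, 1L)
  )
}

zs_subpass <- function(m, pass) {
  nb <- zs_neighbours(m)
  B <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
  ring <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
  A <- matrix(0L, nrow(m), ncol(m))
  for (k in 1:8) A <- A + as.integer(ring[[k]] == 0L & ring[[k + 1L]] == 1L)
  if (pass == 1L) {
    c1 <- nb$p2 * nb$p4 * nb$p6
    c2 <- nb$p4 * nb$p6 * nb$p8
  } else {
    c1 <- nb$p2 * nb$p4 * nb$p8
    c2 <- nb$p2 * nb$p6 * nb$p8
  }
  del <- m == 1L & B >= 2L & B <= 6L & A == 1L & c1 == 0L & c2 == 0L
  m[del] <- 0L
  m
}

#' Zhang-Suen thinning
#'
#' Iterates the two Zhang-Suen sub-passes (neighbour count `B(p)` in
#' `[2, 6]`, exactly one 0-to-1 transition around the pixel, and the two
#' edge-deletion templates) with simultaneous deletion inside each sub-pass,
#' until a full iteration changes nothing. The result is a 1-pixel-wide,
#' 8-connected skeleton with classified endpoints and junctions.
#'
#' @inheritParams mask_shape
#' @return an object of class `skeleton`: a list with elements `mask`
#'   (a [binary_mask()]), `endpoints` and `junctions` (two-column `(x, y)`
#'   matrices, 0-based).
#' @export
zhang_suen_thin <- function(mask) {
  m <- as_mask_matrix(mask)
  # thinning is a local operation: restricting to the foreground bounding
  # box (plus a one-pixel zero margin) is exact and much faster
  fg <- which(m == 1L)
  if (length(fg) > 0L) {
    rs <- range((fg - 1L) %% nrow(m) + 1L)
    cs <- range((fg - 1L) %/% nrow(m) + 1L)
    r0 <- max(1L, rs[1L] - 1L); r1 <- min(nrow(m), rs[2L] + 1L)
    c0 <- max(1L, cs[1L] - 1L); c1 <- min(ncol(m), cs[2L] + 1L)
    sub <- m[r0:r1, c0:c1, drop = FALSE]
    repeat {
      before <- sub
      sub <- zs_subpass(sub, 1L)
      sub <- zs_subpass(sub, 2L)
      if (identical(sub, before)) break
    }
    m[r0:r1, c0:c1] <- sub
  }
  new_skeleton(binary_mask(m))
}

new_skeleton <- function(mask) {
  cls <- classify_skeleton_pixels(mask)
  structure(
    list(mask = mask, endpoints = cls$endpoints, junctions = cls$junctions),
    class = "skeleton"
  )
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf(
    "<skeleton> %d pixel(s), %d endpoint(s), %d junction(s)\n",
    sum(x$mask), nrow(x$endpoints), nrow(x$junctions)
  ))
  invisible(x)
}

# count of foreground 8-neighbours for every pixel
neighbour_counts <- function(m) {
  nb <- zs_neighbours(m)
  nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
}

#' Classify skeleton pixels
#'
#' Endpoints have exactly one foreground 8-neighbour; junctions have three
#' or more.
#'
#' @inheritParams mask_shape
#' @return a list with `(x, y)` matrices `endpoints` and `junctions`
#'   (0-based coordinates).
#' @export
classify_skeleton_pixels <- function(mask) {
  m <- as_mask_matrix(mask)
  cnt <- neighbour_counts(m)
  to_xy <- function(idx) {
    cbind(x = (idx - 1L) %/% nrow(m), y = (idx - 1L) %% nrow(m))
  }
  list(
    endpoints = to_xy(which(m == 1L & cnt == 1L)),
    junctions = to_xy(which(m == 1L & cnt >= 3L))
  )
}

# 8-neighbour indices of linear index idx within a h x w matrix
lin_neighbours <- function(idx, h, w) {
  r <- (idx - 1L) %% h + 1L
  c <- (idx - 1L) %/% h + 1L
  out <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    rr <- r + dr; cc <- c + dc
    if (rr >= 1L && rr <= h && cc >= 1L && cc <= w) {
      out <- c(out, (cc - 1L) * h + rr)
    }
  }
  out
}

# crossing number: 0 -> 1 transitions around each pixel, i.e. the number of
# distinct branches emanating from it. Robust junction test for pruning:
# Zhang-Suen staircase corners have >= 3 neighbours but a crossing number
# of 2 and must not be mistaken for branch points.
crossing_number <- function(m) {
  nb <- zs_neighbours(m)
  ring <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
  A <- matrix(0L, nrow(m), ncol(m))
  for (k in 1:8) A <- A + as.integer(ring[[k]] == 0L & ring[[k + 1L]] == 1L)
  A
}

#' Prune a skeleton
#'
#' Two-step cleanup of a thinned skeleton, repeated to stability:
#' branches - every geodesic path from an endpoint to its nearest branch
#' point containing fewer than `min_len` pixels (endpoint inclusive, branch
#' point exclusive) is deleted, the branch point itself retained;
#' fragments - 8-connected components with fewer than `min_len` pixels are
#' removed, unless that would empty the skeleton entirely, in which case
#' the largest component survives. A final thinning pass restores the
#' 1-pixel-width invariant where branch removal exposed junction pixels.
#'
#' Branch points are detected by crossing number (the count of distinct
#' branches around a pixel) rather than by raw neighbour count: thinning
#' leaves staircase corners with three neighbours but only two branches,
#' and treating those as junctions would truncate every path at its first
#' corner.
#'
#' @param skel a `skeleton` (or mask coercible to one).
#' @param min_len minimum branch / component size in pixels.
#' @return a `skeleton`.
#' @export
prune_skeleton <- function(skel, min_len = 10) {
  m <- as_mask_matrix(if (inherits(skel, "skeleton")) skel$mask else skel)
  if (min_len <= 0) return(new_skeleton(binary_mask(m)))
  h <- nrow(m); w <- ncol(m)
  repeat {
    cnt <- neighbour_counts(m)
    branchy <- crossing_number(m) >= 3L
    eps <- which(m == 1L & cnt == 1L)
    removed_any <- FALSE
    for (ep in eps) {
      if (m[ep] == 0L) next
      # walk from the endpoint towards the skeleton interior
      path <- ep
      cur <- ep
      hit_junction <- FALSE
      while (length(path) < min_len) {
        nbr <- lin_neighbours(cur, h, w)
        nbr <- nbr[m[nbr] == 1L & !(nbr %in% path)]
        if (length(nbr) == 0L) break           # isolated path, not a branch
        if (any(branchy[nbr])) { hit_junction <- TRUE; break }
        # at a staircase corner both continuations are mutually adjacent;
        # either one extends the same path
        cur <- nbr[1L]
        path <- c(path, cur)
      }
      if (hit_junction && length(path) < min_len) {
        m[path] <- 0L
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  # drop undersized fragments, but never empty the skeleton
  lab <- label_components(m)
  ncomp <- max(lab)
  if (ncomp > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
    keep <- which(sizes >= min_len)
    if (length(keep) == 0L) keep <- which.max(sizes)
    m[!(lab %in% keep)] <- 0L
  }
  # branch removal can leave ex-junction pixels deletable by a further pass
  zhang_suen_thin(binary_mask(m))
}
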