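#' Binary mask
#'
#' The elementary raster of the pipeline: an integer matrix of 0/1 values with
#' the origin at the top-left corner. Rows index the y axis (downwards) and
#' columns the x axis (rightwards). All point coordinates exposed by the
#' package are 0-based, so the pixel at coordinate `(x, y)` lives at
#' `data[y + 1, x + 1]` and addresses the centre of a unit pixel square.
#'
#' @param data numeric or logical matrix; any non-zero entry becomes
#'   foreground (1).
#' @return an integer matrix of class `binary_mask`.
#' @examples
#' m <- binary_mask(matrix(c(0, 1, 1, 0), 2, 2))
#' mask_shape(m)
#' @export
binary_mask <- function(data) {
  if (!is.matrix(data) || nrow(data) < 1L || ncol(data) < 1L) {
    stop("`data` must be a non-empty matrix", call. = FALSE)
  }
  if (anyNA(data)) stop("mask values must not be NA", call. = FALSE)
  m <- matrix(as.integer(data != 0), nrow(data), ncol(data))
  class(m) <- c("binary_mask", class(m))
  m
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf(
    "<binary_mask> %d x %d (h x w), %d foreground pixel(s)\n",
    nrow(x), ncol(x), sum(x)
  ))
  invisible(x)
}

#' @rdname binary_mask
#' @param mask a `binary_mask` or plain 0/1 matrix.
#' @export
mask_shape <- function(mask) c(height = nrow(mask), width = ncol(mask))

# strip the class so arithmetic stays on plain integer matrices
as_mask_matrix <- function(mask) {
  if (!is.matrix(mask)) stop("expected a matrix mask", call. = FALSE)
  matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
}

#' Segmentation result
#'
#' Container pairing the corolla (class 0) and stem (class 1) instance masks
#' of one image. Every instance mask must share the frame's shape.
#'
#' @param image_shape integer `(height, width)` in pixels.
#' @param corolla_instances,stem_instances lists of [binary_mask()] rasters.
#' @return an object of class `segmentation_result`.
#' @export
segmentation_result <- function(image_shape,
                                corolla_instances = list(),
                                stem_instances = list()) {
  image_shape <- as.integer(image_shape)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 1L))
  check <- function(m) {
    if (!all(dim(m) == image_shape)) {
      stop("instance mask shape differs from `image_shape`", call. = FALSE)
    }
    binary_mask(m)
  }
  structure(
    list(
      image_shape = image_shape,
      corolla_instances = lapply(corolla_instances, check),
      stem_instances = lapply(stem_instances, check)
    ),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> %d x %d: %d corolla, %d stem instance(s)\n",
    x$image_shape[1], x$image_shape[2],
    length(x$corolla_instances), length(x$stem_instances)
  ))
  invisible(x)
}

#' Label 8-connected foreground components
#'
#' Breadth-first labelling over the 8-neighbourhood. Returns an integer matrix
#' of the mask's shape where 0 is background and components are numbered from
#' 1 in scan order of their first pixel.
#'
#' @inheritParams mask_shape
#' @return integer label matrix.
#' @export
label_components <- function(mask) {
  m <- as_mask_matrix(mask)
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  fg <- which(m == 1L)
  if (length(fg) == 0L) return(lab)
  cur <- 0L
  for (start in fg) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0L) {
      idx <- queue
      queue <- integer(0)
      r <- (idx - 1L) %% h + 1L
      c <- (idx - 1L) %/% h + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; cc <- c + dc
        ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
        if (!any(ok)) next
        nidx <- (cc[ok] - 1L) * h + rr[ok]
        nidx <- nidx[m[nidx] == 1L & lab[nidx] == 0L]
        if (length(nidx) > 0L) {
          nidx <- unique(nidx)
          lab[nidx] <- cur
          queue <- c(queue, nidx)
        }
      }
    }
  }
  lab
}

# largest component as a mask of the same shape; NULL if empty
largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(NULL)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  binary_mask(matrix(as.integer(lab == keep), nrow(lab), ncol(lab)))
}

#' Trace the external boundary of the largest foreground component
#'
#' Moore boundary tracing (8-connected, clockwise in image coordinates) of
#' the largest-area 8-connected component. The contour is returned closed in
#' the sense that consecutive points are 8-adjacent and the sequence wraps
#' around; each boundary pixel appears at least once.
#'
#' @inheritParams mask_shape
#' @return a two-column matrix of 0-based `(x, y)` boundary coordinates.
#' @export
largest_contour <- function(mask) {
  comp <- largest_component(mask)
  if (is.null(comp)) stop("mask has no foreground pixels", call. = FALSE)
  m <- as_mask_matrix(comp)
  h <- nrow(m); w <- ncol(m)
  fg <- which(m == 1L)
  if (length(fg) == 1L) {
    r <- (fg - 1L) %% h + 1L; c <- (fg - 1L) %/% h + 1L
    return(cbind(x = c - 1L, y = r - 1L))
  }
  # start at the first foreground pixel in scan order (top-most, then left-most)
  rs <- (fg - 1L) %% h + 1L
  cs <- (fg - 1L) %/% h + 1L
  ord <- order(rs, cs)
  r0 <- rs[ord[1L]]; c0 <- cs[ord[1L]]
  # clockwise Moore neighbourhood in (row, col) offsets starting from west
  nb <- rbind(
    c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
    c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L)
  )
  at <- function(r, c) r >= 1L && r <= h && c >= 1L && c <= w && m[r, c] == 1L
  contour <- matrix(integer(0), 0L, 2L)
  r <- r0; c <- c0
  # backtrack starts west of the start pixel (the scan came from there)
  dir <- 1L
  repeat {
    contour <- rbind(contour, c(r, c))
    found <- FALSE
    for (k in 0:7) {
      d <- (dir - 1L + k) %% 8L + 1L
      rr <- r + nb[d, 1L]; cc <- c + nb[d, 2L]
      if (at(rr, cc)) {
        # next search starts from the neighbour "behind" the move
        dir <- (d - 3L) %% 8L + 1L
        r <- rr; c <- cc
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel (cannot happen here)
    if (r == r0 && c == c0 && nrow(contour) > 2L) break
    if (nrow(contour) > 4L * (h * w)) break  # safety net
  }
  cbind(x = contour[, 2L] - 1L, y = contour[, 1L] - 1L)
}
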