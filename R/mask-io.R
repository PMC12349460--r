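#' Binarize a grayscale raster
#'
#' A pixel becomes foreground (1) exactly when its value is strictly greater
#' than `threshold`; the shape is preserved. The on-disk encoding is
#' irrelevant downstream: 0/255 images, 0/1 masks and probability maps all
#' normalise to the same internal 0/1 convention.
#'
#' @param raster numeric matrix (any value range).
#' @param threshold cut-off on the raster's own scale. The default 0.5 suits
#'   probability-like rasters in `[0, 1]`.
#' @return a [binary_mask()].
#' @examples
#' binarize(matrix(c(0, 255, 10, 200), 2, 2), threshold = 127)
#' @export
binarize <- function(raster, threshold = 0.5) {
  if (!is.matrix(raster) || length(raster) == 0L) {
    stop("`raster` must be a non-empty matrix", call. = FALSE)
  }
  binary_mask(matrix(as.integer(raster > threshold), nrow(raster), ncol(raster)))
}

# read a PNG as a grayscale matrix in [0,1], h x w
read_png_gray <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  arr
}

#' Load per-instance mask images
#'
#' Each file becomes one instance mask of its class; instance order follows
#' the input order. Class 0 is the corolla, class 1 the stem.
#'
#' @param paths character vector of PNG paths.
#' @param class_ids integer vector in `{0, 1}`, one per path.
#' @param threshold binarization threshold on the `[0, 1]` scale PNGs are
#'   read at.
#' @return a [segmentation_result()].
#' @export
load_mask_images <- function(paths, class_ids, threshold = 0.5) {
  stopifnot(length(paths) == length(class_ids))
  if (length(paths) == 0L) {
    stop("cannot infer the frame shape from an empty path list; ",
         "construct an empty segmentation_result() directly", call. = FALSE)
  }
  if (!all(class_ids %in% c(0L, 1L))) {
    stop("unknown class id: only 0 (corolla) and 1 (stem) exist", call. = FALSE)
  }
  rasters <- lapply(paths, read_png_gray)
  shp <- dim(rasters[[1L]])
  same <- vapply(rasters, function(r) all(dim(r) == shp), logical(1))
  if (!all(same)) stop("all mask images must share the same dimensions", call. = FALSE)
  masks <- lapply(rasters, binarize, threshold = threshold)
  segmentation_result(
    image_shape = shp,
    corolla_instances = masks[class_ids == 0L],
    stem_instances = masks[class_ids == 1L]
  )
}

#' Write a mask as an 8-bit grayscale PNG
#'
#' Foreground is written as 255, background as 0, so the file round-trips
#' through [load_mask_images()] bit-exactly.
#'
#' @inheritParams mask_shape
#' @param path output file.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(as_mask_matrix(mask) * 1.0, path)
  invisible(path)
}

#' Rasterize a polygon with the even-odd rule
#'
#' Scanline fill at pixel centres: pixel `(x, y)` (0-based, centre-addressed)
#' is foreground when the point `(x, y)` is inside the polygon under the
#' even-odd rule. Crossings are counted half-open in both axes (an edge spans
#' scanlines `[min(y), max(y))`, a span fills centres `[x_enter, x_exit)`),
#' so two polygons sharing an edge never double-fill a pixel.
#'
#' @param xs,ys polygon vertices in continuous 0-based pixel coordinates
#'   (not necessarily closed; the closing edge is implied).
#' @param shape integer `(height, width)`.
#' @return a [binary_mask()].
#' @export
fill_polygon_mask <- function(xs, ys, shape) {
  stopifnot(length(xs) == length(ys), length(xs) >= 3L)
  h <- as.integer(shape[1L]); w <- as.integer(shape[2L])
  m <- matrix(0L, h, w)
  n <- length(xs)
  x2 <- c(xs[-1L], xs[1L]); y2 <- c(ys[-1L], ys[1L])
  ylo <- pmin(ys, y2); yhi <- pmax(ys, y2)
  for (row in seq_len(h)) {
    y <- row - 1L
    active <- which(ylo <= y & y < yhi)   # horizontal edges drop out
    if (length(active) == 0L) next
    cx <- xs[active] + (y - ys[active]) * (x2[active] - xs[active]) /
      (y2[active] - ys[active])
    cx <- sort(cx)
    for (k in seq(1L, length(cx) - 1L, by = 2L)) {
      from <- ceiling(cx[k])
      to <- ceiling(cx[k + 1L]) - 1L      # half-open [enter, exit)
      if (to < from) next
      from <- max(from, 0L); to <- min(to, w - 1L)
      if (to >= from) m[row, (from:to) + 1L] <- 1L
    }
  }
  binary_mask(m)
}

parse_yolo_line <- function(line, lineno) {
  parts <- strsplit(trimws(line), "\\s+")[[1L]]
  vals <- suppressWarnings(as.numeric(parts))
  if (anyNA(vals) || length(vals) < 1L) {
    stop(sprintf("label line %d: not numeric", lineno), call. = FALSE)
  }
  cls <- vals[1L]
  coords <- vals[-1L]
  if (cls != round(cls) || !(cls %in% c(0, 1))) {
    stop(sprintf("label line %d: class id must be 0 or 1", lineno), call. = FALSE)
  }
  if (length(coords) %% 2L != 0L || length(coords) < 6L) {
    stop(sprintf(
      "label line %d: expected an even number (>= 6) of coordinates",
      lineno
    ), call. = FALSE)
  }
  if (any(coords < 0 | coords > 1)) {
    stop(sprintf("label line %d: coordinates outside [0, 1]", lineno), call. = FALSE)
  }
  list(class_id = as.integer(cls),
       x = coords[seq(1L, length(coords), 2L)],
       y = coords[seq(2L, length(coords), 2L)])
}

#' Load YOLO-segmentation polygon labels
#'
#' One object per line: a class index followed by normalized polygon vertices
#' `x1 y1 x2 y2 ...` in `[0, 1]`. Each polygon is scaled to the frame
#' (normalized coordinate times width or height, landing in continuous
#' centre-addressed pixel coordinates via an offset of one half pixel) and
#' rasterized with [fill_polygon_mask()] into one instance mask.
#'
#' @param label_file path to the label text file.
#' @param image_shape integer `(height, width)` of the target frame.
#' @return a [segmentation_result()].
#' @export
load_yolo_seg_labels <- function(label_file, image_shape) {
  h <- as.integer(image_shape[1L]); w <- as.integer(image_shape[2L])
  lines <- readLines(label_file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  corolla <- list(); stem <- list()
  for (i in seq_along(lines)) {
    p <- parse_yolo_line(lines[i], i)
    mask <- fill_polygon_mask(p$x * w - 0.5, p$y * h - 0.5, c(h, w))
    if (p$class_id == 0L) corolla[[length(corolla) + 1L]] <- mask
    else stem[[length(stem) + 1L]] <- mask
  }
  segmentation_result(c(h, w), corolla, stem)
}

# boundary polygon of a mask's largest component, pushed half a pixel outwards
# along the local normal so that an even-odd refill reproduces the region
outer_polygon <- function(mask) {
  ct <- largest_contour(mask)
  n <- nrow(ct)
  if (n < 3L) {
    # degenerate: wrap the pixel(s) in a small box
    x <- ct[1L, 1L]; y <- ct[1L, 2L]
    return(list(x = x + c(-0.45, 0.45, 0.45, -0.45),
                y = y + c(-0.45, -0.45, 0.45, 0.45)))
  }
  m <- as_mask_matrix(mask)
  h <- nrow(m); w <- ncol(m)
  prv <- ct[c(n, seq_len(n - 1L)), , drop = FALSE]
  nxt <- ct[c(seq_len(n)[-1L], 1L), , drop = FALSE]
  tx <- nxt[, 1L] - prv[, 1L]; ty <- nxt[, 2L] - prv[, 2L]
  len <- sqrt(tx^2 + ty^2); len[len == 0] <- 1
  nx <- ty / len; ny <- -tx / len
  # orient each normal away from the region
  px <- round(ct[, 1L] + nx); py <- round(ct[, 2L] + ny)
  inside <- px >= 0L & px < w & py >= 0L & py < h
  inside[inside] <- m[cbind(py[inside] + 1L, px[inside] + 1L)] == 1L
  nx[inside] <- -nx[inside]; ny[inside] <- -ny[inside]
  list(x = ct[, 1L] + 0.5 * nx, y = ct[, 2L] + 0.5 * ny)
}

#' Write YOLO-segmentation polygon labels
#'
#' Emits one line per instance (corollas first, class 0, then stems, class
#' 1), tracing each instance's outer boundary and normalizing to `[0, 1]`.
#' Reloading with [load_yolo_seg_labels()] reproduces fat regions exactly
#' and slender ones to within a one-pixel boundary band.
#'
#' @param seg a [segmentation_result()].
#' @param path output label file.
#' @param digits coordinate precision written to file.
#' @export
write_yolo_seg_labels <- function(seg, path, digits = 6L) {
  h <- seg$image_shape[1L]; w <- seg$image_shape[2L]
  fmt_line <- function(mask, cls) {
    poly <- outer_polygon(mask)
    xs <- pmin(pmax((poly$x + 0.5) / w, 0), 1)
    ys <- pmin(pmax((poly$y + 0.5) / h, 0), 1)
    paste(cls, paste(sprintf(paste0("%.", digits, "f"),
                             as.vector(rbind(xs, ys))), collapse = " "))
  }
  lines <- c(
    vapply(seg$corolla_instances, fmt_line, character(1), cls = 0L),
    vapply(seg$stem_instances, fmt_line, character(1), cls = 1L)
  )
  writeLines(lines, path)
  invisible(path)
}
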