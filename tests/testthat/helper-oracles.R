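# Independent reference implementations used as oracles. These deliberately
# share no code with the package: per-pixel loops and textbook formulations
# instead of the package's vectorized production paths.

# -- even-odd point-in-polygon (crossing number, PNPOLY formulation) --------

point_in_polygon_oracle <- function(px, py, xs, ys) {
  n <- length(xs)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py)) {
      xint <- xs[i] + (py - ys[i]) * (xs[j] - xs[i]) / (ys[j] - ys[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

fill_polygon_oracle <- function(xs, ys, shape) {
  m <- matrix(0L, shape[1L], shape[2L])
  for (row in seq_len(shape[1L])) {
    for (col in seq_len(shape[2L])) {
      if (point_in_polygon_oracle(col - 1L, row - 1L, xs, ys)) {
        m[row, col] <- 1L
      }
    }
  }
  m
}

random_convex_polygon <- function(max_vertices = 12L, frame = 64L) {
  repeat {
    pts <- cbind(
      stats::runif(max_vertices, 4, frame - 5),
      stats::runif(max_vertices, 4, frame - 5)
    )
    hull <- grDevices::chull(pts)
    if (length(hull) >= 3L) return(pts[hull, , drop = FALSE])
  }
}

# -- literal two-subpass Zhang-Suen transcription ---------------------------

zhang_suen_reference <- function(m) {
  h <- nrow(m); w <- ncol(m)
  val <- function(r, c) {
    if (r < 1L || r > h || c < 1L || c > w) 0L else m[r, c]
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      marks <- matrix(FALSE, h, w)
      for (r in seq_len(h)) {
        for (c in seq_len(w)) {
          if (m[r, c] != 1L) next
          # P2..P9 clockwise starting north
          p <- c(
            val(r - 1L, c), val(r - 1L, c + 1L), val(r, c + 1L),
            val(r + 1L, c + 1L), val(r + 1L, c), val(r + 1L, c - 1L),
            val(r, c - 1L), val(r - 1L, c - 1L)
          )
          B <- sum(p)
          if (B < 2L || B > 6L) next
          ring <- c(p, p[1L])
          A <- sum(ring[-9L] == 0L & ring[-1L] == 1L)
          if (A != 1L) next
          if (pass == 1L) {
            if (p[1L] * p[3L] * p[5L] != 0L) next
            if (p[3L] * p[5L] * p[7L] != 0L) next
          } else {
            if (p[1L] * p[3L] * p[7L] != 0L) next
            if (p[1L] * p[5L] * p[7L] != 0L) next
          }
          marks[r, c] <- TRUE
        }
      }
      if (any(marks)) {
        m[marks] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# -- 8-connected component count by iterative min-label propagation --------

count_components_oracle <- function(m) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(seq_len(h * w), h, w)
  lab[m == 0L] <- 0L
  shift0 <- function(x, dr, dc) {
    out <- matrix(0L, h, w)
    rs <- max(1L, 1L + dr):min(h, h + dr)
    cs <- max(1L, 1L + dc):min(w, w + dc)
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  repeat {
    nxt <- lab
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      s <- shift0(lab, dr, dc)
      upd <- m == 1L & s > 0L & (nxt == 0L | s < nxt)
      nxt[upd] <- s[upd]
    }
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  length(unique(lab[lab > 0L]))
}

# -- naive square-kernel erosion / dilation --------------------------------

erode_oracle <- function(m, k) {
  h <- nrow(m); w <- ncol(m); r <- (k - 1L) %/% 2L
  out <- matrix(0L, h, w)
  for (row in seq_len(h)) for (col in seq_len(w)) {
    rs <- (row - r):(row + r); cs <- (col - r):(col + r)
    ok <- rs >= 1L & rs <= h
    okc <- cs >= 1L & cs <= w
    if (!all(ok) || !all(okc)) next   # zero padding: border never survives
    if (all(m[rs, cs] == 1L)) out[row, col] <- 1L
  }
  out
}

dilate_oracle <- function(m, k) {
  h <- nrow(m); w <- ncol(m); r <- (k - 1L) %/% 2L
  out <- matrix(0L, h, w)
  for (row in seq_len(h)) for (col in seq_len(w)) {
    rs <- max(1L, row - r):min(h, row + r)
    cs <- max(1L, col - r):min(w, col + r)
    if (any(m[rs, cs] == 1L)) out[row, col] <- 1L
  }
  out
}

# -- exhaustive optimal one-to-one point matching --------------------------

optimal_match_count <- function(pred, truth, radius) {
  np <- nrow(pred); nt <- nrow(truth)
  if (nt == 0L || np == 0L) return(0L)
  best <- 0L
  used <- logical(np)
  rec <- function(ti, acc) {
    if (ti > nt) {
      best <<- max(best, acc)
      return()
    }
    rec(ti + 1L, acc)
    for (pi in seq_len(np)) {
      if (used[pi]) next
      d <- sqrt(sum((pred[pi, ] - truth[ti, ])^2))
      if (d <= radius) {
        used[pi] <<- TRUE
        rec(ti + 1L, acc + 1L)
        used[pi] <<- FALSE
      }
    }
  }
  rec(1L, 0L)
  best
}

# -- boundary pixels by 4-neighbour background test ------------------------

boundary_pixels_oracle <- function(m) {
  h <- nrow(m); w <- ncol(m)
  val <- function(r, c) if (r < 1L || r > h || c < 1L || c > w) 0L else m[r, c]
  out <- NULL
  for (row in seq_len(h)) for (col in seq_len(w)) {
    if (m[row, col] != 1L) next
    if (val(row - 1L, col) == 0L || val(row + 1L, col) == 0L ||
        val(row, col - 1L) == 0L || val(row, col + 1L) == 0L) {
      out <- rbind(out, c(col - 1L, row - 1L))
    }
  }
  out
}

# rasterize an ellipse from its generating inequality, per pixel
ellipse_raster_oracle <- function(cx, cy, a, b, angle_deg, shape) {
  th <- angle_deg * pi / 180
  m <- matrix(0L, shape[1L], shape[2L])
  for (row in seq_len(shape[1L])) for (col in seq_len(shape[2L])) {
    dx <- (col - 1L) - cx; dy <- (row - 1L) - cy
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / b
    if (u^2 + v^2 <= 1) m[row, col] <- 1L
  }
  m
}

random_mask <- function(h = 32L, w = 32L, density = 0.4) {
  matrix(as.integer(stats::runif(h * w) < density), h, w)
}

# isolated 2x2 square components: the one shape Zhang-Suen's simultaneous
# sub-pass deletes entirely (all four pixels satisfy the first sub-pass
# conditions at once), so component preservation holds up to these
count_2x2_square_components <- function(m) {
  h <- nrow(m); w <- ncol(m)
  val <- function(r, c) if (r < 1L || r > h || c < 1L || c > w) 0L else m[r, c]
  n <- 0L
  for (r in seq_len(h - 1L)) for (c in seq_len(w - 1L)) {
    if (m[r, c] + m[r, c + 1L] + m[r + 1L, c] + m[r + 1L, c + 1L] != 4L) next
    ring_clear <- TRUE
    for (rr in (r - 1L):(r + 2L)) for (cc in (c - 1L):(c + 2L)) {
      if (rr >= r && rr <= r + 1L && cc >= c && cc <= c + 1L) next
      if (val(rr, cc) == 1L) ring_clear <- FALSE
    }
    if (ring_clear) n <- n + 1L
  }
  n
}

# "unambiguous" matching instance: the within-radius bipartite graph is
# already a partial matching (no point is inside the radius of two others)
matching_unambiguous <- function(pred, truth, radius) {
  d <- outer(seq_len(nrow(pred)), seq_len(nrow(truth)), function(i, j) {
    sqrt((pred[i, 1] - truth[j, 1])^2 + (pred[i, 2] - truth[j, 2])^2)
  })
  g <- d <= radius
  all(rowSums(g) <= 1L) && all(colSums(g) <= 1L)
}
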