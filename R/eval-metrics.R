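#' Evaluation counts
#'
#' Bookkeeping for picking-point evaluation: `point_all` ground-truth
#' targets, of which `point_a` were accurately detected and `point_e`
#' remained undetected. The complement identity
#' `point_a + point_e == point_all` is enforced.
#'
#' @param point_all,point_a,point_e non-negative integers.
#' @export
eval_counts <- function(point_all, point_a, point_e = point_all - point_a) {
  point_all <- as.integer(point_all)
  point_a <- as.integer(point_a)
  point_e <- as.integer(point_e)
  if (any(c(point_all, point_a, point_e) < 0L) ||
      point_a + point_e != point_all) {
    stop("counts must be non-negative with point_a + point_e == point_all",
         call. = FALSE)
  }
  structure(
    list(point_all = point_all, point_a = point_a, point_e = point_e),
    class = "eval_counts"
  )
}

as_eval_counts <- function(c) {
  if (inherits(c, "eval_counts")) c
  else eval_counts(c$point_all, c$point_a, c$point_e)
}

#' Picking-point accuracy (AP)
#'
#' The percentage of ground-truth target points accurately detected,
#' `100 * point_a / point_all`, reported to two decimals.
#'
#' @param counts an [eval_counts()] (or list with the same fields).
#' @return percentage in `[0, 100]`.
#' @examples
#' compute_ap(eval_counts(point_all = 572, point_a = 534))
#' @export
compute_ap <- function(counts) {
  counts <- as_eval_counts(counts)
  if (counts$point_all == 0L) {
    stop("AP is undefined for zero target points", call. = FALSE)
  }
  round(100 * counts$point_a / counts$point_all, 2)
}

#' Wrong-point rate (WP)
#'
#' The percentage of target points left undetected,
#' `100 * point_e / point_all`, to two decimals. AP and WP of the same
#' counts sum to 100.
#'
#' @inheritParams compute_ap
#' @export
compute_wp <- function(counts) {
  counts <- as_eval_counts(counts)
  if (counts$point_all == 0L) {
    stop("WP is undefined for zero target points", call. = FALSE)
  }
  round(100 * counts$point_e / counts$point_all, 2)
}

#' Match predicted points to ground truth
#'
#' Greedy one-to-one matching in ascending pair-distance order: the closest
#' (prediction, truth) pair is matched first, both are retired, and so on.
#' A truth point counts as accurately detected when its match lies within
#' `radius` pixels. Spurious predictions are ignored beyond occupying a
#' match slot; unmatched truths are the undetected count.
#'
#' @param predicted,truth two-column `(x, y)` matrices (zero rows allowed).
#' @param radius tolerance radius in pixels.
#' @return an [eval_counts()].
#' @export
match_points <- function(predicted, truth, radius = 10) {
  stopifnot(radius >= 0)
  predicted <- as_point_matrix(predicted)
  truth <- as_point_matrix(truth)
  np <- nrow(predicted); nt <- nrow(truth)
  if (nt == 0L) return(eval_counts(0L, 0L))
  if (np == 0L) return(eval_counts(nt, 0L))
  d <- outer(seq_len(np), seq_len(nt), function(i, j) {
    sqrt((predicted[i, 1L] - truth[j, 1L])^2 +
           (predicted[i, 2L] - truth[j, 2L])^2)
  })
  matched <- 0L
  repeat {
    k <- which.min(d)
    if (!is.finite(d[k])) break
    if (d[k] <= radius) matched <- matched + 1L
    i <- (k - 1L) %% np + 1L
    j <- (k - 1L) %/% np + 1L
    d[i, ] <- Inf
    d[, j] <- Inf
    if (all(!is.finite(d))) break
  }
  eval_counts(nt, matched)
}

as_point_matrix <- function(p) {
  if (is.null(p)) return(matrix(numeric(0), 0L, 2L))
  if (is.data.frame(p)) p <- as.matrix(p[, c("x", "y")])
  p <- as.matrix(p)
  if (length(p) == 0L) return(matrix(numeric(0), 0L, 2L))
  stopifnot(ncol(p) == 2L)
  p
}

#' Evaluate predicted picking points against ground truth
#'
#' Convenience wrapper combining [match_points()], [compute_ap()] and
#' [compute_wp()] into a one-row report in the layout of the method's
#' evaluation table.
#'
#' @inheritParams match_points
#' @return a tibble: `point_all`, `point_a`, `point_e`, `ap_percent`,
#'   `wp_percent`, of class `eval_result`.
#' @export
evaluate_points <- function(predicted, truth, radius = 10) {
  counts <- match_points(predicted, truth, radius)
  out <- tibble::tibble(
    point_all = counts$point_all,
    point_a = counts$point_a,
    point_e = counts$point_e,
    ap_percent = compute_ap(counts),
    wp_percent = compute_wp(counts)
  )
  class(out) <- c("eval_result", class(out))
  out
}

#' @export
print.eval_result <- function(x, ...) {
  cat("Picking-point evaluation\n")
  cat(sprintf("  Point_all: %d   Point_a: %d   Point_e: %d\n",
              x$point_all, x$point_a, x$point_e))
  cat(sprintf("  AP: %.2f%%   WP: %.2f%%\n", x$ap_percent, x$wp_percent))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.eval_result <- function(x, ...) {
  tibble::tibble(
    metric = c("point_all", "point_a", "point_e", "ap_percent", "wp_percent"),
    value = c(x$point_all, x$point_a, x$point_e, x$ap_percent, x$wp_percent)
  )
}

#' @export
glance.eval_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("point_all", "ap_percent", "wp_percent")])
}
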