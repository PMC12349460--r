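test_that("morphological cleaning removes speckle and fills holes", {
  m <- matrix(0L, 9, 9); m[5, 5] <- 1L
  expect_equal(sum(clean_mask(binary_mask(m), 3)), 0)   # speckle opened away

  m <- matrix(0L, 11, 11); m[3:9, 3:9] <- 1L; m[6, 6] <- 0L
  got <- clean_mask(binary_mask(m), 3)
  # compose the naive morphology oracles: open then close
  o <- dilate_oracle(erode_oracle(m, 3L), 3L)
  want <- erode_oracle(dilate_oracle(o, 3L), 3L)
  expect_identical(unclass(got), want)
  expect_equal(got[6, 6], 1L)                            # hole closed

  empty <- binary_mask(matrix(0L, 6, 6))
  expect_equal(sum(clean_mask(empty, 3)), 0)
})

test_that("thinning leaves 1-px diagonals unchanged and thins bars to paths", {
  d <- matrix(0L, 10, 10); d[cbind(2:8, 2:8)] <- 1L
  expect_identical(unclass(zhang_suen_thin(binary_mask(d))$mask), d)

  bar <- matrix(0L, 9, 16); bar[4:6, 3:14] <- 1L
  sk <- zhang_suen_thin(binary_mask(bar))
  m <- unclass(sk$mask)
  expect_true(all(m <= bar))                      # never adds foreground
  expect_true(all(which(rowSums(m) > 0) == 5L))   # a single horizontal row
  expect_gte(sum(m[5L, ]), 8L)                    # spanning (most of) the bar
  expect_true(all(diff(which(m[5L, ] == 1L)) == 1L))
  expect_equal(nrow(sk$endpoints), 2L)

  # fixed-point idempotence
  sk2 <- zhang_suen_thin(sk$mask)
  expect_identical(unclass(sk2$mask), m)
})

test_that("production thinning equals the literal two-subpass reference", {
  set.seed(99)
  for (i in 1:150) {
    m <- random_mask(32, 32, runif(1, 0.2, 0.6))
    expect_identical(
      unclass(zhang_suen_thin(binary_mask(m))$mask),
      zhang_suen_reference(m)
    )
  }
})

test_that("thinning preserves the 8-connected component count", {
  # the single known exception: an isolated 2x2 square is deleted outright
  # by the simultaneous first sub-pass (all four pixels satisfy B in [2,6],
  # A = 1 and both edge templates at once), so it is asserted explicitly
  # and discounted from the preservation property
  sq <- matrix(0L, 6, 6); sq[3:4, 3:4] <- 1L
  expect_equal(sum(zhang_suen_thin(binary_mask(sq))$mask), 0)

  set.seed(123)
  for (i in 1:150) {
    m <- random_mask(32, 32, runif(1, 0.2, 0.6))
    thin <- unclass(zhang_suen_thin(binary_mask(m))$mask)
    expect_true(all(thin <= m))
    expect_equal(
      count_components_oracle(thin),
      count_components_oracle(m) - count_2x2_square_components(m)
    )
  }
})

test_that("skeleton pixel classification finds endpoints and junctions", {
  line <- matrix(0L, 5, 14); line[3, 3:12] <- 1L
  cls <- classify_skeleton_pixels(binary_mask(line))
  expect_equal(nrow(cls$endpoints), 2L)
  expect_equal(nrow(cls$junctions), 0L)

  # T: horizontal bar with a vertical drop from its middle. Under the
  # 8-neighbour rule the arms' pixels diagonally adjacent to the meeting
  # point also reach three neighbours, so the junction appears as one
  # tight cluster around the meeting pixel; exactly one pixel is a true
  # branch point (three distinct emanating branches).
  tshape <- matrix(0L, 12, 12)
  tshape[3, 2:10] <- 1L
  tshape[4:10, 6] <- 1L
  cls <- classify_skeleton_pixels(binary_mask(tshape))
  expect_equal(nrow(cls$endpoints), 3L)
  expect_gte(nrow(cls$junctions), 1L)
  expect_true(all(abs(cls$junctions[, "x"] - 5L) <= 1L &
                    abs(cls$junctions[, "y"] - 2L) <= 1L))
  branch <- pickpoint:::crossing_number(tshape) >= 3L & tshape == 1L
  expect_equal(which(branch), (6L - 1L) * 12L + 3L)  # the meeting pixel only

  # diamond ring: every pixel has exactly two (diagonal) neighbours
  ring <- matrix(0L, 11, 11)
  for (x in 0:10) for (y in 0:10) if (abs(x - 5) + abs(y - 5) == 4) {
    ring[y + 1, x + 1] <- 1L
  }
  cls <- classify_skeleton_pixels(binary_mask(ring))
  expect_equal(nrow(cls$endpoints), 0L)
  expect_equal(nrow(cls$junctions), 0L)
})

test_that("pruning removes short branches and fragments but keeps the trunk", {
  # straight 30-px line survives untouched
  line <- matrix(0L, 6, 34); line[3, 3:32] <- 1L
  pr <- prune_skeleton(zhang_suen_thin(binary_mask(line)), 10)
  expect_identical(unclass(pr$mask), line)

  # 30-px trunk with a 5-px side branch: branch goes, trunk stays
  m <- matrix(0L, 12, 34)
  m[6, 3:32] <- 1L
  m[7:11, 18] <- 1L
  pr <- prune_skeleton(zhang_suen_thin(binary_mask(m)), 10)
  kept <- unclass(pr$mask)
  expect_equal(sum(kept[7:11, 18]), 0)        # branch removed
  expect_true(all(kept[6, 3:32] == 1L))       # trunk intact

  # min_len 0 is the identity
  pr0 <- prune_skeleton(zhang_suen_thin(binary_mask(m)), 0)
  expect_identical(unclass(pr0$mask), m)

  # an isolated small fragment disappears, unless it is all there is
  m2 <- matrix(0L, 20, 40)
  m2[10, 2:30] <- 1L
  m2[3, 35:38] <- 1L
  pr2 <- prune_skeleton(zhang_suen_thin(binary_mask(m2)), 10)
  expect_equal(sum(unclass(pr2$mask)[3, ]), 0)
  expect_true(all(unclass(pr2$mask)[10, 2:30] == 1L))

  only <- matrix(0L, 10, 10); only[5, 3:6] <- 1L
  pr3 <- prune_skeleton(zhang_suen_thin(binary_mask(only)), 10)
  expect_equal(sum(pr3$mask), 4)              # largest component kept alive
})

test_that("pruned skeletons are subsets with no short endpoint branches left", {
  set.seed(31)
  for (i in 1:10) {
    sc <- generate_scene(scene_params(seed = 300 + i, image_shape = c(320, 320),
                                      stem_length = c(60, 120)))
    sk <- zhang_suen_thin(clean_mask(sc$seg$stem_instances[[1]], 3))
    pr <- prune_skeleton(sk, 10)
    expect_true(all(unclass(pr$mask) <= unclass(sk$mask)))
    # no remaining endpoint lies on a short branch: walking min_len pixels
    # from any endpoint never meets a pixel with 3+ distinct branches
    m <- unclass(pr$mask)
    A <- pickpoint:::crossing_number(m)
    cnt <- pickpoint:::neighbour_counts(m)
    for (ep in which(m == 1L & cnt == 1L)) {
      path <- ep; cur <- ep
      repeat {
        nbr <- pickpoint:::lin_neighbours(cur, nrow(m), ncol(m))
        nbr <- nbr[m[nbr] == 1L & !(nbr %in% path)]
        if (length(nbr) == 0L || length(path) >= 10L) break
        expect_true(all(A[nbr] < 3L))
        cur <- nbr[1L]; path <- c(path, cur)
      }
    }
  }
})
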