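test_that("outlier removal is a disk opening", {
  speck <- matrix(0L, 20, 20)
  speck[c(5, 40, 250)] <- 1L  # isolated pixels
  expect_equal(sum(remove_outliers(speck, 2)), 0)

  sq <- matrix(0L, 30, 30); sq[6:25, 6:25] <- 1L
  expect_identical(remove_outliers(sq, 2), naive_opening(sq, 2))

  empty <- matrix(0L, 10, 10)
  expect_identical(remove_outliers(empty, 2), empty)

  set.seed(21)
  rnd <- matrix(rbinom(24 * 24, 1, 0.45), 24, 24)
  expect_identical(remove_outliers(rnd, 1), naive_opening(rnd, 1))
  expect_identical(remove_outliers(rnd, 2), naive_opening(rnd, 2))
})

test_that("component labeling matches flood fill and honors connectivity", {
  set.seed(5)
  rnd <- matrix(rbinom(20 * 20, 1, 0.35), 20, 20)
  for (conn in c(4, 8)) {
    lab <- label_components(rnd, conn)
    ff <- flood_fill_label(rnd, conn)
    # same partition (labels may be permuted)
    expect_equal(length(lab$sizes), max(ff))
    for (id in seq_len(max(ff))) {
      got <- unique(lab$labels[ff == id])
      expect_length(got, 1)
    }
    expect_equal(sum(lab$sizes), sum(rnd))
  }
  # diagonal pair: one component under 8, two under 4
  diagm <- matrix(0L, 4, 4); diagm[1, 1] <- 1L; diagm[2, 2] <- 1L
  expect_length(label_components(diagm, 8)$sizes, 1)
  expect_length(label_components(diagm, 4)$sizes, 2)
})

test_that("largest component retention and its tie rules", {
  m <- matrix(0L, 30, 30)
  m[2:11, 2:11] <- 1L           # 100 px
  m[20:25, 20:26] <- 1L         # 42 px
  keep <- largest_component(m)
  expect_equal(sum(keep), 100)
  expect_equal(keep[3, 3], 1L)

  tie <- matrix(0L, 10, 20)
  tie[3:5, 2:4] <- 1L           # left blob, 9 px
  tie[6:8, 15:17] <- 1L         # right blob, 9 px
  keep <- largest_component(tie)
  expect_equal(keep[4, 3], 1L)  # leftmost wins
  expect_equal(sum(keep[, 10:20]), 0)

  expect_error(largest_component(matrix(0L, 5, 5)), "no positive")
})

test_that("inversion and erosion turns closed contours into interior regions", {
  ring <- matrix(0L, 30, 30)
  ring[10:20, 10:20] <- 1L
  ring[12:18, 12:18] <- 0L      # square annulus, 2 px thick
  inv <- invert_and_erode(ring, 1)
  lab <- label_components(inv, 8)
  expect_gte(length(lab$sizes), 2)
  interior_label <- lab$labels[15, 15]
  outside_label <- lab$labels[2, 2]
  expect_true(interior_label > 0 && outside_label > 0)
  expect_true(interior_label != outside_label)

  # all-zero edges: complement is everything, erosion shaves the image border
  inv0 <- invert_and_erode(matrix(0L, 12, 12), 2)
  expect_equal(inv0[1, 1], 0L)
  expect_equal(inv0[6, 6], 1L)
  expect_identical(inv0, naive_erode(matrix(1L, 12, 12), 2))

  # all-ones edges: nothing remains
  expect_equal(sum(invert_and_erode(matrix(1L, 12, 12), 2)), 0)
})

test_that("smoothing preserves large shapes and closes slits", {
  disk <- matrix(0L, 40, 40)
  for (i in 1:40) for (j in 1:40)
    if ((i - 20)^2 + (j - 20)^2 <= 144) disk[i, j] <- 1L
  sm <- smooth_and_reconnect(disk, 2, 5)
  expect_lt(abs(sum(sm) - sum(disk)) / sum(disk), 0.05)

  slit <- disk; slit[20, ] <- 0L  # 1-px slit through the disk
  healed <- smooth_and_reconnect(slit, 2, 5)
  expect_true(all(healed[20, 15:25] == 1L))
  expect_length(label_components(healed, 8)$sizes, 1)

  empty <- matrix(0L, 20, 20)
  expect_identical(smooth_and_reconnect(empty, 2, 5), empty)
})

test_that("anatomical selection prefers the largest left-region component", {
  m <- matrix(0L, 40, 100)
  m[10:30, 5:30] <- 1L     # large left blob
  m[15:20, 80:90] <- 1L    # small right blob
  sel <- select_liver(label_components(m), dim(m))
  expect_equal(sel[20, 10], 1L)
  expect_equal(sum(sel[, 60:100]), 0)

  # the left-region rule dominates size
  m2 <- matrix(0L, 40, 100)
  m2[5:35, 65:99] <- 1L    # huge right blob (centroid col 82 > 60)
  m2[15:25, 10:25] <- 1L   # medium left blob
  sel2 <- select_liver(label_components(m2), dim(m2))
  expect_equal(sel2[20, 15], 1L)
  expect_equal(sum(sel2[, 60:100]), 0)

  # single component anywhere is returned (with a warning if not left)
  m3 <- matrix(0L, 40, 100)
  m3[10:20, 70:90] <- 1L
  expect_warning(sel3 <- select_liver(label_components(m3), dim(m3)), "left")
  expect_equal(sum(sel3), sum(m3))

  expect_error(select_liver(label_components(matrix(0L, 5, 5)), c(5, 5)),
               "no candidate")
})

test_that("ring mask keeps the body and excludes a boundary ring", {
  ph <- generate_phantom(phantom_spec(ring = TRUE, noise_sigma = 0, seed = 2))
  den <- median_filter_2d(apply_window(ph$slice), 5)
  M <- ring_artifact_mask(den, 20)
  expect_equal(sum(M * ph$ring), 0)          # ring fully excluded
  expect_gt(sum(M * ph$truth) / sum(ph$truth), 0.99)  # liver inside M

  # near-uniform bright image: the opened mask covers almost everything
  img <- matrix(250, 80, 80); img[1:3, 1:3] <- 5
  M2 <- ring_artifact_mask(img, 5)
  expect_gt(mean(M2), 0.95)

  # a body smaller than the structuring disk is annihilated
  small <- matrix(1, 60, 60)
  small[25:35, 25:35] <- 250
  expect_error(ring_artifact_mask(small, 20), "smaller than")
})
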