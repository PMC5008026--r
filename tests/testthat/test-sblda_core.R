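test_that("block CT value is the block mean", {
  const <- matrix(4.5, 9, 9)
  expect_equal(block_ct_value(const, c(5, 5), 3), 4.5)
  expect_equal(block_ct_value(const, c(5, 5), 5), 4.5)

  seq9 <- matrix(1:9, 3, 3)
  expect_equal(block_ct_value(seq9, c(2, 2), 3), 5)

  set.seed(3)
  img <- matrix(runif(81, 1, 256), 9, 9)
  for (i in 2:8) for (j in 2:8) {
    expect_equal(block_ct_value(img, c(i, j), 3),
                 sum(img[(i - 1):(i + 1), (j - 1):(j + 1)]) / 9,
                 tolerance = 1e-12)
  }
  expect_error(block_ct_value(img, c(1, 5), 3), "bounds")
})

test_that("ratio parameter is zero on constants and recovers a dark line", {
  const <- matrix(123, 21, 21)
  for (theta in seq(0, 315, by = 45)) {
    expect_equal(ratio_parameter(const, c(11, 11), theta), 0)
  }

  # dark 1-pixel vertical line in a bright field; detection across the line
  img <- matrix(201, 15, 15)
  img[, 8] <- 1
  # seed left of the line so the candidate (one step at theta = 0) is on it
  r <- ratio_parameter(img, c(8, 7), theta = 0, w = 7, N = 1)
  expect_equal(r, (201 + 201 - 2) / 2)  # = 200
})

test_that("opposite directions probe mirrored candidates", {
  set.seed(11)
  img <- matrix(runif(30 * 30, 1, 256), 30, 30)
  for (theta in c(0, 45, 90, 135)) {
    rad <- theta * pi / 180
    d <- c(-round(sin(rad)), round(cos(rad)))
    p <- c(15, 15)
    expect_equal(ratio_parameter(img, p, theta),
                 ratio_parameter(img, p + 2 * d, theta + 180))
  }
})

test_that("vectorized ratio field equals the naive loop bit-exactly", {
  p <- sblda_params()
  for (s in 1:3) {
    set.seed(s)
    img <- matrix(runif(40 * 40, 1, 256), 40, 40)
    field <- max_ratio_field(img, p)
    expect_identical(field$values, oracle_max_ratio_field(img, p$w, p$N))
    expect_equal(field$margin, 6L)
  }
})

test_that("ratio field is zero on constants and scale-free", {
  p <- sblda_params()
  const <- matrix(55, 40, 40)
  f <- max_ratio_field(const, p)
  expect_true(all(f$values[!is.na(f$values)] == 0))

  set.seed(9)
  img <- matrix(runif(40 * 40, 1, 256), 40, 40)
  base <- confidence_matrix(max_ratio_field(img, p), p$T)
  for (k in c(0.5, 2, 10)) {
    scaled <- confidence_matrix(max_ratio_field(k * img, p), p$T)
    expect_identical(scaled, base)
  }
})

test_that("ratio field rejects non-positive or too-small images", {
  p <- sblda_params()
  expect_error(max_ratio_field(matrix(0, 40, 40), p), "positive")
  expect_error(max_ratio_field(matrix(10, 20, 20), p), "too small")
})

test_that("confidence matrix thresholds inclusively and zeroes the margin", {
  p <- sblda_params()
  const <- matrix(5, 40, 40)
  f <- max_ratio_field(const, p)
  expect_true(all(confidence_matrix(f, 0.85) == 0L))

  # exact threshold hit counts as edge evidence
  f$values[20, 20] <- 0.85
  cm <- confidence_matrix(f, 0.85)
  expect_equal(cm[20, 20], 1L)
  expect_equal(sum(cm), 1L)
  expect_true(all(cm[1:6, ] == 0L) && all(cm[, 1:6] == 0L))

  expect_error(confidence_matrix(f, 0), "T")
})

test_that("positive sets are nested decreasing in the threshold", {
  ph <- generate_phantom(phantom_spec(seed = 5))
  den <- median_filter_2d(apply_window(ph$slice), 5)
  f <- max_ratio_field(den, sblda_params())
  ts <- c(0.5, 0.8, 0.85, 0.9, 1.2)
  masks <- lapply(ts, function(t) confidence_matrix(f, t))
  counts <- vapply(masks, sum, numeric(1))
  expect_true(all(diff(counts) < 0))
  for (i in seq_len(length(ts) - 1)) {
    expect_true(all(masks[[i + 1]] <= masks[[i]]))  # subset relation
  }
})

test_that("the perpendicular block orientation is available as a variant", {
  set.seed(13)
  img <- matrix(runif(40 * 40, 1, 256), 40, 40)
  p_along <- sblda_params()
  p_perp <- sblda_params(orientation = "perpendicular")
  f1 <- max_ratio_field(img, p_along)
  f2 <- max_ratio_field(img, p_perp)
  expect_false(identical(f1$values, f2$values))
  # scalar and field variants agree with each other
  expect_equal(f2$values[20, 20],
               max(vapply(seq(0, 315, by = 45), function(th) {
                 abs(ratio_parameter(img, c(20, 20), th,
                                     orientation = "perpendicular"))
               }, numeric(1))))
})
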