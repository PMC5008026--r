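test_that("confusion metrics match hand counts and brute force", {
  # 4x4: ref = left half, pred = top half
  ref <- matrix(0L, 4, 4); ref[, 1:2] <- 1L
  pred <- matrix(0L, 4, 4); pred[1:2, ] <- 1L
  r <- confusion_metrics(pred, ref)
  expect_equal(r$tp, 4); expect_equal(r$fp, 4)
  expect_equal(r$fn, 4); expect_equal(r$tn, 4)
  expect_equal(r$sensitivity, 0.5)
  expect_equal(r$specificity, 0.5)
  expect_equal(r$accuracy, 0.5)

  for (s in 1:20) {
    set.seed(s)
    a <- matrix(rbinom(256, 1, runif(1, 0.2, 0.8)), 16, 16)
    b <- matrix(rbinom(256, 1, runif(1, 0.2, 0.8)), 16, 16)
    got <- confusion_metrics(a, b)
    ora <- naive_confusion(a, b)
    expect_identical(got[c("tp", "tn", "fp", "fn")], ora)
    expect_equal(got$tp + got$tn + got$fp + got$fn, 256)
  }
})

test_that("perfect and inverted predictions hit the metric extremes", {
  ref <- random_blob(24, 31)
  r <- confusion_metrics(ref, ref)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$accuracy, 1)

  r2 <- confusion_metrics(1L - ref, ref)
  expect_equal(r2$sensitivity, 0)
  expect_equal(r2$specificity, 0)
})

test_that("undefined ratios are flagged, not silently zeroed", {
  pred <- matrix(0L, 4, 4)
  ref <- matrix(0L, 4, 4)
  r <- confusion_metrics(pred, ref)
  expect_true(is.na(r$sensitivity))
  expect_true("sensitivity" %in% r$undefined)
  expect_equal(r$specificity, 1)
  expect_error(confusion_metrics(matrix(0L, 3, 3), ref), "shape")
})

test_that("volume metrics follow the set arithmetic definitions", {
  ref <- random_blob(24, 7)
  expect_equal(volume_metrics(ref, ref), list(voe = 0, srvd = 0))

  a <- matrix(0L, 10, 10); a[1:5, 1:5] <- 1L
  b <- matrix(0L, 10, 10); b[6:10, 6:10] <- 1L
  expect_equal(volume_metrics(a, b)$voe, 100)  # disjoint

  # |A| = 150, |B| = 100, |A∩B| = 100
  a2 <- matrix(0L, 20, 20); a2[1:10, 1:15] <- 1L
  b2 <- matrix(0L, 20, 20); b2[1:10, 1:10] <- 1L
  vm <- volume_metrics(a2, b2)
  expect_equal(vm$voe, 100 * (1 - 100 / 150))
  expect_equal(vm$srvd, 50)
  # anti-symmetry up to the denominator change
  vm_rev <- volume_metrics(b2, a2)
  expect_equal(vm_rev$srvd, 100 * (100 - 150) / 150)
  expect_equal(vm_rev$voe, vm$voe)  # VOE is symmetric

  expect_error(volume_metrics(a, matrix(0L, 10, 10)), "empty")
})

test_that("surface distances match the all-pairs oracle", {
  # concentric axis-aligned squares, borders 3 px apart
  outer_sq <- matrix(0L, 20, 20); outer_sq[4:17, 4:17] <- 1L
  inner_sq <- matrix(0L, 20, 20); inner_sq[7:14, 7:14] <- 1L
  got <- surface_distance_metrics(outer_sq, inner_sq)
  ora <- naive_surface_metrics(outer_sq, inner_sq)
  expect_equal(got$asd, ora$asd, tolerance = 1e-9)
  expect_equal(got$rmsd, ora$rmsd, tolerance = 1e-9)
  expect_equal(got$msd, ora$msd, tolerance = 1e-9)
  expect_equal(got$msd, sqrt(18))  # corner-to-corner distance

  for (s in 1:5) {
    a <- random_blob(28, s)
    b <- random_blob(28, s + 100)
    got <- surface_distance_metrics(a, b)
    ora <- naive_surface_metrics(a, b)
    expect_equal(got$asd, ora$asd, tolerance = 1e-9)
    expect_equal(got$rmsd, ora$rmsd, tolerance = 1e-9)
    expect_equal(got$msd, ora$msd, tolerance = 1e-9)
    # power-mean ordering and symmetry
    expect_lte(got$asd, got$rmsd + 1e-12)
    expect_lte(got$rmsd, got$msd + 1e-12)
    swapped <- surface_distance_metrics(b, a)
    expect_equal(swapped, got)
  }

  expect_equal(surface_distance_metrics(inner_sq, inner_sq),
               list(asd = 0, rmsd = 0, msd = 0))
  expect_error(surface_distance_metrics(matrix(0L, 5, 5), inner_sq[1:5, 1:5]),
               "non-empty")
})

test_that("anisotropic spacing scales horizontal distances", {
  a <- matrix(0L, 9, 9); a[5, 3] <- 1L
  b <- matrix(0L, 9, 9); b[5, 5] <- 1L  # two columns apart
  iso <- surface_distance_metrics(a, b, spacing = c(1, 1))
  expect_equal(iso$msd, 2)
  for (k in c(0.5, 2, 3.25)) {
    an <- surface_distance_metrics(a, b, spacing = c(1, k))
    expect_equal(an$msd, 2 * k)
    expect_equal(an$asd, 2 * k)
  }
})

test_that("evaluate_segmentation assembles the full report", {
  ref <- random_blob(24, 3)
  r <- evaluate_segmentation(ref, ref, spacing = c(0.7, 0.7))
  expect_s3_class(r, "seg_report")
  expect_equal(r$voe, 0)
  expect_equal(r$msd, 0)
  expect_equal(r$accuracy, 1)
  expect_output(print(r), "VOE")
})
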