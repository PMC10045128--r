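test_that("confusion counts and overlap metrics match hand-worked examples", {
  sp <- mask_of(array(c(1, 0, 1, 0), c(1, 2, 2)))
  gt <- mask_of(array(c(1, 1, 0, 0), c(1, 2, 2)))
  cc <- confusion_counts(sp, gt)
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  expect_equal(dice(sp, gt), 0.5)
  expect_equal(sensitivity(sp, gt), 0.5)
  expect_equal(sensibility(sp, gt), 0.5)

  # tp=8, fn=2, fp=4 -> dice 16/22, sensitivity 0.8, sensibility 0.6
  a <- array(0, c(1, 8, 8)); b <- array(0, c(1, 8, 8))
  a[1, 1, 1:8] <- 1; b[1, 1, 1:8] <- 1          # 8 tp
  b[1, 2, 1:2] <- 1                              # 2 fn
  a[1, 3, 1:4] <- 1                              # 4 fp
  expect_equal(dice(mask_of(a), mask_of(b)), 16 / 22)
  expect_equal(sensitivity(mask_of(a), mask_of(b)), 0.8)
  expect_equal(sensibility(mask_of(a), mask_of(b)), 0.6)

  # sensibility is unclamped: tp=1, fn=0, fp=3 -> -2
  a2 <- array(0, c(1, 4, 4)); g2 <- array(0, c(1, 4, 4))
  a2[1, 1, 1:4] <- 1; g2[1, 1, 1] <- 1
  expect_equal(sensibility(mask_of(a2), mask_of(g2)), -2.0)
})

test_that("empty-mask conventions: dice 1 on double-empty, errors elsewhere", {
  e <- mask_of(array(0, c(1, 4, 4)))
  k <- mask_of(array(c(1, 1, rep(0, 14)), c(1, 4, 4)))
  expect_equal(dice(e, e), 1.0)
  expect_equal(dice(e, k), 0.0)
  expect_equal(sensitivity(e, k), 0.0)
  expect_error(sensitivity(k, e), "empty")
  expect_error(sensibility(k, e), "empty")
  expect_error(extract_contour(e), "empty")
  expect_error(confusion_counts(e, mask_of(array(0, c(1, 8, 8)))), "differ")
})

test_that("contours are per-slice 4-neighbour boundaries in physical mm", {
  # single voxel at 0-based (0,5,5) with spacing (1,0.2,0.2) -> (0,1,1)
  arr <- array(0, c(1, 16, 16)); arr[1, 6, 6] <- 1
  pts <- extract_contour(mask_of(arr, c(1, 0.2, 0.2)))
  expect_equal(nrow(pts), 1)
  expect_equal(as.vector(pts), c(0, 1, 1))

  # filled 3x3 square: 8 boundary points, the centre excluded
  sq <- array(0, c(1, 8, 8)); sq[1, 3:5, 3:5] <- 1
  expect_equal(nrow(extract_contour(mask_of(sq))), 8)

  # 1-voxel-thick line: every voxel is boundary
  ln <- array(0, c(1, 8, 8)); ln[1, 4, 2:7] <- 1
  expect_equal(nrow(extract_contour(mask_of(ln))), 6)
})

test_that("hausdorff and average hausdorff match closed-form cases", {
  a <- matrix(c(0, 0, 0), 1, 3)
  b <- matrix(c(0, 3, 4), 1, 3)
  expect_equal(hausdorff(a, b), 5.0)         # 3-4-5 triangle
  expect_equal(hausdorff(a, a), 0.0)
  expect_equal(average_hausdorff(a, a), 0.0)

  a2 <- rbind(c(0, 0, 0), c(0, 1, 0))
  b2 <- matrix(c(0, 0, 0), 1, 3)
  expect_equal(hausdorff(a2, b2), 1.0)
  expect_equal(average_hausdorff(a2, b2), 0.25)  # directed means 0.5 and 0
  expect_error(hausdorff(a, matrix(numeric(0), 0, 3)), "non-empty")
})

test_that("metrics agree with explicit brute-force oracles on random masks", {
  withr::with_seed(33, {
    for (i in 1:60) {
      dims <- c(sample(1:2, 1), sample(4:16, 1), sample(4:16, 1))
      sp <- random_mask(dims, p = stats::runif(1, 0.15, 0.6))
      gt <- random_mask(dims, p = stats::runif(1, 0.15, 0.6))
      spacing <- stats::runif(3, 0.1, 2)
      msp <- mask_of(sp, spacing); mgt <- mask_of(gt, spacing)
      expect_equal(dice(msp, mgt), oracle_dice(sp, gt), tolerance = 1e-12)
      expect_equal(sensitivity(msp, mgt), oracle_sensitivity(sp, gt),
                   tolerance = 1e-12)
      expect_equal(sensibility(msp, mgt), oracle_sensibility(sp, gt),
                   tolerance = 1e-12)
      ca <- extract_contour(msp); cb <- extract_contour(mgt)
      oa <- oracle_contour(sp, spacing); ob <- oracle_contour(gt, spacing)
      expect_equal(nrow(ca), nrow(oa))
      expect_equal(hausdorff(ca, cb), oracle_hausdorff(oa, ob))
      expect_equal(average_hausdorff(ca, cb), oracle_avg_hausdorff(oa, ob))
    }
  })
})

test_that("distance metrics are symmetric; sensitivity and sensibility are not", {
  withr::with_seed(34, {
    sp <- random_mask(c(2, 12, 12)); gt <- random_mask(c(2, 12, 12))
  })
  msp <- mask_of(sp); mgt <- mask_of(gt)
  ca <- extract_contour(msp); cb <- extract_contour(mgt)
  expect_equal(hausdorff(ca, cb), hausdorff(cb, ca))
  expect_equal(average_hausdorff(ca, cb), average_hausdorff(cb, ca))
  expect_equal(dice(msp, mgt), dice(mgt, msp))
  # explicit asymmetry counterexample
  a <- array(0, c(1, 4, 4)); g <- array(0, c(1, 4, 4))
  a[1, 1, 1:2] <- 1; g[1, 1, 1] <- 1
  expect_false(isTRUE(all.equal(sensitivity(mask_of(a), mask_of(g)),
                                sensitivity(mask_of(g), mask_of(a)))))
  expect_false(isTRUE(all.equal(sensibility(mask_of(a), mask_of(g)),
                                sensibility(mask_of(g), mask_of(a)))))
})

test_that("average hausdorff never exceeds hausdorff", {
  withr::with_seed(35, {
    for (i in 1:100) {
      a <- matrix(stats::rnorm(3 * sample(2:20, 1)), ncol = 3)
      b <- matrix(stats::rnorm(3 * sample(2:20, 1)), ncol = 3)
      expect_lte(average_hausdorff(a, b), hausdorff(a, b) + 1e-12)
    }
  })
})

test_that("evaluate_pair is consistent with the individual metrics", {
  withr::with_seed(36, {
    for (i in 1:25) {
      dims <- c(2, 10, 10)
      spacing <- c(1, 0.5, 0.5)
      sp <- mask_of(random_mask(dims), spacing)
      gt <- mask_of(random_mask(dims), spacing)
      r <- evaluate_pair(sp, gt)
      expect_equal(r$dice, dice(sp, gt))
      expect_equal(r$sensitivity, sensitivity(sp, gt))
      expect_equal(r$sensibility, sensibility(sp, gt))
      expect_equal(r$hausdorff_mm,
                   hausdorff(extract_contour(sp), extract_contour(gt)))
      expect_equal(r$avg_hausdorff_mm,
                   average_hausdorff(extract_contour(sp),
                                     extract_contour(gt)))
    }
  })
  m <- mask_of(random_mask(c(2, 10, 10)))
  r <- evaluate_pair(m, m)
  expect_equal(c(r$dice, r$sensitivity, r$sensibility,
                 r$hausdorff_mm, r$avg_hausdorff_mm), c(1, 1, 1, 0, 0))
})

test_that("paired t-test reproduces the closed-form case and guards degeneracy", {
  # differences {1,1,2}: mean 4/3, sd 1/sqrt(3), t = 4, df = 2
  r <- paired_t_test(c(1, 2, 4), c(0, 1, 2))
  expect_equal(r$t, 4.0, tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * stats::pt(-4, df = 2), tolerance = 1e-12)
  expect_equal(r$p, 0.05719096, tolerance = 1e-6)

  expect_error(paired_t_test(c(1, 2, 3), c(1, 2, 3)), "identical")
  expect_error(paired_t_test(c(1, 2, 3), c(0, 1, 2)), "identical")
  expect_error(paired_t_test(1:3, 1:4), "equal length")
  expect_error(paired_t_test(1, 2), "two pairs")
})
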