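test_that("layer inventory matches the published architecture at any size and width", {
  for (cfg in list(c(64, 16), c(128, 4), c(256, 2), c(96, 3))) {
    inv <- network_inventory(build_runet(cfg[1], cfg[2]))
    expect_equal(inv$conv_total, 33)
    expect_equal(inv$pool, 5)
    expect_equal(inv$unpool, 5)
    expect_equal(inv$conv_encoder, 14)
    expect_equal(inv$conv_decoder, 19)
  }
  expect_error(build_runet(100, 8), "multiple of 32")
  expect_error(build_runet(0, 8), "multiple of 32")
  expect_error(build_runet(64, 0), ">= 1")
})

test_that("channel and spatial arithmetic follow the U-shape contract", {
  C <- 3L
  m <- build_runet(64, C, seed = 2)
  x <- array(stats::rnorm(64 * 64 * 2), c(64, 64, 1, 2))
  fwd <- ratunet:::runet_forward(m, x, training = TRUE)
  for (nd in m$nodes) {
    d <- dim(fwd$vals[[nd$id]])
    if (nd$op == "concat") {
      # concatenations are the only place the width doubles
      expect_equal(d[3], 2L * C)
    } else if (nd$op == "conv") {
      # every convolution returns to width C; the 1x1 head consolidates to 1
      expect_equal(d[3],
                   if (identical(nd$kernel, c(1L, 1L))) 1L else C)
    } else if (nd$op %in% c("pool", "unpool", "add")) {
      expect_equal(d[3], C)
    } else if (nd$op %in% c("bn", "relu", "sigmoid")) {
      # pre-activation layers preserve their input's width (2C right after
      # a concatenation, C elsewhere)
      expect_equal(d[3], dim(fwd$vals[[nd$inputs[1]]])[3])
    } else if (nd$op == "input") {
      expect_equal(d[3], 1L)
    }
    # encoder level k lives at N / 2^k; the deepest pool reaches N/32
    if (nd$op == "pool") expect_equal(d[1], 64 / 2^nd$level)
    if (nd$op == "unpool") expect_equal(d[1], 64 / 2^nd$level)
  }
  out <- fwd$output
  expect_equal(dim(out), c(64L, 64L, 1L, 2L))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("max pooling records argmax positions with row-major tie-break", {
  # [[1,2],[3,4]] pools to 4 at the bottom-right corner
  r <- max_pool_with_indices(matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE))
  expect_equal(as.vector(r$pooled), 4)
  expect_equal(as.vector(r$record$indices), 3L)  # 0-based linear of (2,2)
  expect_equal(max_unpool(r$pooled, r$record),
               matrix(c(0, 0, 0, 4), 2, 2, byrow = TRUE))

  # ties break to the first window position in row-major order
  r2 <- max_pool_with_indices(matrix(5, 2, 2))
  expect_equal(as.vector(r2$record$indices), 0L)

  # output dims are exactly half the input
  withr::with_seed(51, x <- array(stats::rnorm(8 * 8 * 3), c(8, 8, 3)))
  r3 <- max_pool_with_indices(x)
  expect_equal(dim(r3$pooled), c(4L, 4L, 3L))
  expect_error(max_pool_with_indices(matrix(0, 5, 4)), "even")
})

test_that("unpooling satisfies the pool round-trip identity", {
  # non-negative maps, as produced by the ReLU-family features the pooling
  # layers consume: zero-filled unpooling only preserves maxima >= 0
  withr::with_seed(52, {
    for (i in 1:100) {
      n <- sample(c(2, 4, 8, 16, 32, 64), 1)
      x <- array(abs(stats::rnorm(n * n * 2)), c(n, n, 2))
      p1 <- max_pool_with_indices(x)
      u <- max_unpool(p1$pooled, p1$record)
      p2 <- max_pool_with_indices(u)
      expect_identical(p2$pooled, p1$pooled)
      expect_lte(sum(u != 0), length(p1$pooled))
      expect_identical(dim(u), dim(x))
    }
  })
  # shape compatibility guard
  p <- max_pool_with_indices(matrix(1:16 + 0, 4, 4))
  expect_error(max_unpool(matrix(0, 3, 3), p$record), "compatible")
})

test_that("prediction is slice-stateless with a >= threshold convention", {
  m <- build_runet(64, 2, seed = 3)
  withr::with_seed(53, sl <- matrix(stats::rnorm(64 * 64), 64, 64))
  vox <- array(0, c(4, 64, 64))
  for (s in 1:4) vox[s, , ] <- sl
  vol <- mr_volume(vox, c(1, 0.4, 0.4), subject_id = "dup")
  res <- predict_volume(m, vol, threshold = 0.5)
  expect_equal(dim(res$probability), c(4L, 64L, 64L))
  expect_true(all(res$probability >= 0 & res$probability <= 1))
  for (s in 2:4) expect_equal(res$probability[s, , ], res$probability[1, , ])
  expect_identical(res$mask$voxels,
                   binarize_probability(res$probability, 0.5))

  # boundary convention: probability equal to the threshold is foreground
  pr <- array(c(0.5, 0.49999, 0.50001, 0), c(1, 2, 2))
  expect_equal(as.vector(binarize_probability(pr, 0.5)), c(1, 0, 1, 0))

  bad <- mr_volume(array(0, c(2, 128, 128)), c(1, 0.2, 0.2))
  expect_error(predict_volume(m, bad), "does not match")
})

test_that("checkpoints round-trip parameters, state and predictions", {
  m <- build_runet(64, 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  save_runet(m, path)
  m2 <- load_runet(path)
  expect_equal(m2$params, m$params, tolerance = 1e-12)
  expect_equal(m2$state, m$state, tolerance = 1e-12)
  withr::with_seed(54, x <- array(stats::rnorm(64 * 64), c(64, 64, 1, 1)))
  o1 <- ratunet:::runet_forward(m, x)$output
  o2 <- ratunet:::runet_forward(m2, x)$output
  expect_equal(o1, o2, tolerance = 1e-12)
})
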