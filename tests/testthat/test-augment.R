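test_that("sampled parameters stay within the protocol bounds", {
  withr::with_seed(41, {
    draws <- replicate(10000, sample_augment_params(), simplify = FALSE)
  })
  sh <- vapply(draws, `[[`, 0, "shear_rad")
  ro <- vapply(draws, `[[`, 0, "rotation_deg")
  zo <- vapply(draws, `[[`, 0, "zoom_frac")
  hf <- vapply(draws, `[[`, NA, "hflip")
  expect_true(all(abs(sh) <= 0.3))
  expect_true(all(abs(ro) <= 30))
  expect_true(all(abs(zo) <= 0.2))
  expect_gte(mean(hf), 0.47)
  expect_lte(mean(hf), 0.53)
})

test_that("parameter draws are reproducible from the seed", {
  a <- withr::with_seed(7, replicate(50, sample_augment_params(),
                                     simplify = FALSE))
  b <- withr::with_seed(7, replicate(50, sample_augment_params(),
                                     simplify = FALSE))
  expect_identical(a, b)
})

test_that("identity parameters are a strict no-op and hflip is an involution", {
  withr::with_seed(42, img <- matrix(stats::rnorm(64 * 64), 64, 64))
  msk <- matrix(0, 64, 64); msk[20:45, 15:50] <- 1
  r <- apply_augment(img, msk, identity_augment_params())
  expect_identical(r$image, img)
  expect_identical(r$mask, msk)

  p <- identity_augment_params(); p$hflip <- TRUE
  once <- apply_augment(img, msk, p)
  twice <- apply_augment(once$image, once$mask, p)
  expect_identical(twice$mask, msk)
  expect_identical(twice$image, img)
  expect_false(identical(once$image, img))
})

test_that("rotation forward and back nearly restores a centred disk", {
  msk <- matrix((outer(1:64 - 32.5, 1:64 - 32.5,
                       function(a, b) a^2 + b^2) <= 18^2) * 1, 64, 64)
  img <- msk + 0.1
  p1 <- identity_augment_params(); p1$rotation_deg <- 30
  p2 <- identity_augment_params(); p2$rotation_deg <- -30
  fwd <- apply_augment(img, msk, p1)
  bck <- apply_augment(fwd$image, fwd$mask, p2)
  d <- dice(array(bck$mask, c(1, dim(msk))), array(msk, c(1, dim(msk))))
  expect_gte(d, 0.95)
})

test_that("every transform preserves mask binariness and shape", {
  withr::with_seed(43, {
    img <- matrix(stats::rnorm(64 * 64), 64, 64)
    msk <- matrix(0, 64, 64); msk[25:40, 20:44] <- 1
    for (i in 1:25) {
      p <- sample_augment_params()
      r <- apply_augment(img, msk, p)
      expect_identical(dim(r$image), dim(img))
      expect_identical(dim(r$mask), dim(msk))
      expect_true(all(r$mask %in% c(0, 1)))
    }
  })
  expect_error(apply_augment(matrix(0, 4, 4), matrix(0, 4, 5),
                             identity_augment_params()), "differ")
})

test_that("augment streams have the contracted length and are deterministic", {
  withr::with_seed(44, {
    pairs <- lapply(1:3, function(i)
      list(image = matrix(stats::rnorm(32 * 32), 32, 32),
           mask = {
             m <- matrix(0, 32, 32); m[8:24, 8:24] <- 1; m
           }))
  })
  s <- augment_stream(pairs, factor = 4, seed = 99)
  expect_equal(s$length, 12)
  all1 <- as.list(s)
  all2 <- as.list(augment_stream(pairs, factor = 4, seed = 99))
  expect_identical(all1, all2)
  expect_true(all(vapply(all1, function(p) all(p$mask %in% c(0, 1)), NA)))
  other <- as.list(augment_stream(pairs, factor = 4, seed = 100))
  expect_false(identical(all1, other))
  expect_error(augment_stream(list(), 2, 1), "non-empty")
  expect_error(augment_stream(pairs, 0, 1), ">= 1")
})
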