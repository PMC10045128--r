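test_that("soft dice loss reproduces closed-form values", {
  g <- array(0, c(1, 16, 16)); g[1, 3:12, 3:14] <- 1   # 120 voxels
  expect_lt(dice_loss(g, g), 1e-5)
  d <- array(0, c(1, 16, 16)); d[1, 14:16, 1:16] <- 1  # disjoint from g
  expect_gt(dice_loss(d, g), 1 - 1e-5)
  # soft example: p = {0.5, 0.5}, g = {1, 0} -> loss exactly 0.5 at eps = 0
  expect_equal(dice_loss(c(0.5, 0.5), c(1, 0), eps = 0), 0.5,
               tolerance = 1e-12)
  # both empty: smoothing defines loss 0
  z <- array(0, c(1, 4, 4))
  expect_equal(dice_loss(z, z), 0)
  expect_error(dice_loss(array(0, c(1, 2, 2)), array(0, c(1, 2, 3))),
               "differ")
})

test_that("dice loss gradient matches numerical differentiation", {
  withr::with_seed(61, {
    p <- array(stats::runif(32), c(4, 8))
    g <- array(as.numeric(stats::runif(32) < 0.4), c(4, 8))
  })
  ana <- ratunet:::dice_loss_grad(p, g)
  eps <- 1e-7
  for (i in c(1, 9, 20, 32)) {
    pp <- p; pp[i] <- pp[i] + eps
    pm <- p; pm[i] <- pm[i] - eps
    num <- (dice_loss(pp, g) - dice_loss(pm, g)) / (2 * eps)
    expect_equal(ana[i], num, tolerance = 1e-5)
  }
})

test_that("learning-rate schedule holds at 5e-4 then decays to 1e-4", {
  cfg <- train_config()
  expect_equal(learning_rate(1, cfg), 5e-4)
  expect_equal(learning_rate(20, cfg), 5e-4)
  expect_equal(learning_rate(100, cfg), 1e-4)
  expect_equal(learning_rate(60, cfg), 3e-4)   # linear midpoint of the decay
  expect_error(learning_rate(0, cfg), "outside")
  expect_error(learning_rate(101, cfg), "outside")
  step <- train_config(lr_schedule = "step")
  expect_equal(learning_rate(21, step), 1e-4)
  expect_equal(learning_rate(20, step), 5e-4)
})

test_that("6:2:2 split is subject-level, proportional, disjoint and seeded", {
  ids <- sprintf("S%03d", 1:55)
  sp <- split_subjects(ids, c(6, 2, 2), seed = 5)
  expect_equal(lengths(sp), c(train = 33L, validation = 11L, test = 11L))
  expect_setequal(unlist(sp), ids)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$validation, sp$test), 0)
  expect_identical(sp, split_subjects(ids, c(6, 2, 2), seed = 5))
  expect_false(identical(sp, split_subjects(ids, c(6, 2, 2), seed = 6)))
  expect_error(split_subjects(ids[1:2], c(6, 2, 2), 1), "at least")
  # leakage guard: slices inherit their subject's partition, so a subject id
  # can never occur in two partitions
  all_ids <- c(sp$train, sp$validation, sp$test)
  expect_equal(anyDuplicated(all_ids), 0L)
})

test_that("five folds cover every subject exactly once", {
  ids <- sprintf("S%03d", 1:55)
  folds <- make_folds(ids, 5, seed = 9)
  expect_length(folds, 5)
  val_sizes <- vapply(folds, function(f) length(f$validation), 0L)
  expect_true(all(val_sizes == 11L))
  expect_setequal(unlist(lapply(folds, `[[`, "validation")), ids)
  for (f in folds) {
    expect_length(intersect(f$train, f$validation), 0)
    expect_setequal(c(f$train, f$validation), ids)
  }
  expect_identical(folds, make_folds(ids, 5, seed = 9))
  expect_error(make_folds(ids, 1, 1), ">= 2")
  expect_error(make_folds(ids[1:3], 5, 1), "at least")
})

test_that("short phantom training runs are recorded, finite and improving", {
  subj <- lapply(1:2, small_phantom_pair)
  names(subj) <- c("a", "b")
  st <- compute_dataset_stats(lapply(subj, `[[`, "volume"))
  norm <- lapply(subj, function(s) {
    s$volume <- zscore_normalize(s$volume, st); s
  })
  pairs <- subjects_to_slices(norm)[1:16]
  cfg <- train_config(epochs = 5, batch_size = 8, seed = 17,
                      per_epoch_factor = 1)
  model <- build_runet(64, 4, seed = 17)
  fit <- train_runet(model, pairs, val_pairs = pairs[1:4], cfg)
  expect_equal(nrow(fit$history), 5)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_true(all(is.finite(fit$history$val_loss)))
  expect_lt(fit$history$train_loss[5], fit$history$train_loss[1])
  expect_error(train_runet(model, list(), list(), cfg), "empty")
})

test_that("training is bitwise deterministic given the seed", {
  subj <- small_phantom_pair(3)
  st <- compute_dataset_stats(list(subj$volume))
  vol <- zscore_normalize(subj$volume, st)
  pairs <- subjects_to_slices(list(list(volume = vol, mask = subj$mask)))[1:8]
  cfg <- train_config(epochs = 2, batch_size = 4, seed = 23,
                      per_epoch_factor = 1)
  f1 <- train_runet(build_runet(64, 4, seed = 23), pairs, pairs[1:2], cfg)
  f2 <- train_runet(build_runet(64, 4, seed = 23), pairs, pairs[1:2], cfg)
  expect_identical(f1$history$val_dice, f2$history$val_dice)
  expect_identical(f1$model$params, f2$model$params)
})
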