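#' Soft Dice loss
#'
#' The training loss is one minus the Dice coefficient evaluated in
#' differentiable soft form over all pixels of the batch jointly:
#' `kappa = (2 * sum(p*g) + eps) / (sum(p) + sum(g) + eps)`, `loss = 1 - kappa`.
#' The smoothing constant `eps` keeps the loss defined (and equal to 0) when
#' both prediction and target are empty.
#'
#' @param pred numeric array of probabilities in \[0, 1\].
#' @param gt binary array of the same shape.
#' @param eps smoothing constant (default `1e-6`); pass 0 for the exact
#'   unsmoothed form on non-empty masks.
#' @return Loss value in \[0, 1\].
#' @export
dice_loss <- function(pred, gt, eps = 1e-6) {
  if (!identical(dim(pred), dim(gt)) &&
      !(is.null(dim(pred)) && is.null(dim(gt)) &&
        length(pred) == length(gt)))
    stop("prediction and target shapes differ", call. = FALSE)
  num <- 2 * sum(pred * gt) + eps
  den <- sum(pred) + sum(gt) + eps
  if (den == 0) return(0)
  1 - num / den
}

# Gradient of dice_loss w.r.t. pred.
dice_loss_grad <- function(pred, gt, eps = 1e-6) {
  a <- sum(pred * gt)
  den <- sum(pred) + sum(gt) + eps
  -(2 * gt * den - (2 * a + eps)) / den^2
}

#' Training configuration
#'
#' Bundles the training protocol's hyper-parameters with their published
#' defaults: mini-batch 8, 100 epochs, Adam with learning rate 5e-4 decaying
#' to 1e-4 after epoch 20, subject split 6:2:2, five folds.
#'
#' @param batch_size mini-batch size.
#' @param epochs total epochs.
#' @param lr_initial,lr_final,lr_decay_start_epoch learning-rate schedule;
#'   see [learning_rate()].
#' @param lr_schedule `"linear"` (interpolate from `lr_initial` at the decay
#'   start to `lr_final` at the last epoch) or `"step"` (drop to `lr_final`
#'   immediately after the decay start).
#' @param split_ratios length-3 positive weights for train/validation/test.
#' @param folds number of cross-validation folds.
#' @param seed master seed; every source of randomness in a run (splits,
#'   weight init, shuffling, augmentation) derives from it.
#' @param per_epoch_factor fresh augmented variants per original slice per
#'   epoch (10 per epoch over 100 epochs realizes the protocol's 1000-fold
#'   expansion).
#' @param augment logical; disable to train on the raw slices.
#' @param dice_eps soft Dice smoothing constant.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 8L, epochs = 100L, lr_initial = 5e-4,
                         lr_final = 1e-4, lr_decay_start_epoch = 20L,
                         lr_schedule = c("linear", "step"),
                         split_ratios = c(6, 2, 2), folds = 5L, seed = 1L,
                         per_epoch_factor = 10L, augment = TRUE,
                         dice_eps = 1e-6) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(batch_size >= 1, epochs >= 1, lr_initial > 0, lr_final > 0,
            lr_final <= lr_initial, lr_decay_start_epoch >= 1,
            length(split_ratios) == 3, all(split_ratios > 0), folds >= 2,
            per_epoch_factor >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr_initial = lr_initial,
                 lr_final = lr_final,
                 lr_decay_start_epoch = as.integer(lr_decay_start_epoch),
                 lr_schedule = lr_schedule,
                 split_ratios = as.numeric(split_ratios),
                 folds = as.integer(folds), seed = as.integer(seed),
                 per_epoch_factor = as.integer(per_epoch_factor),
                 augment = isTRUE(augment), dice_eps = dice_eps),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' Constant at `lr_initial` up to and including `lr_decay_start_epoch`, then
#' either linearly interpolated down to `lr_final` at the final epoch
#' (default reading of a gradual decay) or stepped straight to `lr_final`.
#'
#' @param epoch 1-based epoch number, `1 <= epoch <= cfg$epochs`.
#' @param cfg a [train_config()].
#' @return The learning rate for that epoch.
#' @export
learning_rate <- function(epoch, cfg) {
  if (epoch < 1 || epoch > cfg$epochs)
    stop("epoch ", epoch, " outside 1..", cfg$epochs, call. = FALSE)
  if (epoch <= cfg$lr_decay_start_epoch) return(cfg$lr_initial)
  if (cfg$lr_schedule == "step") return(cfg$lr_final)
  frac <- (epoch - cfg$lr_decay_start_epoch) /
    (cfg$epochs - cfg$lr_decay_start_epoch)
  cfg$lr_initial + frac * (cfg$lr_final - cfg$lr_initial)
}

#' Subject-level train/validation/test split
#'
#' Partitions subject identifiers (never individual slices, guarding against
#' leakage of a subject across partitions) into disjoint, exhaustive sets
#' with sizes proportional to `ratios` under largest-remainder rounding.
#' Deterministic given `seed`.
#'
#' @param subject_ids character or integer vector of unique subject ids.
#' @param ratios length-3 positive weights (default 6:2:2).
#' @param seed integer seed.
#' @return A list with `train`, `validation`, `test` id vectors.
#' @export
split_subjects <- function(subject_ids, ratios = c(6, 2, 2), seed = 1L) {
  n <- length(subject_ids)
  if (anyDuplicated(subject_ids)) stop("subject ids must be unique",
                                       call. = FALSE)
  if (n < length(ratios))
    stop("need at least ", length(ratios), " subjects, got ", n,
         call. = FALSE)
  q <- n * ratios / sum(ratios)
  sizes <- floor(q)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(q - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  perm <- withr::with_seed(seed, sample(subject_ids))
  cut1 <- sizes[1]; cut2 <- sizes[1] + sizes[2]
  list(train = perm[seq_len(cut1)],
       validation = perm[(cut1 + 1):cut2],
       test = perm[(cut2 + 1):n])
}

#' Subject-level k-fold assignment
#'
#' Every subject appears in exactly one validation fold; fold sizes differ
#' by at most one.  Deterministic given `seed`.
#'
#' @param subject_ids unique subject ids.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return A list of `k` elements, each a list with `train` and `validation`
#'   id vectors.
#' @export
make_folds <- function(subject_ids, k = 5L, seed = 1L) {
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  n <- length(subject_ids)
  if (n < k) stop("need at least ", k, " subjects", call. = FALSE)
  perm <- withr::with_seed(seed, sample(subject_ids))
  fold_of <- rep(seq_len(k), length.out = n)
  lapply(seq_len(k), function(f)
    list(train = perm[fold_of != f], validation = perm[fold_of == f]))
}

# Assemble a list of slice pairs into H x W x 1 x B arrays.
.batch_arrays <- function(pairs, idx) {
  d <- dim(pairs[[idx[1]]]$image)
  nb <- length(idx)
  x <- array(0, c(d[1], d[2], 1L, nb))
  g <- array(0, c(d[1], d[2], 1L, nb))
  for (j in seq_along(idx)) {
    x[, , 1L, j] <- pairs[[idx[j]]]$image
    g[, , 1L, j] <- pairs[[idx[j]]]$mask
  }
  list(x = x, g = g)
}

.adam_init <- function(params) {
  list(m = lapply(params, function(p) lapply(p, function(v) v * 0)),
       v = lapply(params, function(p) lapply(p, function(v) v * 0)),
       t = 0L)
}

.adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) {
      g <- grads[[nm]][[f]]
      m <- beta1 * opt$m[[nm]][[f]] + (1 - beta1) * g
      v <- beta2 * opt$v[[nm]][[f]] + (1 - beta2) * g^2
      opt$m[[nm]][[f]] <- m
      opt$v[[nm]][[f]] <- v
      params[[nm]][[f]] <- params[[nm]][[f]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(params = params, opt = opt)
}

# Forward a set of slice pairs in inference mode; returns loss/dice/accuracy.
.evaluate_slices <- function(model, pairs, batch_size, dice_eps) {
  n <- length(pairs)
  idxs <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  tot_loss <- 0; inter <- 0; psum <- 0; gsum <- 0; correct <- 0; voxels <- 0
  for (idx in idxs) {
    b <- .batch_arrays(pairs, idx)
    out <- runet_forward(model, b$x, training = FALSE)$output
    tot_loss <- tot_loss + dice_loss(out, b$g, dice_eps) * length(idx)
    hard <- binarize_probability(out, 0.5)
    inter <- inter + sum(hard * b$g)
    psum <- psum + sum(hard); gsum <- gsum + sum(b$g)
    correct <- correct + sum(hard == b$g)
    voxels <- voxels + length(b$g)
  }
  list(loss = tot_loss / n,
       dice = if (psum + gsum == 0) 1 else 2 * inter / (psum + gsum),
       accuracy = correct / voxels)
}

#' Train an RU-Net with the Dice-loss protocol
#'
#' Optimizes the soft Dice loss with Adam over mini-batches of augmented
#' slices, with the decaying learning-rate schedule of [learning_rate()].
#' Per-epoch training and validation loss, hard Dice and pixel accuracy are
#' recorded; the returned model carries the parameters of the epoch with the
#' best validation Dice.  All randomness (shuffling, augmentation) derives
#' from `cfg$seed`.
#'
#' @param model a freshly built [build_runet()] model.
#' @param train_pairs list of slice pairs (`$image`, `$mask`, both 2-D and
#'   already z-score normalized).
#' @param val_pairs list of validation slice pairs (never augmented); may be
#'   empty, in which case model selection falls back to the last epoch.
#' @param cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return A list with `model` (trained) and `history` (data.frame with one
#'   row per epoch).
#' @export
train_runet <- function(model, train_pairs, val_pairs = list(),
                        cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "runet"), inherits(cfg, "train_config"))
  if (length(train_pairs) == 0) stop("empty training set", call. = FALSE)
  opt <- .adam_init(model$params)
  hist <- vector("list", cfg$epochs)
  best <- list(dice = -Inf, params = NULL, state = NULL)

  withr::with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- learning_rate(epoch, cfg)
      if (cfg$augment) {
        stream <- augment_stream(train_pairs, cfg$per_epoch_factor,
                                 seed = sample.int(.Machine$integer.max, 1))
        epoch_pairs <- as.list(stream)
      } else {
        epoch_pairs <- rep(train_pairs, cfg$per_epoch_factor)
      }
      ord <- sample(length(epoch_pairs))
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_loss <- 0; inter <- 0; psum <- 0; gsum <- 0
      correct <- 0; voxels <- 0
      for (idx in batches) {
        b <- .batch_arrays(epoch_pairs, idx)
        fwd <- runet_forward(model, b$x, training = TRUE)
        model$state <- fwd$state
        loss <- dice_loss(fwd$output, b$g, cfg$dice_eps)
        if (!is.finite(loss))
          stop("non-finite loss at epoch ", epoch,
               "; training diverged", call. = FALSE)
        gout <- dice_loss_grad(fwd$output, b$g, cfg$dice_eps)
        pg <- runet_backward(model, fwd, gout)
        upd <- .adam_step(model$params, pg, opt, lr)
        model$params <- upd$params
        opt <- upd$opt
        ep_loss <- ep_loss + loss * length(idx)
        hard <- binarize_probability(fwd$output, 0.5)
        inter <- inter + sum(hard * b$g)
        psum <- psum + sum(hard); gsum <- gsum + sum(b$g)
        correct <- correct + sum(hard == b$g)
        voxels <- voxels + length(b$g)
      }
      tr <- list(loss = ep_loss / length(epoch_pairs),
                 dice = if (psum + gsum == 0) 1 else 2 * inter / (psum + gsum),
                 accuracy = correct / voxels)
      va <- if (length(val_pairs))
        .evaluate_slices(model, val_pairs, cfg$batch_size, cfg$dice_eps)
      else list(loss = NA_real_, dice = NA_real_, accuracy = NA_real_)
      hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                  train_loss = tr$loss, train_dice = tr$dice,
                                  train_accuracy = tr$accuracy,
                                  val_loss = va$loss, val_dice = va$dice,
                                  val_accuracy = va$accuracy)
      if (verbose)
        message(sprintf(
          "epoch %3d  lr %.2e  train loss %.4f dice %.4f  val loss %s dice %s",
          epoch, lr, tr$loss, tr$dice,
          formatC(va$loss, format = "f", digits = 4),
          formatC(va$dice, format = "f", digits = 4)))
      sel_dice <- if (length(val_pairs)) va$dice else tr$dice
      if (is.finite(sel_dice) && sel_dice >= best$dice) {
        best$dice <- sel_dice
        best$params <- model$params
        best$state <- model$state
      }
    }
  })
  if (!is.null(best$params)) {
    model$params <- best$params
    model$state <- best$state
  }
  list(model = model, history = do.call(rbind, hist))
}

#' Subject-level k-fold cross-validation on slice data
#'
#' Runs [train_runet()] on each fold's training subjects and evaluates hard
#' Dice on the fold's held-out subjects.
#'
#' @param subjects named list: each element has `$volume` (normalized
#'   [mr_volume()]) and `$mask` ([binary_mask()]).
#' @param cfg a [train_config()].
#' @param input_size,base_channels network geometry for each fold's model.
#' @param verbose forwarded to [train_runet()].
#' @return A data.frame with one row per fold (`fold`, `n_train`, `n_val`,
#'   `val_dice`, `val_loss`) and attribute `"histories"`.
#' @export
crossval_runet <- function(subjects, cfg = train_config(), input_size,
                           base_channels, verbose = FALSE) {
  ids <- names(subjects)
  stopifnot(length(ids) >= cfg$folds)
  folds <- make_folds(ids, cfg$folds, cfg$seed)
  seeds <- withr::with_seed(cfg$seed,
                            sample.int(.Machine$integer.max, cfg$folds))
  rows <- list(); hists <- list()
  for (f in seq_along(folds)) {
    tr_pairs <- subjects_to_slices(subjects[folds[[f]]$train])
    va_pairs <- subjects_to_slices(subjects[folds[[f]]$validation])
    model <- build_runet(input_size, base_channels, seed = seeds[f])
    fit <- train_runet(model, tr_pairs, va_pairs, cfg, verbose = verbose)
    last <- fit$history[nrow(fit$history), ]
    best <- max(fit$history$val_dice, na.rm = TRUE)
    rows[[f]] <- data.frame(fold = f,
                            n_train = length(folds[[f]]$train),
                            n_val = length(folds[[f]]$validation),
                            val_dice = best, val_loss = last$val_loss)
    hists[[f]] <- fit$history
  }
  out <- do.call(rbind, rows)
  attr(out, "histories") <- hists
  out
}

#' Flatten subject volumes into 2-D slice pairs
#'
#' @param subjects list of elements with `$volume` and `$mask`.
#' @return A list of `$image` / `$mask` slice pairs.
#' @export
subjects_to_slices <- function(subjects) {
  out <- list()
  for (s in subjects) {
    d <- dim(s$volume$voxels)
    for (k in seq_len(d[1]))
      out[[length(out) + 1L]] <- list(image = s$volume$voxels[k, , ],
                                      mask = s$mask$voxels[k, , ])
  }
  out
}
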