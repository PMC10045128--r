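#' Build the RU-Net segmentation network
#'
#' Constructs the full U-shaped encoder-decoder graph with batch-normalized
#' pre-activation residual blocks and pooling-index transmission:
#'
#' * Encoder level 0 (N x N): a 3x3 convolution lifts the single input
#'   channel to `base_channels`, followed by two blocks
#'   (BN -> ReLU -> 3x3 conv) and a residual addition of the initial
#'   convolution output with the second block output.
#' * Encoder level 1 (N/2): 2x2 stride-2 max pooling (argmax indices
#'   stored), two blocks, residual addition of the pool output and the block
#'   output.
#' * Encoder levels 2-4 (N/4 .. N/16): max pooling, three blocks, residual
#'   addition.
#' * A fifth max pooling reaches N/32.
#' * Decoder levels at N/16 .. N/2: max-unpooling driven by the matching
#'   pool's stored indices (deepest pool feeds the first unpool),
#'   concatenation with the corresponding encoder addition output (double
#'   channel structure), one channel-reducing block, three more blocks, and
#'   a residual addition of the reducing block's output with the third
#'   block's output.
#' * Final level at N: unpooling with the first pool's indices,
#'   concatenation with the encoder level-0 addition, one reducing block,
#'   one sigmoid-activated block, and a final 1x1 convolution consolidating
#'   all channels into a single probability map.  A sigmoid maps the 1x1
#'   convolution output into \[0, 1\] (a linear layer alone cannot bound it).
#'
#' At any valid input size and width the graph contains exactly 33
#' convolutions (14 encoder-side, 19 decoder-side including the final 1x1),
#' 5 max-pooling and 5 unpooling layers.
#'
#' @param input_size in-plane image size N; must be divisible by 32.
#' @param base_channels channel width C of the first level (64 at published
#'   fidelity; smaller widths are structurally identical and train quickly
#'   on a desktop CPU).
#' @param seed optional integer; when given, weight initialization
#'   (He-style normal for convolutions) is reproducible.
#' @return An object of class `runet`: a computational graph (`$nodes`),
#'   parameters (`$params`), batch-norm running state (`$state`) and a
#'   `$spec` summary.  See [network_inventory()].
#' @export
build_runet <- function(input_size, base_channels = 64L, seed = NULL) {
  input_size <- as.integer(input_size)
  if (is.na(input_size) || input_size < 32L || input_size %% 32L != 0L)
    stop("`input_size` must be a positive multiple of 32, got ", input_size,
         call. = FALSE)
  C <- as.integer(base_channels)
  if (is.na(C) || C < 1L) stop("`base_channels` must be >= 1", call. = FALSE)

  env <- new.env(parent = emptyenv())
  env$nodes <- list(); env$params <- list(); env$state <- list()
  env$pcount <- 0L

  node <- function(op, inputs = integer(), phase, level, channels,
                   kernel = NULL, param = NULL, pool_pair = NA_integer_,
                   cin = NULL) {
    id <- length(env$nodes) + 1L
    env$nodes[[id]] <- list(id = id, op = op, inputs = as.integer(inputs),
                            phase = phase, level = level,
                            channels = channels, kernel = kernel,
                            param = param, pool_pair = pool_pair, cin = cin)
    id
  }
  conv_param <- function(name, kh, kw, cin, cout) {
    k <- kh * kw * cin
    sd <- sqrt(2 / k)  # He initialization for ReLU-family networks
    env$params[[name]] <- list(W = matrix(stats::rnorm(k * cout, 0, sd),
                                          k, cout),
                               b = rep(0, cout))
  }
  bn_param <- function(name, c) {
    env$params[[name]] <- list(gamma = rep(1, c), beta = rep(0, c))
    env$state[[name]] <- list(mean = rep(0, c), var = rep(1, c))
  }
  conv <- function(input, cin, cout, phase, level, k = 3L) {
    env$pcount <- env$pcount + 1L
    nm <- sprintf("conv%02d", env$pcount)
    conv_param(nm, k, k, cin, cout)
    node("conv", input, phase, level, cout, kernel = c(k, k), param = nm,
         cin = cin)
  }
  block <- function(input, cin, cout, phase, level, activation = "relu") {
    env$pcount <- env$pcount + 1L
    nm <- sprintf("bn%02d", env$pcount)
    bn_param(nm, cin)
    b <- node("bn", input, phase, level, cin, param = nm)
    a <- node(activation, b, phase, level, cin)
    conv(a, cin, cout, phase, level)
  }

  init <- function() {
    inp <- node("input", integer(), "encoder", 0L, 1L)

    # ---- encoder ----
    enc_adds <- integer(5)   # addition outputs at levels 0..4 (N .. N/16)
    pools <- integer(5)
    c0 <- conv(inp, 1L, C, "encoder", 0L)
    x <- block(c0, C, C, "encoder", 0L)
    x <- block(x, C, C, "encoder", 0L)
    enc_adds[1] <- node("add", c(c0, x), "encoder", 0L, C)
    nblocks <- c(2L, 3L, 3L, 3L)
    for (lev in 1:4) {
      p <- node("pool", enc_adds[lev], "encoder", lev, C)
      pools[lev] <- p
      x <- p
      for (i in seq_len(nblocks[lev])) x <- block(x, C, C, "encoder", lev)
      enc_adds[lev + 1] <- node("add", c(p, x), "encoder", lev, C)
    }
    pools[5] <- node("pool", enc_adds[5], "encoder", 5L, C)

    # ---- decoder ----
    x <- pools[5]
    for (lev in 4:1) {
      # deepest pool pairs with the first unpool, and so on outward
      u <- node("unpool", x, "decoder", lev, C, pool_pair = pools[lev + 1])
      cc <- node("concat", c(u, enc_adds[lev + 1]), "decoder", lev, 2L * C)
      r <- block(cc, 2L * C, C, "decoder", lev)
      x <- r
      for (i in 1:3) x <- block(x, C, C, "decoder", lev)
      x <- node("add", c(r, x), "decoder", lev, C)
    }
    u <- node("unpool", x, "decoder", 0L, C, pool_pair = pools[1])
    cc <- node("concat", c(u, enc_adds[1]), "decoder", 0L, 2L * C)
    x <- block(cc, 2L * C, C, "decoder", 0L)
    x <- block(x, C, C, "decoder", 0L, activation = "sigmoid")
    x <- conv(x, C, 1L, "decoder", 0L, k = 1L)
    node("sigmoid", x, "decoder", 0L, 1L)
  }
  if (is.null(seed)) init() else withr::with_seed(seed, init())

  model <- structure(list(nodes = env$nodes, params = env$params,
                          state = env$state, input_size = input_size,
                          base_channels = C),
                     class = "runet")
  model$spec <- network_inventory(model)
  model
}

#' Layer inventory of a network by graph traversal
#'
#' Walks the instantiated computational graph and counts operations by type
#' and by phase, the structural signature of the architecture.
#'
#' @param model a `runet` object.
#' @return A list with `conv_total`, `pool`, `unpool`, `bn`, `activation`,
#'   `conv_encoder`, `conv_decoder`, `input_size`, `base_channels`.
#' @export
network_inventory <- function(model) {
  stopifnot(inherits(model, "runet"))
  ops <- vapply(model$nodes, `[[`, "", "op")
  phase <- vapply(model$nodes, `[[`, "", "phase")
  list(conv_total = sum(ops == "conv"),
       pool = sum(ops == "pool"),
       unpool = sum(ops == "unpool"),
       bn = sum(ops == "bn"),
       activation = sum(ops %in% c("relu", "sigmoid")),
       conv_encoder = sum(ops == "conv" & phase == "encoder"),
       conv_decoder = sum(ops == "conv" & phase == "decoder"),
       input_size = model$input_size,
       base_channels = model$base_channels)
}

#' @export
print.runet <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<runet> N=%d, width %d: %d conv (%d encoder + %d decoder), %d pool, %d unpool, %d BN\n",
    s$input_size, s$base_channels, s$conv_total, s$conv_encoder,
    s$conv_decoder, s$pool, s$unpool, s$bn))
  invisible(x)
}

# Coerce a feature map to H x W x C x B, remembering the original rank.
.as_feature4 <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  else if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  else if (length(dim(x)) != 4L)
    stop("expected a 2-D, 3-D or 4-D feature map", call. = FALSE)
  x
}

#' Max pooling with stored argmax indices
#'
#' 2x2 stride-2 max pooling over non-overlapping windows; for every window
#' and channel the position of the maximum is recorded (ties break to the
#' first position in row-major window order) so that the paired
#' [max_unpool()] can scatter decoder features back to the encoder's salient
#' locations — the pooling-index transmission mechanism.
#'
#' @param feature a 2-D, `H x W x C` or `H x W x C x B` numeric array with
#'   even spatial dimensions.
#' @return A list with `pooled` (same rank as the input, halved spatial
#'   dims) and `record` (class `pool_record`: 0-based linear argmax indices
#'   plus the input dimensions).
#' @export
max_pool_with_indices <- function(feature) {
  rank <- if (is.matrix(feature)) 2L else length(dim(feature))
  x <- .as_feature4(feature)
  d <- dim(x)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
    stop("spatial dimensions must be even, got ", d[1], "x", d[2],
         call. = FALSE)
  r <- maxpool2_fwd(x)
  pooled <- r$y
  keep <- switch(rank, NULL, dim(pooled)[1:2], dim(pooled)[1:3], dim(pooled))
  dim(pooled) <- keep
  record <- structure(list(indices = r$idx, input_dim = d), class = "pool_record")
  list(pooled = pooled, record = record)
}

#' Max unpooling from a pooling record
#'
#' Scatters pooled values back to the argmax positions stored in `record`;
#' every other position is zero and the spatial dimensions double.
#'
#' @param pooled output of [max_pool_with_indices()] (any processing that
#'   preserves its shape may have been applied).
#' @param record the matching `pool_record`.
#' @return An array with the record's original input dimensions (rank
#'   matching `pooled`).
#' @export
max_unpool <- function(pooled, record) {
  stopifnot(inherits(record, "pool_record"))
  rank <- if (is.matrix(pooled)) 2L else length(dim(pooled))
  x <- .as_feature4(pooled)
  if (length(x) != length(record$indices))
    stop("pooled map is not shape-compatible with the pooling record",
         call. = FALSE)
  y <- scatter_to(x, record$indices, as.integer(record$input_dim))
  d <- dim(y)
  keep <- switch(rank, NULL, d[1:2], d[1:3], d)
  dim(y) <- keep
  y
}

# Forward pass over the graph.  x: H x W x 1 x B.  Returns the final output
# plus per-node values and caches (needed for backprop), and the possibly
# updated batch-norm state.
runet_forward <- function(model, x, training = FALSE,
                          bn_eps = 1e-5, bn_momentum = 0.1) {
  nodes <- model$nodes
  nv <- length(nodes)
  vals <- vector("list", nv)
  caches <- vector("list", nv)
  st <- model$state
  for (nd in nodes) {
    v <- switch(nd$op,
      input = x,
      conv = {
        p <- model$params[[nd$param]]
        conv2d_fwd(vals[[nd$inputs]], p$W, p$b, nd$kernel[1], nd$kernel[2])
      },
      bn = {
        p <- model$params[[nd$param]]
        s <- st[[nd$param]]
        r <- bn_fwd(vals[[nd$inputs]], p$gamma, p$beta, s$mean, s$var,
                    bn_eps, bn_momentum, training)
        if (training)
          st[[nd$param]] <- list(mean = r$running_mean, var = r$running_var)
        caches[[nd$id]] <- list(xhat = r$xhat, istd = r$istd)
        r$y
      },
      relu = relu_fwd(vals[[nd$inputs]]),
      sigmoid = 1 / (1 + exp(-vals[[nd$inputs]])),
      pool = {
        r <- maxpool2_fwd(vals[[nd$inputs]])
        caches[[nd$id]] <- list(idx = r$idx,
                                indim = dim(vals[[nd$inputs]]))
        r$y
      },
      unpool = {
        pc <- caches[[nd$pool_pair]]
        scatter_to(vals[[nd$inputs]], pc$idx, as.integer(pc$indim))
      },
      add = vals[[nd$inputs[1]]] + vals[[nd$inputs[2]]],
      concat = {
        v1 <- vals[[nd$inputs[1]]]; v2 <- vals[[nd$inputs[2]]]
        d1 <- dim(v1); d2 <- dim(v2)
        y <- array(0, c(d1[1], d1[2], d1[3] + d2[3], d1[4]))
        y[, , seq_len(d1[3]), ] <- v1
        y[, , d1[3] + seq_len(d2[3]), ] <- v2
        y
      },
      stop("unknown op: ", nd$op))
    vals[[nd$id]] <- v
  }
  list(output = vals[[nv]], vals = vals, caches = caches, state = st)
}

# Backward pass: gout is the gradient of the loss w.r.t. the final output.
# Returns per-parameter gradients (same nesting as model$params).
runet_backward <- function(model, fwd, gout) {
  nodes <- model$nodes
  nv <- length(nodes)
  grads <- vector("list", nv)
  grads[[nv]] <- gout
  pgrads <- list()
  acc <- function(i, g) {
    grads[[i]] <<- if (is.null(grads[[i]])) g else grads[[i]] + g
  }
  pacc <- function(name, lst) {
    cur <- pgrads[[name]]
    pgrads[[name]] <<- if (is.null(cur)) lst
      else Map(`+`, cur, lst)
  }
  for (nd in rev(nodes)) {
    g <- grads[[nd$id]]
    if (is.null(g)) next
    switch(nd$op,
      input = NULL,
      conv = {
        p <- model$params[[nd$param]]
        r <- conv2d_bwd(fwd$vals[[nd$inputs]], p$W, g,
                        nd$kernel[1], nd$kernel[2])
        pacc(nd$param, list(W = r$gW, b = as.numeric(r$gb)))
        acc(nd$inputs, r$gx)
      },
      bn = {
        p <- model$params[[nd$param]]
        cc <- fwd$caches[[nd$id]]
        r <- bn_bwd(cc$xhat, g, p$gamma, cc$istd)
        pacc(nd$param, list(gamma = as.numeric(r$ggamma),
                            beta = as.numeric(r$gbeta)))
        acc(nd$inputs, r$gx)
      },
      relu = acc(nd$inputs, relu_bwd(fwd$vals[[nd$inputs]], g)),
      sigmoid = {
        y <- fwd$vals[[nd$id]]
        acc(nd$inputs, g * y * (1 - y))
      },
      pool = {
        cc <- fwd$caches[[nd$id]]
        acc(nd$inputs, scatter_to(g, cc$idx, as.integer(cc$indim)))
      },
      unpool = {
        pc <- fwd$caches[[nd$pool_pair]]
        acc(nd$inputs,
            gather_from(g, pc$idx, dim(fwd$vals[[nd$inputs]])))
      },
      add = {
        acc(nd$inputs[1], g)
        acc(nd$inputs[2], g)
      },
      concat = {
        d1 <- dim(fwd$vals[[nd$inputs[1]]])
        acc(nd$inputs[1], g[, , seq_len(d1[3]), , drop = FALSE])
        acc(nd$inputs[2],
            g[, , (d1[3] + 1):dim(g)[3], , drop = FALSE])
      })
    grads[nd$id] <- list(NULL)  # release memory as we walk back
  }
  pgrads
}

#' Binarize a probability map
#'
#' Foreground where `probability >= threshold` (the boundary value counts as
#' foreground).
#'
#' @param probability numeric array in \[0, 1\].
#' @param threshold fraction in \[0, 1\].
#' @return A `{0,1}` array of the same shape.
#' @export
binarize_probability <- function(probability, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  (probability >= threshold) * 1
}

#' Segment an MR volume slice-by-slice
#'
#' Runs every coronal slice of a z-score-normalized volume through the
#' network (inference mode: batch-norm uses running statistics), stacks the
#' per-slice probability maps and thresholds them into a brain mask.
#'
#' @param model a trained `runet`.
#' @param volume an [mr_volume()] whose in-plane size equals the model's
#'   `input_size`; expected to be normalized with the training-set
#'   statistics.
#' @param threshold binarization threshold (default 0.5).
#' @param keep_largest_component if `TRUE`, retain only the largest in-plane
#'   connected component per slice (off by default).
#' @return A list of class `segmentation_result` with `probability`
#'   (slices x rows x cols array in \[0,1\]), `mask` (a [binary_mask()]) and
#'   `threshold`.
#' @export
predict_volume <- function(model, volume, threshold = 0.5,
                           keep_largest_component = FALSE) {
  stopifnot(inherits(model, "runet"), inherits(volume, "mr_volume"))
  d <- dim(volume$voxels)
  if (d[2] != model$input_size)
    stop("volume in-plane size ", d[2], " does not match model input size ",
         model$input_size, call. = FALSE)
  nb <- d[1]
  x <- array(0, c(d[2], d[3], 1L, nb))
  for (s in seq_len(nb)) x[, , 1L, s] <- volume$voxels[s, , ]
  out <- runet_forward(model, x, training = FALSE)$output
  prob <- array(0, d)
  for (s in seq_len(nb)) prob[s, , ] <- out[, , 1L, s]
  maskarr <- binarize_probability(prob, threshold)
  if (keep_largest_component) {
    for (s in seq_len(nb)) {
      sl <- maskarr[s, , ]
      if (sum(sl) == 0) next
      lab <- EBImage::bwlabel(sl)
      tab <- tabulate(lab[lab > 0])
      maskarr[s, , ] <- (lab == which.max(tab)) * 1
    }
  }
  structure(list(probability = prob,
                 mask = binary_mask(maskarr, volume$spacing_mm,
                                    subject_id = volume$subject_id),
                 threshold = threshold),
            class = "segmentation_result")
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a plain-text JSON file holding every parameter, the
#' batch-norm running state and the architecture spec; portable and
#' human-inspectable, at the cost of size for wide networks.
#'
#' @param model a `runet`.
#' @param path output `.json` path.
#' @export
save_runet <- function(model, path) {
  payload <- list(input_size = model$input_size,
                  base_channels = model$base_channels,
                  spec = model$spec,
                  params = model$params,
                  state = model$state)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_runet
#' @return `load_runet` returns the restored `runet`.
#' @export
load_runet <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- build_runet(payload$input_size, payload$base_channels)
  for (nm in names(model$params)) {
    p <- payload$params[[nm]]
    if (!is.null(p$W)) {
      model$params[[nm]]$W <- matrix(as.numeric(p$W),
                                     nrow(model$params[[nm]]$W),
                                     ncol(model$params[[nm]]$W))
      model$params[[nm]]$b <- as.numeric(p$b)
    } else {
      model$params[[nm]]$gamma <- as.numeric(p$gamma)
      model$params[[nm]]$beta <- as.numeric(p$beta)
    }
  }
  for (nm in names(model$state))
    model$state[[nm]] <- list(mean = as.numeric(payload$state[[nm]]$mean),
                              var = as.numeric(payload$state[[nm]]$var))
  model
}
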