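#' Sample a random augmentation parameter set
#'
#' Draws one set of geometric augmentation parameters from the training
#' protocol's ranges: shear angle uniform in \[-0.3, 0.3\] rad, rotation
#' uniform in \[-30, 30\] degrees, isotropic zoom uniform in \[-20%, +20%\],
#' and a horizontal reflection with probability 1/2.  Draws come from R's
#' global RNG, so seed with `set.seed()` (or [withr::with_seed()]) for
#' reproducibility.
#'
#' @param shear_max_rad,rotation_max_deg,zoom_max_frac half-widths of the
#'   uniform ranges.
#' @param hflip logical; if `FALSE` the reflection is disabled.
#' @return A list of class `augment_params` with fields `shear_rad`,
#'   `rotation_deg`, `zoom_frac`, `hflip`.
#' @export
sample_augment_params <- function(shear_max_rad = 0.3, rotation_max_deg = 30,
                                  zoom_max_frac = 0.2, hflip = TRUE) {
  structure(list(shear_rad = stats::runif(1, -shear_max_rad, shear_max_rad),
                 rotation_deg = stats::runif(1, -rotation_max_deg,
                                             rotation_max_deg),
                 zoom_frac = stats::runif(1, -zoom_max_frac, zoom_max_frac),
                 hflip = hflip && (stats::runif(1) < 0.5)),
            class = "augment_params")
}

#' Identity augmentation parameters
#' @return An `augment_params` object that makes [apply_augment()] a no-op.
#' @export
identity_augment_params <- function() {
  structure(list(shear_rad = 0, rotation_deg = 0, zoom_frac = 0,
                 hflip = FALSE),
            class = "augment_params")
}

# Composite 2x2 linear map: shear, then rotation, then zoom, all about the
# image centre.  Coordinates are (row, col).
.augment_linear_map <- function(params) {
  sh <- matrix(c(1, 0, tan(params$shear_rad), 1), 2, 2)
  th <- params$rotation_deg * pi / 180
  ro <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  s <- 1 + params$zoom_frac
  zo <- diag(c(s, s))
  zo %*% ro %*% sh
}

.warp_slice <- function(slice, A, bilinear) {
  d <- dim(slice)
  ctr <- (d + 1) / 2
  # EBImage transforms row vectors: p_out = p_in %*% m[1:2,] + m[3,]
  m <- rbind(t(A), ctr - as.vector(ctr %*% t(A)))
  EBImage::imageData(EBImage::affine(
    EBImage::Image(slice), m,
    filter = if (bilinear) "bilinear" else "none",
    output.dim = d, bg.col = 0))
}

#' Apply one augmentation to a paired image/mask slice
#'
#' A single affine transform (shear, then rotation, then zoom, about the
#' image centre) is applied identically to both slices, followed by an
#' optional horizontal reflection (exact column reversal).  The image is
#' interpolated bilinearly, the mask by nearest neighbour; out-of-frame
#' regions are zero-filled and the output shape equals the input shape.
#' Identity parameters are a strict no-op.
#'
#' @param image 2-D numeric intensity slice.
#' @param mask 2-D binary slice of the same shape.
#' @param params an `augment_params` object.
#' @return A list with transformed `image` and `mask`.
#' @export
apply_augment <- function(image, mask, params) {
  if (!identical(dim(image), dim(mask)))
    stop("image and mask shapes differ", call. = FALSE)
  stopifnot(inherits(params, "augment_params"))
  img <- image; msk <- mask
  geometric <- params$shear_rad != 0 || params$rotation_deg != 0 ||
    params$zoom_frac != 0
  if (geometric) {
    A <- .augment_linear_map(params)
    img <- .warp_slice(img, A, bilinear = TRUE)
    msk <- .warp_slice(msk, A, bilinear = FALSE)
    msk <- (msk >= 0.5) * 1  # nearest-neighbour output; re-assert {0,1}
  }
  if (params$hflip) {
    img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
    msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
  }
  list(image = img, mask = msk)
}

#' Deterministic stream of augmented slice pairs
#'
#' Produces `factor * length(pairs)` augmented image/mask pairs, each from a
#' fresh random parameter draw, fully reproducible from `seed`.  Parameters
#' for the whole stream are drawn up-front (they are 4 numbers per item);
#' warps are applied lazily when an item is requested.
#'
#' The acquisition protocol this emulates expands the training data by a
#' factor of 1000 over the course of training; realized on the fly that is
#' `per_epoch_factor` fresh variants per original slice per epoch.
#'
#' @param pairs non-empty list of lists with components `image` and `mask`.
#' @param factor number of augmented variants per original pair.
#' @param seed integer seed for the parameter draws.
#' @param shear_max_rad,rotation_max_deg,zoom_max_frac,hflip range settings
#'   passed to [sample_augment_params()].
#' @return An object of class `augment_stream`: use `x$length`, `x$get(i)`
#'   to retrieve the i-th augmented pair, or [as.list()] to materialize all.
#' @export
augment_stream <- function(pairs, factor, seed, shear_max_rad = 0.3,
                           rotation_max_deg = 30, zoom_max_frac = 0.2,
                           hflip = TRUE) {
  if (length(pairs) == 0) stop("`pairs` must be non-empty", call. = FALSE)
  if (factor < 1) stop("`factor` must be >= 1", call. = FALSE)
  n <- length(pairs) * factor
  src <- rep(seq_along(pairs), times = factor)
  params <- withr::with_seed(seed, lapply(seq_len(n), function(i)
    sample_augment_params(shear_max_rad, rotation_max_deg, zoom_max_frac,
                          hflip)))
  get <- function(i) {
    stopifnot(i >= 1, i <= n)
    p <- pairs[[src[i]]]
    apply_augment(p$image, p$mask, params[[i]])
  }
  structure(list(length = n, get = get, source_index = src, params = params),
            class = "augment_stream")
}

#' @export
as.list.augment_stream <- function(x, ...) {
  lapply(seq_len(x$length), x$get)
}
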