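#' MR volume container
#'
#' A light S3 container for a single-channel 3-D MR acquisition: a
#' `slices x rows x cols` intensity array plus physical voxel spacing in mm
#' and a modality tag.  In-plane dimensions must be square and divisible by
#' 32, the spatial granularity the segmentation network's five pooling
#' levels (plus one extra pool) require.
#'
#' @param voxels numeric 3-D array, `slices x rows x cols`, all finite.
#' @param spacing_mm numeric length-3, `(slice thickness, row, col)` in mm,
#'   strictly positive.
#' @param modality one of `"DWI"`, `"T2WI"`, `"synthetic"`.
#' @param subject_id character scalar identifier.
#' @return An object of class `mr_volume`.
#' @export
mr_volume <- function(voxels, spacing_mm, modality = "synthetic",
                      subject_id = "subject") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array (slices x rows x cols)", call. = FALSE)
  d <- dim(voxels)
  if (d[2] != d[3])
    stop("in-plane dimensions must be square, got ", d[2], "x", d[3],
         call. = FALSE)
  if (d[2] %% 32L != 0L)
    stop("in-plane size must be divisible by 32, got ", d[2], call. = FALSE)
  if (!all(is.finite(voxels)))
    stop("all voxel values must be finite", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 strictly positive numbers", call. = FALSE)
  modality <- match.arg(modality, c("DWI", "T2WI", "synthetic"))
  structure(list(voxels = voxels, spacing_mm = spacing_mm,
                 modality = modality, subject_id = as.character(subject_id)),
            class = "mr_volume")
}

#' @export
print.mr_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<mr_volume %s> %d slices of %dx%d (%s), spacing %s mm\n",
              x$subject_id, d[1], d[2], d[3], x$modality,
              paste(signif(x$spacing_mm, 3), collapse = " x ")))
  invisible(x)
}

#' Binary mask container
#'
#' A `{0,1}` array geometrically aligned with an [mr_volume()]; used both for
#' ground-truth brain masks and for segmentation predictions.
#'
#' @param voxels 3-D array containing only 0 and 1.
#' @param spacing_mm numeric length-3 voxel spacing in mm.
#' @param subject_id character scalar identifier.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing_mm, subject_id = "subject") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array", call. = FALSE)
  v <- as.numeric(voxels)
  if (anyNA(v) || !all(v %in% c(0, 1)))
    stop("mask voxels must contain only 0 and 1", call. = FALSE)
  storage.mode(voxels) <- "double"
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 strictly positive numbers", call. = FALSE)
  structure(list(voxels = voxels, spacing_mm = spacing_mm,
                 subject_id = as.character(subject_id)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_mask %s> %d x %d x %d, %d foreground voxels\n",
              x$subject_id, d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

# Reorder a raw NIfTI array so the slice axis comes first.  The slice axis is
# the axis of length <= 31 whose two companions are square; if no such axis
# exists the first axis is taken as-is.
.canonical_axes <- function(dims) {
  for (ax in 1:3) {
    others <- setdiff(1:3, ax)
    if (dims[ax] <= 31L && dims[others[1]] == dims[others[2]])
      return(c(ax, others))
  }
  c(1L, 2L, 3L)
}

#' Read a NIfTI volume as an MR volume
#'
#' Reads a 3-D single-channel NIfTI-1 file, reorders axes so that slices come
#' first (the slice axis is identified as the axis of length at most 31 whose
#' companion axes are square, falling back to the file's first axis) and
#' carries voxel spacing over from the header.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param modality modality tag to attach, see [mr_volume()].
#' @param subject_id identifier; defaults to the file name stem.
#' @return An [mr_volume()].
#' @export
read_mr_volume <- function(path, modality = "synthetic", subject_id = NULL) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D single-channel image, got ",
         length(dim(arr)), "-D", call. = FALSE)
  pix <- RNifti::pixdim(img)[1:3]
  ord <- .canonical_axes(dim(arr))
  if (!identical(ord, c(1L, 2L, 3L))) {
    arr <- aperm(arr, ord)
    pix <- pix[ord]
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  mr_volume(arr, pix, modality = modality, subject_id = subject_id)
}

#' Read a NIfTI binary mask
#'
#' @inheritParams read_mr_volume
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, subject_id = NULL) {
  vol <- read_mr_volume(path, subject_id = subject_id)
  binary_mask(vol$voxels, vol$spacing_mm, subject_id = vol$subject_id)
}

.write_nifti <- function(voxels, spacing_mm, path, datatype) {
  img <- RNifti::asNifti(voxels)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write an MR volume to NIfTI
#'
#' Volumes are written as float32 (value-preserving within single precision);
#' spacing goes to the header `pixdim`.
#'
#' @param volume an [mr_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_mr_volume <- function(volume, path) {
  stopifnot(inherits(volume, "mr_volume"))
  .write_nifti(volume$voxels, volume$spacing_mm, path, "float")
}

#' Write a binary mask to NIfTI
#'
#' Masks are written with an integer (uint8) datatype so that the
#' write-then-read round trip is bit-exact.
#'
#' @param mask a [binary_mask()].
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  if (!inherits(mask, "binary_mask"))
    mask <- binary_mask(mask$voxels, mask$spacing_mm, mask$subject_id)
  .write_nifti(mask$voxels, mask$spacing_mm, path, "uint8")
}

#' Pooled intensity statistics of a dataset
#'
#' Computes the population mean and population standard deviation pooled over
#' every voxel of every volume in the collection (background included).
#' These dataset-level statistics are the mu and sigma of standard-score
#' normalization; computed on a training split they are meant to be frozen
#' and reused for validation, test and inference data of the same modality.
#'
#' @param volumes a non-empty list of [mr_volume()] objects.
#' @return An object of class `dataset_stats` with fields `mean`, `std`,
#'   `n_volumes`, `n_voxels`.
#' @export
compute_dataset_stats <- function(volumes) {
  if (inherits(volumes, "mr_volume")) volumes <- list(volumes)
  if (length(volumes) == 0L)
    stop("`volumes` must be a non-empty collection", call. = FALSE)
  s <- 0; s2 <- 0; n <- 0
  for (v in volumes) {
    stopifnot(inherits(v, "mr_volume"))
    s <- s + sum(v$voxels)
    s2 <- s2 + sum(v$voxels^2)
    n <- n + length(v$voxels)
  }
  m <- s / n
  var <- s2 / n - m^2
  if (var <= 0)
    stop("degenerate dataset: pooled intensity variance is zero",
         call. = FALSE)
  structure(list(mean = m, std = sqrt(var), n_volumes = length(volumes),
                 n_voxels = n),
            class = "dataset_stats")
}

#' @export
print.dataset_stats <- function(x, ...) {
  cat(sprintf("<dataset_stats> mean %.6g, std %.6g (%d volumes, %d voxels)\n",
              x$mean, x$std, x$n_volumes, x$n_voxels))
  invisible(x)
}

#' Standard-score (z-score) normalization
#'
#' Transforms every voxel as `(I - mu) / sigma` using dataset-level
#' statistics, leaving geometry, modality and identity unchanged.
#'
#' @param volume an [mr_volume()].
#' @param stats a `dataset_stats` object with `std > 0`.
#' @return The normalized [mr_volume()].
#' @export
zscore_normalize <- function(volume, stats) {
  stopifnot(inherits(volume, "mr_volume"))
  if (!is.numeric(stats$std) || stats$std <= 0)
    stop("`stats$std` must be strictly positive", call. = FALSE)
  volume$voxels <- (volume$voxels - stats$mean) / stats$std
  volume
}

#' Read or write a dataset manifest
#'
#' A manifest is a plain CSV table with columns `subject_id`, `image_path`,
#' `mask_path`, `modality`, the interchange format between the phantom
#' generator, training and evaluation.
#'
#' @param path CSV path.
#' @return `read_manifest` returns a data.frame with the four columns.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "image_path", "mask_path", "modality")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df[need]
}

#' @param manifest data.frame with the manifest columns.
#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
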