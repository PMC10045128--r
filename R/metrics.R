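#' Voxelwise confusion counts between two aligned masks
#'
#' @param sp predicted [binary_mask()] (or bare `{0,1}` array).
#' @param gt ground-truth mask of identical shape.
#' @return A list of class `confusion_counts` with integer fields `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion_counts <- function(sp, gt) {
  a <- .mask_array(sp); b <- .mask_array(gt)
  if (!identical(dim(a), dim(b)))
    stop("mask shapes differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  tp <- sum(a == 1 & b == 1)
  fp <- sum(a == 1 & b == 0)
  fn <- sum(a == 0 & b == 1)
  tn <- length(a) - tp - fp - fn
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusion_counts")
}

.mask_array <- function(m) {
  if (inherits(m, "binary_mask")) return(m$voxels)
  if (is.array(m) || is.matrix(m)) {
    if (!all(m %in% c(0, 1))) stop("mask must be binary", call. = FALSE)
    return(m)
  }
  stop("expected a binary_mask or a binary array", call. = FALSE)
}

.mask_spacing <- function(m, spacing_mm) {
  if (inherits(m, "binary_mask")) m$spacing_mm else spacing_mm
}

#' Overlap and contour-distance metrics
#'
#' Implements the standard skull-stripping evaluation suite between a
#' segmentation prediction `sp` and a ground truth `gt`:
#' * Dice coefficient `2*TP / (2*TP + FN + FP)`;
#' * sensitivity `TP / (TP + FN)` (under-segmentation);
#' * sensibility `1 - FP / (TP + FN)` (over-segmentation penalty; deliberately
#'   unclamped, so it can be negative when FP exceeds the ground-truth size);
#' * Hausdorff and average Hausdorff distance between the mask contours in
#'   physical millimetres.
#'
#' When both masks are empty, `dice()` returns 1 by convention; sensitivity,
#' sensibility and the distance metrics instead raise errors on empty
#' ground truth or empty contours, since such comparisons are undefined.
#'
#' @param sp,gt aligned [binary_mask()] objects (or bare binary arrays).
#' @return A fraction (`dice`, `sensitivity`) or real (`sensibility`).
#' @export
dice <- function(sp, gt) {
  cc <- confusion_counts(sp, gt)
  denom <- 2 * cc$tp + cc$fn + cc$fp
  if (denom == 0) return(1.0)  # both masks empty: perfect agreement
  2 * cc$tp / denom
}

#' @rdname dice
#' @export
sensitivity <- function(sp, gt) {
  cc <- confusion_counts(sp, gt)
  if (cc$tp + cc$fn == 0)
    stop("ground-truth mask is empty; sensitivity undefined", call. = FALSE)
  cc$tp / (cc$tp + cc$fn)
}

#' @rdname dice
#' @export
sensibility <- function(sp, gt) {
  cc <- confusion_counts(sp, gt)
  if (cc$tp + cc$fn == 0)
    stop("ground-truth mask is empty; sensibility undefined", call. = FALSE)
  1 - cc$fp / (cc$tp + cc$fn)
}

#' Extract the contour of a mask as a physical point set
#'
#' Within each slice, a foreground voxel is a boundary voxel iff at least one
#' of its in-plane 4-neighbours is background or lies outside the image.  The
#' union over slices of boundary voxel centres is returned in mm, mapping the
#' 0-based voxel index `(s, r, c)` to
#' `(s * slice thickness, r * row spacing, c * col spacing)`.
#'
#' @param mask a non-empty [binary_mask()] (or binary array, in which case
#'   `spacing_mm` must be given).
#' @param spacing_mm spacing override for bare arrays.
#' @return An `n x 3` numeric matrix of contour points in mm, class
#'   `contour_points`.
#' @export
extract_contour <- function(mask, spacing_mm = NULL) {
  arr <- .mask_array(mask)
  if (is.matrix(arr)) arr <- array(arr, c(1L, dim(arr)))
  sp <- .mask_spacing(mask, spacing_mm)
  if (is.null(sp)) stop("spacing_mm required for bare arrays", call. = FALSE)
  if (sum(arr) == 0) stop("cannot extract the contour of an empty mask",
                          call. = FALSE)
  d <- dim(arr)
  # shifted copies padded with background outside the image
  shift <- function(a, dr, dc) {
    out <- array(0, dim(a))
    rs <- seq_len(d[2]); cs <- seq_len(d[3])
    rsrc <- rs - dr; csrc <- cs - dc
    keep_r <- rsrc >= 1 & rsrc <= d[2]
    keep_c <- csrc >= 1 & csrc <= d[3]
    out[, rs[keep_r], cs[keep_c]] <- a[, rsrc[keep_r], csrc[keep_c]]
    out
  }
  interior <- shift(arr, 1, 0) * shift(arr, -1, 0) *
    shift(arr, 0, 1) * shift(arr, 0, -1)
  boundary <- which(arr == 1 & interior == 0, arr.ind = TRUE)
  pts <- cbind((boundary[, 1] - 1) * sp[1],
               (boundary[, 2] - 1) * sp[2],
               (boundary[, 3] - 1) * sp[3])
  colnames(pts) <- c("s_mm", "r_mm", "c_mm")
  structure(pts, class = c("contour_points", class(pts)))
}

.as_points <- function(x) {
  m <- unclass(x)
  if (!is.matrix(m) || ncol(m) != 3 || nrow(m) == 0)
    stop("expected a non-empty n x 3 point matrix", call. = FALSE)
  storage.mode(m) <- "double"
  m
}

#' Hausdorff distance between two contour point sets
#'
#' `hausdorff()` is the classical symmetric Hausdorff distance: the larger of
#' the two directed farthest-nearest-neighbour distances.
#' `average_hausdorff()` replaces the outer maximum by a mean: it is the
#' symmetric mean of the two directed average nearest-neighbour distances,
#' `(mean_a min_b ||a-b|| + mean_b min_a ||b-a||) / 2`.  Both are Euclidean
#' in mm and satisfy `average_hausdorff(a, b) <= hausdorff(a, b)`.
#'
#' @param a,b non-empty point sets from [extract_contour()] (or bare
#'   `n x 3` matrices in mm).
#' @return Distance in mm.
#' @export
hausdorff <- function(a, b) {
  pa <- .as_points(a); pb <- .as_points(b)
  max(directed_nn_stats(pa, pb)[1], directed_nn_stats(pb, pa)[1])
}

#' @rdname hausdorff
#' @export
average_hausdorff <- function(a, b) {
  pa <- .as_points(a); pb <- .as_points(b)
  (directed_nn_stats(pa, pb)[2] + directed_nn_stats(pb, pa)[2]) / 2
}

#' Full per-subject metric report
#'
#' Computes confusion counts, Dice, sensitivity, sensibility, Hausdorff and
#' average Hausdorff distance (in mm, using the masks' voxel spacing) in one
#' consistent pass.
#'
#' @param sp,gt aligned [binary_mask()] objects; `gt` must be non-empty.
#' @return A list of class `metric_report` with fields `dice`, `sensitivity`,
#'   `sensibility`, `hausdorff_mm`, `avg_hausdorff_mm`, `counts`.
#' @export
evaluate_pair <- function(sp, gt) {
  cc <- confusion_counts(sp, gt)
  if (cc$tp + cc$fn == 0)
    stop("ground-truth mask is empty", call. = FALSE)
  d <- {
    den <- 2 * cc$tp + cc$fn + cc$fp
    if (den == 0) 1.0 else 2 * cc$tp / den
  }
  ca <- extract_contour(sp)
  cb <- extract_contour(gt)
  ab <- directed_nn_stats(.as_points(ca), .as_points(cb))
  ba <- directed_nn_stats(.as_points(cb), .as_points(ca))
  structure(list(dice = d,
                 sensitivity = cc$tp / (cc$tp + cc$fn),
                 sensibility = 1 - cc$fp / (cc$tp + cc$fn),
                 hausdorff_mm = max(ab[1], ba[1]),
                 avg_hausdorff_mm = (ab[2] + ba[2]) / 2,
                 counts = cc),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> dice %.4f  sens %.4f  sensb %.4f  HD %.3f mm  aHD %.3f mm\n",
    x$dice, x$sensitivity, x$sensibility, x$hausdorff_mm, x$avg_hausdorff_mm))
  invisible(x)
}

#' Evaluate a cohort of prediction / ground-truth mask pairs
#'
#' @param pairs a list whose elements are lists with components `sp` and `gt`
#'   ([binary_mask()] objects) and optionally `subject_id`.
#' @return A data.frame with one row per subject (columns `subject_id`,
#'   `dice`, `sensitivity`, `sensibility`, `hausdorff_mm`,
#'   `avg_hausdorff_mm`) plus attribute `"summary"` holding mean and sd rows.
#' @export
evaluate_cohort <- function(pairs) {
  stopifnot(length(pairs) >= 1)
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    r <- evaluate_pair(p$sp, p$gt)
    data.frame(subject_id = if (!is.null(p$subject_id)) p$subject_id
               else p$gt$subject_id,
               dice = r$dice, sensitivity = r$sensitivity,
               sensibility = r$sensibility, hausdorff_mm = r$hausdorff_mm,
               avg_hausdorff_mm = r$avg_hausdorff_mm,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  num <- df[, -1, drop = FALSE]
  summ <- data.frame(statistic = c("mean", "sd"),
                     rbind(colMeans(num), apply(num, 2, stats::sd)))
  attr(df, "summary") <- summ
  df
}

#' Paired t-test between two score vectors
#'
#' Classical paired two-tailed t-test on the per-subject differences, the
#' significance test used to compare segmentation methods (threshold
#' conventionally p < 0.05).  Degenerate inputs (unequal lengths, fewer than
#' two pairs, or all differences identical so the t statistic is undefined)
#' raise errors rather than returning NaN.
#'
#' @param scores_a,scores_b equal-length numeric vectors of paired scores.
#' @return A list with `t`, `p`, `df`, `mean_difference`.
#' @export
paired_t_test <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors must have equal length", call. = FALSE)
  if (length(scores_a) < 2)
    stop("need at least two pairs", call. = FALSE)
  d <- scores_a - scores_b
  if (stats::sd(d) == 0)
    stop("all paired differences are identical; t statistic undefined",
         call. = FALSE)
  ht <- stats::t.test(scores_a, scores_b, paired = TRUE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_difference = unname(ht$estimate))
}
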