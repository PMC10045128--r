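#' Parameters of the synthetic stroke-rat MR phantom
#'
#' The phantom emulates the geometry of coronal stroke-rat acquisitions: a
#' 15-slice volume over a 25.6 x 25.6 mm field of view with 1 mm slice
#' thickness, so a 128 matrix gives 0.2 mm and a 256 matrix 0.1 mm in-plane
#' spacing.  Each slice contains a bright elliptical brain whose semi-axes
#' shrink toward the first and last slices, a dark skull-gap ring and a
#' moderately bright scalp ring outside it (deliberately brain-like in
#' intensity so plain thresholding fails), a hyperintense ischemic lesion
#' inside one hemisphere on a contiguous subset of slices, a smooth
#' multiplicative bias field (exponential of a random low-order polynomial)
#' and Rician noise (magnitude of signal plus complex Gaussian).
#'
#' @param matrix_size in-plane matrix (must be a multiple of 32; 128
#'   emulates DWI, 256 T2WI, 64 is a convenient desk-scale size).
#' @param n_slices number of coronal slices.
#' @param fov_mm in-plane field of view in mm.
#' @param slice_thickness_mm slice thickness in mm.
#' @param brain_semi_axes_mm mid-slice ellipse semi-axes `(horizontal,
#'   vertical)` in mm before per-subject jitter.
#' @param axis_jitter_mm,center_jitter_mm uniform per-subject jitter on the
#'   semi-axes and the brain centre.
#' @param profile_shrink how strongly the ellipse shrinks toward the end
#'   slices (0 = cylinder, values near 1 = sharp taper).
#' @param skull_gap_width_mm,scalp_ring_width_mm ring widths in mm.
#' @param skull_gap_intensity,scalp_intensity ring intensities relative to
#'   brain tissue (1.0).
#' @param lesion_radius_range_mm,lesion_gain_range,lesion_center_frac lesion
#'   radius (mm), hyperintensity gain and centre offset as a fraction of the
#'   horizontal semi-axis.
#' @param bias_amplitude_range uniform range for the bias-field log
#'   amplitude (capped at 0.3).
#' @param noise_sigma Rician noise sigma; the default gives brain SNR of
#'   about 15.  Set to 0 for a noiseless render.
#' @param seed integer seed; the phantom is a deterministic function of its
#'   parameters.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(matrix_size = 128L, n_slices = 15L,
                           fov_mm = 25.6, slice_thickness_mm = 1.0,
                           brain_semi_axes_mm = c(7.75, 5.75),
                           axis_jitter_mm = 0.4, center_jitter_mm = 1.5,
                           profile_shrink = 0.55,
                           skull_gap_width_mm = 0.4,
                           scalp_ring_width_mm = 1.0,
                           skull_gap_intensity = 0.15,
                           scalp_intensity = 0.75,
                           lesion_radius_range_mm = c(1.2, 2.0),
                           lesion_gain_range = c(1.3, 1.8),
                           lesion_center_frac = 0.45,
                           bias_amplitude_range = c(0.1, 0.3),
                           noise_sigma = 1 / 15,
                           seed = 1L) {
  matrix_size <- as.integer(matrix_size)
  if (matrix_size %% 32L != 0L)
    stop("`matrix_size` must be a multiple of 32", call. = FALSE)
  stopifnot(n_slices >= 3, fov_mm > 0, slice_thickness_mm > 0,
            all(brain_semi_axes_mm > 0), profile_shrink >= 0,
            profile_shrink < 1, skull_gap_width_mm >= 0,
            scalp_ring_width_mm >= 0, noise_sigma >= 0,
            max(bias_amplitude_range) <= 0.3,
            lesion_center_frac >= 0, lesion_center_frac < 1)
  structure(as.list(environment()), class = "phantom_params")
}

#' Generate one synthetic phantom subject
#'
#' Renders a full image volume and its exact ground-truth brain mask (the
#' brain ellipse interior, lesion included, rings excluded).  The mask is
#' exact by construction, so a perfect segmentation has Dice 1.
#'
#' @param params a [phantom_params()].
#' @param subject_id identifier stored in the returned objects.
#' @return A list with `volume` ([mr_volume()], modality `"synthetic"`),
#'   `mask` ([binary_mask()]), `regions` (integer array: 0 background,
#'   1 brain, 2 skull gap, 3 scalp, 4 lesion) and `params`.
#' @export
generate_phantom_subject <- function(params = phantom_params(),
                                     subject_id = "phantom") {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  M <- p$matrix_size; S <- p$n_slices
  px <- p$fov_mm / M
  spacing <- c(p$slice_thickness_mm, px, px)

  withr::with_seed(p$seed, {
    semi_a <- p$brain_semi_axes_mm[1] +
      stats::runif(1, -p$axis_jitter_mm, p$axis_jitter_mm)
    semi_b <- p$brain_semi_axes_mm[2] +
      stats::runif(1, -p$axis_jitter_mm, p$axis_jitter_mm)
    cy <- p$fov_mm / 2 + stats::runif(1, -p$center_jitter_mm,
                                      p$center_jitter_mm)
    cx <- p$fov_mm / 2 + stats::runif(1, -p$center_jitter_mm,
                                      p$center_jitter_mm)
    lesion_radius <- stats::runif(1, p$lesion_radius_range_mm[1],
                                  p$lesion_radius_range_mm[2])
    lesion_gain <- stats::runif(1, p$lesion_gain_range[1],
                                p$lesion_gain_range[2])
    lesion_side <- if (stats::runif(1) < 0.5) 1 else -1
    bias_amp <- stats::runif(1, p$bias_amplitude_range[1],
                             p$bias_amplitude_range[2])
    bias_coef <- stats::rnorm(5)

    # head-to-tail size profile, 1 at the middle slice
    mid <- (S + 1) / 2
    prof <- sqrt(1 - p$profile_shrink * ((seq_len(S) - mid) / (mid))^2)

    # lesion occupies a contiguous band of middle slices
    cand <- which(prof >= 0.9)
    len <- min(length(cand), sample(5:9, 1))
    start <- cand[1] + sample.int(length(cand) - len + 1L, 1) - 1L
    lesion_slices <- start:(start + len - 1L)

    # coordinate grids (mm); rows = vertical (y), cols = horizontal (x)
    yy <- (seq_len(M) - 1) * px
    xx <- (seq_len(M) - 1) * px

    # bias field: exp of a low-order polynomial in normalized coords
    u <- (yy - p$fov_mm / 2) / (p$fov_mm / 2)
    v <- (xx - p$fov_mm / 2) / (p$fov_mm / 2)
    poly <- outer(u, v, function(a, b)
      bias_coef[1] * a + bias_coef[2] * b + bias_coef[3] * a * b +
        bias_coef[4] * a^2 + bias_coef[5] * b^2)
    poly <- poly / max(abs(poly)) * bias_amp
    bias <- exp(poly)

    gapf <- p$skull_gap_width_mm / mean(c(semi_a, semi_b))
    scalpf <- p$scalp_ring_width_mm / mean(c(semi_a, semi_b))

    vox <- array(0, c(S, M, M))
    regions <- array(0L, c(S, M, M))
    mask <- array(0, c(S, M, M))
    lesion_cx <- cx + lesion_side * p$lesion_center_frac * semi_a
    lesion_cy <- cy

    for (s in seq_len(S)) {
      as_ <- semi_a * prof[s]; bs_ <- semi_b * prof[s]
      r <- sqrt(outer(((yy - cy) / bs_)^2, ((xx - cx) / as_)^2, "+"))
      brain <- r <= 1
      gap <- r > 1 & r <= 1 + gapf
      scalp <- r > 1 + gapf & r <= 1 + gapf + scalpf
      slice <- matrix(0, M, M)
      slice[brain] <- 1
      slice[gap] <- p$skull_gap_intensity
      slice[scalp] <- p$scalp_intensity
      reg <- matrix(0L, M, M)
      reg[brain] <- 1L; reg[gap] <- 2L; reg[scalp] <- 3L
      if (s %in% lesion_slices) {
        # the lesion circle must sit entirely inside the slice ellipse
        ctr_r <- sqrt(((lesion_cy - cy) / bs_)^2 + ((lesion_cx - cx) / as_)^2)
        if (ctr_r + lesion_radius / min(as_, bs_) > 1)
          stop("lesion extends outside the brain ellipse; reduce ",
               "`lesion_center_frac` or the lesion radius", call. = FALSE)
        lr <- sqrt(outer((yy - lesion_cy)^2, (xx - lesion_cx)^2, "+"))
        les <- lr <= lesion_radius
        slice[les] <- lesion_gain
        reg[les & brain] <- 4L
      }
      slice <- slice * bias
      if (p$noise_sigma > 0) {
        n1 <- matrix(stats::rnorm(M * M, 0, p$noise_sigma), M, M)
        n2 <- matrix(stats::rnorm(M * M, 0, p$noise_sigma), M, M)
        slice <- sqrt((slice + n1)^2 + n2^2)
      }
      vox[s, , ] <- slice
      regions[s, , ] <- reg
      mask[s, , ] <- brain * 1
    }
  })

  list(volume = mr_volume(vox, spacing, modality = "synthetic",
                          subject_id = subject_id),
       mask = binary_mask(mask, spacing, subject_id = subject_id),
       regions = regions, params = params)
}

#' Generate a phantom dataset
#'
#' Draws `n` subjects with per-subject geometry, lesion, bias and noise
#' realizations; per-subject seeds derive from the master `seed`.  With
#' `outdir` given, image/mask NIfTI pairs and a manifest CSV are written;
#' otherwise subjects are returned in memory.
#'
#' @param n number of subjects.
#' @param modality_like `"DWI"` (128 matrix) or `"T2WI"` (256 matrix).
#' @param seed master seed.
#' @param outdir optional output directory.
#' @param matrix_size override of the modality's default matrix.
#' @param ... further arguments forwarded to [phantom_params()].
#' @return With `outdir`: the manifest data.frame (invisibly written to
#'   `manifest.csv`).  Without: a named list of subjects as returned by
#'   [generate_phantom_subject()].
#' @export
generate_phantom_dataset <- function(n, modality_like = c("DWI", "T2WI"),
                                     seed = 1L, outdir = NULL,
                                     matrix_size = NULL, ...) {
  stopifnot(n >= 1)
  modality_like <- match.arg(modality_like)
  if (is.null(matrix_size))
    matrix_size <- if (modality_like == "DWI") 128L else 256L
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n))
  ids <- sprintf("S%03d", seq_len(n))
  subjects <- lapply(seq_len(n), function(i)
    generate_phantom_subject(
      phantom_params(matrix_size = matrix_size, seed = seeds[i], ...),
      subject_id = ids[i]))
  names(subjects) <- ids
  if (is.null(outdir)) return(subjects)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_len(n), function(i) {
    ip <- file.path(outdir, paste0(ids[i], "_img.nii.gz"))
    mp <- file.path(outdir, paste0(ids[i], "_mask.nii.gz"))
    write_mr_volume(subjects[[i]]$volume, ip)
    write_mask(subjects[[i]]$mask, mp)
    data.frame(subject_id = ids[i], image_path = ip, mask_path = mp,
               modality = modality_like, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(outdir, "manifest.csv"))
  manifest
}
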