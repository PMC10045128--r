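# Independent brute-force oracles used to cross-check the fast
# implementations, plus small fixture generators.  The oracles share no code
# with the package internals: explicit voxel loops and full pairwise
# distance scans only.

oracle_counts <- function(sp, gt) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in seq_along(sp)) {
    if (sp[i] == 1 && gt[i] == 1) tp <- tp + 1L
    else if (sp[i] == 1 && gt[i] == 0) fp <- fp + 1L
    else if (sp[i] == 0 && gt[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_dice <- function(sp, gt) {
  cc <- oracle_counts(sp, gt)
  den <- 2 * cc$tp + cc$fn + cc$fp
  if (den == 0) 1.0 else 2 * cc$tp / den
}

oracle_sensitivity <- function(sp, gt) {
  cc <- oracle_counts(sp, gt)
  cc$tp / (cc$tp + cc$fn)
}

oracle_sensibility <- function(sp, gt) {
  cc <- oracle_counts(sp, gt)
  1 - cc$fp / (cc$tp + cc$fn)
}

# boundary voxels by the in-plane 4-neighbour rule, explicit loops
oracle_contour <- function(arr, spacing) {
  d <- dim(arr)
  pts <- NULL
  for (s in seq_len(d[1])) for (r in seq_len(d[2])) for (c in seq_len(d[3])) {
    if (arr[s, r, c] != 1) next
    nb <- c(if (r > 1) arr[s, r - 1, c] else 0,
            if (r < d[2]) arr[s, r + 1, c] else 0,
            if (c > 1) arr[s, r, c - 1] else 0,
            if (c < d[3]) arr[s, r, c + 1] else 0)
    if (any(nb == 0))
      pts <- rbind(pts, c((s - 1) * spacing[1], (r - 1) * spacing[2],
                          (c - 1) * spacing[3]))
  }
  pts
}

oracle_directed <- function(a, b) {
  # plain double arithmetic, one coordinate at a time (no extended-precision
  # accumulation), so the comparison with the kernel is exact
  mins <- vapply(seq_len(nrow(a)), function(i) {
    d1 <- b[, 1] - a[i, 1]
    d2 <- b[, 2] - a[i, 2]
    d3 <- b[, 3] - a[i, 3]
    sqrt(min(d1 * d1 + d2 * d2 + d3 * d3))
  }, numeric(1))
  c(max = max(mins), mean = mean(mins))
}

oracle_hausdorff <- function(a, b) {
  max(oracle_directed(a, b)["max"], oracle_directed(b, a)["max"])
}

oracle_avg_hausdorff <- function(a, b) {
  unname((oracle_directed(a, b)["mean"] + oracle_directed(b, a)["mean"]) / 2)
}

# random small non-empty mask of the given dims (blobby, not pure salt)
random_mask <- function(dims, p = 0.3) {
  repeat {
    arr <- array(as.numeric(stats::runif(prod(dims)) < p), dims)
    if (sum(arr) > 0) return(arr)
  }
}

mask_of <- function(arr, spacing = c(1, 1, 1), id = "m") {
  binary_mask(arr, spacing, subject_id = id)
}

small_phantom_pair <- function(seed, matrix_size = 64L) {
  generate_phantom_subject(phantom_params(matrix_size = matrix_size,
                                          seed = seed),
                           subject_id = paste0("P", seed))
}
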