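# Independent brute-force oracles and small fixture builders.
# These deliberately use naive triple loops / direct formulas so they share
# no code path with the package implementation they check.

# Naive voxel scan: selected iff inside the VOI and SUV strictly over the
# applied threshold (threshold resolved exactly as the contract states).
oracle_threshold_mask <- function(values, voi_mask, kind, value) {
  d <- dim(values)
  thr <- if (kind == "absolute") value else {
    mx <- -Inf
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
      if (voi_mask[i, j, k] && values[i, j, k] > mx) mx <- values[i, j, k]
    value * mx
  }
  out <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
    out[i, j, k] <- voi_mask[i, j, k] && values[i, j, k] > thr
  list(mask = out, threshold = thr)
}

# Exhaustive SUVpeak: for every scope voxel, average all voxels whose centers
# fall within the sphere radius, computed by direct distance evaluation.
oracle_suv_peak <- function(values, scope_mask, spacing, sphere_volume_cm3 = 1) {
  r <- (3 * sphere_volume_cm3 * 1000 / (4 * pi))^(1 / 3)
  d <- dim(values)
  best <- -Inf
  for (ci in 1:d[1]) for (cj in 1:d[2]) for (ck in 1:d[3]) {
    if (!scope_mask[ci, cj, ck]) next
    tot <- 0; cnt <- 0
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      dd <- ((i - ci) * spacing[1])^2 + ((j - cj) * spacing[2])^2 +
        ((k - ck) * spacing[3])^2
      if (dd <= r^2) { tot <- tot + values[i, j, k]; cnt <- cnt + 1 }
    }
    if (tot / cnt > best) best <- tot / cnt
  }
  best
}

# Exhaustive ROC scan over all distinct-score cutoffs (plus sentinels) and
# rank-sum AUC with tie correction.
oracle_roc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  auc <- mean(cmp)
  cands <- sort(unique(c(-Inf, scores, Inf)))
  best_j <- -Inf; best_c <- Inf
  for (cc in cands) {
    sens <- mean(pos > cc); spec <- mean(neg <= cc)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) { best_j <- j; best_c <- cc }
  }
  list(auc = auc, youden_value = best_j, youden_cutoff = best_c)
}

# Seeded random SUV volume and a random blobby VOI on the same grid.
random_volume_fixture <- function(seed, dims = c(12, 12, 6), spacing = 2) {
  set.seed(seed)
  vals <- array(stats::runif(prod(dims), 0, 8), dims)
  vm <- array(stats::runif(prod(dims)) < 0.6, dims)
  if (!any(vm)) vm[1, 1, 1] <- TRUE
  list(vol = suv_volume(vals, rep(spacing, 3)), voi = voi(vm))
}

# Small noiseless sphere phantom used by several delineation tests.
sphere_phantom <- function(r_mm = 10, uptake = 8, background = 0.5,
                           spacing = 2, fwhm = 0, noise = 0, n = 24,
                           seed = 1) {
  ctr <- ((n - 1) %/% 2) * spacing   # exactly on a voxel center
  generate_phantom(phantom_spec(
    grid_shape = rep(n, 3), spacing_mm = spacing, background_suv = background,
    lesions = list(lesion_spec(rep(ctr, 3), r_mm, uptake)),
    psf_fwhm_mm = fwhm, noise_sd_suv = noise, seed = seed))
}

full_grid_voi <- function(vol) voi(array(TRUE, dim(vol$values)))
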