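# Internal numerical helpers shared across modules.

# Even-odd ray-crossing point-in-polygon test. Points exactly on an edge are
# resolved by the crossing rule itself (deterministic, but formally the test
# is for the strict interior); callers should not place voxel centers on
# polygon edges if they care about the boundary.
point_in_polygon <- function(px, py, vx, vy) {
  stopifnot(length(vx) == length(vy), length(vx) >= 3L)
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]
    xj <- vx[j]; yj <- vy[j]
    denom <- yj - yi
    if (denom != 0) {
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / denom + xi)
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside
}

# Separable Gaussian blur of a 3D array; sigma given per axis in voxel units.
# The kernel is truncated at 4 sigma and normalised to sum 1, applied with
# zero padding: total activity of an object whose support stays clear of the
# grid edges is conserved.
gaussian_blur_3d <- function(arr, sigma_vox) {
  stopifnot(length(dim(arr)) == 3L, length(sigma_vox) == 3L, all(sigma_vox >= 0))
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- dim(arr)[ax]
    half <- max(1L, as.integer(ceiling(4 * s)))
    kern <- stats::dnorm(seq(-half, half), sd = s)
    kern <- kern / sum(kern)
    band <- matrix(0, n, n)
    for (i in seq_len(n)) {
      idx <- (i - half):(i + half)
      ok <- idx >= 1L & idx <= n
      band[i, idx[ok]] <- kern[ok]
    }
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    dm <- dim(a)
    a <- band %*% matrix(a, nrow = dm[1])
    dim(a) <- dm
    arr <- aperm(a, order(perm))
  }
  arr
}

# Integer offsets (voxel steps) whose mm displacement lies within `radius_mm`
# of the origin, for a given spacing. Used for the SUVpeak sphere and for
# binary dilation.
ball_offsets <- function(radius_mm, spacing_mm) {
  nr <- pmax(0L, as.integer(ceiling(radius_mm / spacing_mm)))
  off <- as.matrix(expand.grid(i = -nr[1]:nr[1], j = -nr[2]:nr[2], k = -nr[3]:nr[3]))
  d2 <- (off[, 1] * spacing_mm[1])^2 + (off[, 2] * spacing_mm[2])^2 +
    (off[, 3] * spacing_mm[3])^2
  off[d2 <= radius_mm^2, , drop = FALSE]
}

# Binary dilation of a 3D logical array by a ball of `radius_mm`.
dilate_mask <- function(mask, spacing_mm, radius_mm) {
  if (radius_mm <= 0 || !any(mask)) return(mask)
  d <- dim(mask)
  off <- ball_offsets(radius_mm, spacing_mm)
  ctr <- which(mask, arr.ind = TRUE)
  out <- array(FALSE, d)
  for (m in seq_len(nrow(off))) {
    i <- ctr[, 1] + off[m, 1]
    j <- ctr[, 2] + off[m, 2]
    k <- ctr[, 3] + off[m, 3]
    ok <- i >= 1L & i <= d[1] & j >= 1L & j <= d[2] & k >= 1L & k <= d[3]
    out[cbind(i[ok], j[ok], k[ok])] <- TRUE
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
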