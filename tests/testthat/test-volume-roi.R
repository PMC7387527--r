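test_that("SUV volume and mask NIfTI round-trips are lossless", {
  set.seed(42)
  vol <- suv_volume(array(runif(10 * 10 * 6, 0, 20), c(10, 10, 6)),
                    spacing_mm = c(2, 2, 3), origin_mm = c(5, -4, 0))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_suv_volume(vol, f)
  back <- read_suv_volume(f)
  expect_equal(back$spacing_mm, vol$spacing_mm)
  expect_equal(back$origin_mm, vol$origin_mm)
  # stored as 32-bit float
  expect_equal(back$values, vol$values, tolerance = 1e-6)

  m <- array(FALSE, dim(vol$values)); m[3:6, 2:9, 2:4] <- TRUE
  fm <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(voi(m), fm, vol = vol)
  mb <- read_mask(fm, vol)
  expect_identical(mb$mask, m)
})

test_that("mask/volume mismatches are rejected with both grids named", {
  vol <- suv_volume(array(1, c(8, 8, 4)), 2)
  small <- suv_volume(array(1, c(8, 8, 5)), 2)
  fm <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(voi(array(TRUE, c(8, 8, 5))), fm, vol = small)
  expect_error(read_mask(fm, vol), "8x8x5.*8x8x4")
  wrongsp <- suv_volume(array(1, c(8, 8, 5)), 3)
  fm2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(voi(array(TRUE, c(8, 8, 5))), fm2, vol = wrongsp)
  expect_error(read_mask(fm2, small), "spacing")
})

test_that("a NIfTI written by an independent tool reads with its header spacing", {
  skip_if_not_installed("oro.nifti")
  arr <- array(runif(6 * 6 * 4), c(6, 6, 4))
  nim <- oro.nifti::nifti(arr, datatype = 16)
  oro.nifti::pixdim(nim)[2:4] <- c(2, 2, 2)
  stem <- tempfile()
  oro.nifti::writeNIfTI(nim, stem)
  vol <- read_suv_volume(paste0(stem, ".nii.gz"))
  expect_equal(vol$spacing_mm, c(2, 2, 2))
  expect_equal(vol$values, arr, tolerance = 1e-6)
})

test_that("polygon voxel-center membership agrees with an independent test", {
  skip_if_not_installed("mgcv")
  set.seed(7)
  for (rep in 1:10) {
    # random star-shaped simple polygon
    k <- sample(5:12, 1)
    ang <- sort(runif(k, 0, 2 * pi))
    rad <- runif(k, 4, 18)
    vx <- 20 + rad * cos(ang)
    vy <- 20 + rad * sin(ang)
    pts <- expand.grid(x = seq(0.3, 39.7, by = 1.11),
                       y = seq(0.3, 39.7, by = 1.11))
    mine <- tmtvkit:::point_in_polygon(pts$x, pts$y, vx, vy)
    ref <- mgcv::in.out(cbind(c(vx, vx[1]), c(vy, vy[1])),
                        as.matrix(pts)) > 0
    expect_equal(mine, as.vector(ref))
  }
})

test_that("prism extrusion reproduces exact and analytic footprints", {
  vol <- suv_volume(array(1, c(20, 20, 14)), 2)
  # axis-aligned square covering exactly 10x10 voxel centers
  sq <- planar_roi(5, vertices_mm = rbind(c(3, 3), c(23, 3), c(23, 23), c(3, 23)))
  v <- extrude_single_roi(sq, 3, 7, vol)
  expect_identical(voi_count(v), 500L)
  # single-slice extrusion equals the footprint
  v1 <- extrude_single_roi(sq, 5, 5, vol)
  expect_identical(voi_count(v1), 100L)
  expect_identical(v1$mask[, , 5], v$mask[, , 4])

  # circle r = 15 mm over 20 mm of slices: count near pi r^2 h / voxel volume
  ang <- seq(0, 2 * pi, length.out = 181)[-181]
  circ <- planar_roi(5, vertices_mm = cbind(19 + 15 * cos(ang),
                                            19 + 15 * sin(ang)))
  vc <- extrude_single_roi(circ, 3, 12, vol)  # 10 slices x 2 mm
  expected_vox <- pi * 15^2 * 20 / 8
  shell_vox <- 2 * pi * 15 * 2 * 20 / 8
  expect_lt(abs(voi_count(vc) - expected_vox), shell_vox)
  # footprint equals an independent voxel-center distance test
  fp <- vc$mask[, , 5]
  co <- (seq_len(20) - 1) * 2
  d2 <- outer((co - 19)^2, (co - 19)^2, `+`)
  expect_identical(fp, d2 < 15^2)

  expect_error(extrude_single_roi(sq, 6, 9, vol), "must contain")
  tiny <- planar_roi(5, vertices_mm = rbind(c(2.2, 2.2), c(2.8, 2.2), c(2.5, 2.8)))
  expect_error(extrude_single_roi(tiny, 3, 7, vol), "no voxel centers")
})

test_that("stacking one ROI over a range is identical to extruding it", {
  vol <- suv_volume(array(1, c(16, 16, 9)), 2.5)
  ang <- seq(0, 2 * pi, length.out = 33)[-33]
  circ <- function(z) planar_roi(z, vertices_mm = cbind(18 + 9 * cos(ang),
                                                        18 + 9 * sin(ang)))
  stacked <- stack_slicewise_rois(lapply(3:7, circ), vol)
  prism <- extrude_single_roi(circ(5), 3, 7, vol)
  expect_identical(stacked$mask, prism$mask)

  expect_error(stack_slicewise_rois(list(circ(3), circ(3)), vol), "duplicate")
})

test_that("slice-wise circles circumscribing a sphere contain its ground truth", {
  ph <- sphere_phantom(r_mm = 10, uptake = 8, background = 0.5, spacing = 2)
  gt <- ph$lesion_masks[[1]]$mask
  n <- dim(gt)[1]
  ctr <- ((n - 1) %/% 2) * 2
  ang <- seq(0, 2 * pi, length.out = 73)[-73]
  rois <- list()
  for (z in which(apply(gt, 3, any))) {
    zc <- (z - 1) * 2
    rz <- sqrt(max(10^2 - (zc - ctr)^2, 0)) + 2.5  # circumscribe + margin
    rois[[length(rois) + 1L]] <-
      planar_roi(z, vertices_mm = cbind(ctr + rz * cos(ang),
                                        ctr + rz * sin(ang)))
  }
  v <- stack_slicewise_rois(rois, ph$volume)
  expect_true(all(v$mask[gt]))
})

test_that("lesion-set union adds disjoint masks and rejects overlap", {
  d <- c(14, 14, 8)
  a <- array(FALSE, d); a[2:6, 2:5, 2:6] <- TRUE       # 100 voxels
  b <- array(FALSE, d); b[9:13, 9:12, 2:6] <- TRUE     # 100 voxels
  ls <- lesion_set(list(voi(a), voi(b)))
  expect_identical(voi_count(union_lesions(ls)), 200L)
  expect_identical(union_lesions(lesion_set(list(voi(a))))$mask, a)
  bad <- array(FALSE, d); bad[5:7, 2:5, 2:6] <- TRUE
  expect_error(lesion_set(list(voi(a), voi(bad))), "overlap")

  # brute-force OR oracle on three random blobs
  set.seed(31)
  ms <- list()
  occupied <- array(FALSE, d)
  for (i in 1:3) {
    m <- array(runif(prod(d)) < 0.08, d) & !occupied
    occupied <- occupied | m
    ms[[i]] <- voi(m)
  }
  u <- union_lesions(lesion_set(ms))
  ref <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
    ref[i, j, k] <- ms[[1]]$mask[i, j, k] || ms[[2]]$mask[i, j, k] ||
      ms[[3]]$mask[i, j, k]
  expect_identical(u$mask, ref)
})

test_that("polygon ROIs round-trip through JSON", {
  roi <- planar_roi(4, vertices_mm = rbind(c(1, 2), c(8, 2.5), c(5, 9)))
  f <- withr::local_tempfile(fileext = ".json")
  write_roi_json(roi, f)
  back <- read_roi_json(f)
  expect_identical(back$slice_index, 4L)
  expect_equal(back$vertices_mm, roi$vertices_mm, ignore_attr = TRUE)
})
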