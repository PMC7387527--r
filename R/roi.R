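#' Planar region of interest
#'
#' A 2D region drawn on one axial slice, given either as a simple polygon in
#' world (mm) coordinates of the slice plane or directly as a 2D boolean
#' footprint aligned to the in-plane grid. Polygons are rasterised with a
#' voxel-center even-odd membership test.
#'
#' @param slice_index 1-based axial slice index the region was drawn on.
#' @param vertices_mm Optional n x 2 matrix of polygon vertices (x, y in mm),
#'   at least 3 vertices, non-self-intersecting.
#' @param mask2d Optional 2D logical matrix giving the footprint directly.
#'   Exactly one of `vertices_mm` / `mask2d` must be supplied.
#' @return An object of class `planar_roi`.
#' @export
planar_roi <- function(slice_index, vertices_mm = NULL, mask2d = NULL) {
  slice_index <- as.integer(slice_index)
  stopifnot(length(slice_index) == 1L, slice_index >= 1L)
  if (is.null(vertices_mm) == is.null(mask2d))
    stop("supply exactly one of `vertices_mm` or `mask2d`")
  if (!is.null(vertices_mm)) {
    vertices_mm <- as.matrix(vertices_mm)
    if (ncol(vertices_mm) != 2L || nrow(vertices_mm) < 3L)
      stop("`vertices_mm` must be an n x 2 matrix with n >= 3")
  }
  if (!is.null(mask2d)) {
    mask2d <- as.matrix(mask2d)
    storage.mode(mask2d) <- "logical"
  }
  structure(list(slice_index = slice_index, vertices_mm = vertices_mm,
                 mask2d = mask2d),
            class = "planar_roi")
}

#' @export
print.planar_roi <- function(x, ...) {
  what <- if (is.null(x$vertices_mm))
    sprintf("%d-voxel footprint", sum(x$mask2d))
  else
    sprintf("%d-vertex polygon", nrow(x$vertices_mm))
  cat(sprintf("Planar ROI on slice %d: %s\n", x$slice_index, what))
  invisible(x)
}

#' Read / write a polygon ROI as JSON
#'
#' The JSON layout is `{"slice_index": k, "vertices_mm": [[x, y], ...]}`
#' with `slice_index` 1-based.
#'
#' @param path JSON file path.
#' @return For `read_roi_json`, a [planar_roi].
#' @export
read_roi_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  planar_roi(obj$slice_index, vertices_mm = obj$vertices_mm)
}

#' @rdname read_roi_json
#' @param roi A polygon-based [planar_roi].
#' @export
write_roi_json <- function(roi, path) {
  stopifnot(inherits(roi, "planar_roi"), !is.null(roi$vertices_mm))
  jsonlite::write_json(
    list(slice_index = roi$slice_index, vertices_mm = roi$vertices_mm),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Rasterise a planar ROI to the in-plane grid of `vol`: membership of voxel
# centers under the even-odd rule for polygon ROIs, the stored mask otherwise.
roi_footprint <- function(roi, vol) {
  stopifnot(inherits(roi, "planar_roi"), inherits(vol, "suv_volume"))
  d <- dim(vol$values)
  if (!is.null(roi$mask2d)) {
    if (!identical(dim(roi$mask2d), d[1:2]))
      stop(sprintf("ROI footprint grid %s does not match volume in-plane grid %s",
                   paste(dim(roi$mask2d), collapse = "x"),
                   paste(d[1:2], collapse = "x")))
    return(roi$mask2d)
  }
  xs <- axis_coords(vol, 1)
  ys <- axis_coords(vol, 2)
  pts <- expand.grid(x = xs, y = ys)
  inside <- point_in_polygon(pts$x, pts$y,
                             roi$vertices_mm[, 1], roi$vertices_mm[, 2])
  matrix(inside, nrow = d[1], ncol = d[2])
}

#' Extrude a single planar ROI into a prism VOI
#'
#' Copies the ROI's 2D footprint identically to every axial slice in
#' `[z_min, z_max]`, emulating a single region drawn on one slice and
#' extrapolated to limiting slices. Deliberately, anything lying inside the
#' footprint at other depths — including physiological hot structures — ends
#' up inside the VOI; that is the characteristic failure mode of the
#' single-region prism strategy and is not filtered here.
#'
#' @param roi A [planar_roi].
#' @param z_min,z_max Inclusive axial slice range; must bracket
#'   `roi$slice_index` and lie within the grid.
#' @param vol The [suv_volume] defining the grid.
#' @return A [voi].
#' @export
extrude_single_roi <- function(roi, z_min, z_max, vol) {
  stopifnot(inherits(vol, "suv_volume"))
  z_min <- as.integer(z_min); z_max <- as.integer(z_max)
  nz <- dim(vol$values)[3]
  if (z_min > roi$slice_index || z_max < roi$slice_index)
    stop("slice range [", z_min, ", ", z_max, "] must contain the ROI slice ",
         roi$slice_index)
  if (z_min < 1L || z_max > nz) stop("slice range outside grid (1..", nz, ")")
  fp <- roi_footprint(roi, vol)
  if (!any(fp)) stop("ROI footprint contains no voxel centers")
  mask <- array(FALSE, dim(vol$values))
  mask[, , z_min:z_max] <- fp
  voi(mask)
}

#' Stack slice-wise ROIs into a VOI
#'
#' Union of per-slice footprints, one ROI at most per slice; slices without a
#' ROI stay empty. This emulates slice-by-slice editing in which only tumoral
#' regions are traced and physiological uptake is avoided.
#'
#' @param rois List of [planar_roi], pairwise distinct `slice_index`.
#' @param vol The [suv_volume] defining the grid.
#' @return A [voi].
#' @export
stack_slicewise_rois <- function(rois, vol) {
  stopifnot(inherits(vol, "suv_volume"), is.list(rois))
  idx <- vapply(rois, function(r) r$slice_index, integer(1))
  if (anyDuplicated(idx))
    stop("duplicate slice index: ", paste(idx[duplicated(idx)], collapse = ", "))
  nz <- dim(vol$values)[3]
  if (length(idx) && (min(idx) < 1L || max(idx) > nz))
    stop("slice index outside grid (1..", nz, ")")
  mask <- array(FALSE, dim(vol$values))
  for (r in rois) mask[, , r$slice_index] <- roi_footprint(r, vol)
  voi(mask)
}

#' Lesion set: one VOI per lesion
#'
#' @param vois List of [voi] with pairwise disjoint masks on a common grid.
#' @return An object of class `lesion_set`.
#' @export
lesion_set <- function(vois) {
  stopifnot(is.list(vois), length(vois) >= 1L,
            all(vapply(vois, inherits, logical(1), "voi")))
  d <- dim(vois[[1]]$mask)
  occupancy <- array(0L, d)
  for (v in vois) {
    if (!identical(dim(v$mask), d)) stop("lesion masks on different grids")
    occupancy <- occupancy + v$mask
  }
  if (any(occupancy > 1L)) stop("lesion masks overlap; they must be disjoint")
  structure(list(vois = vois), class = "lesion_set")
}

#' @export
print.lesion_set <- function(x, ...) {
  cat(sprintf("Lesion set: %d lesions, %s voxels\n", length(x$vois),
              paste(vapply(x$vois, voi_count, integer(1)), collapse = " + ")))
  invisible(x)
}

#' Union of the lesion VOIs
#'
#' Voxelwise OR; since the set is disjoint by construction the union count is
#' the sum of per-lesion counts.
#'
#' @param ls A [lesion_set].
#' @return A [voi].
#' @export
union_lesions <- function(ls) {
  stopifnot(inherits(ls, "lesion_set"))
  mask <- Reduce(`|`, lapply(ls$vois, `[[`, "mask"))
  voi(mask)
}
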