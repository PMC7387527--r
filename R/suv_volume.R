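#' SUV volume
#'
#' The image substrate the whole package operates on: a 3D grid of
#' standardized uptake values (SUV, g/mL convention, nonnegative) together
#' with its voxel spacing and world origin in millimetres. Voxel `(i, j, k)`
#' (1-based) has its center at `origin_mm + (c(i, j, k) - 1) * spacing_mm`;
#' the third index is the axial (slice) axis.
#'
#' @param values 3D numeric array of nonnegative SUV values.
#' @param spacing_mm Positive length-3 numeric, voxel spacing in mm.
#' @param origin_mm Length-3 numeric, world coordinate (mm) of the center of
#'   voxel `(1, 1, 1)`.
#' @return An object of class `suv_volume`.
#' @examples
#' vol <- suv_volume(array(1, c(8, 8, 4)), spacing_mm = c(2, 2, 2))
#' voxel_volume_cm3(vol)
#' @export
suv_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array, got ", length(dim(values)), " dims")
  if (any(values < 0)) stop("SUV values must be nonnegative")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0)) stop("`spacing_mm` must be positive")
  origin_mm <- as.numeric(origin_mm)
  stopifnot(length(origin_mm) == 3L)
  structure(
    list(values = values, spacing_mm = spacing_mm, origin_mm = origin_mm,
         axial_axis = 3L),
    class = "suv_volume"
  )
}

#' @export
print.suv_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("SUV volume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing_mm), collapse = " x ")))
  cat(sprintf("  SUV range [%.3g, %.3g], voxel volume %.4g cm^3\n",
              min(x$values), max(x$values), voxel_volume_cm3(x)))
  invisible(x)
}

#' Voxel volume in cubic centimetres
#'
#' @param vol A [suv_volume].
#' @return The volume of one voxel in cm^3 (product of spacings / 1000).
#' @export
voxel_volume_cm3 <- function(vol) {
  stopifnot(inherits(vol, "suv_volume"))
  prod(vol$spacing_mm) / 1000
}

#' Volume of interest (VOI)
#'
#' A 3D boolean mask aligned voxel-for-voxel with an [suv_volume]. All ROI
#' strategies produce a `voi`; the threshold segmentation consumes one.
#'
#' @param mask 3D logical (or 0/1) array.
#' @return An object of class `voi`.
#' @export
voi <- function(mask) {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3D array")
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("mask must not contain NA")
  structure(list(mask = mask), class = "voi")
}

#' @export
print.voi <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("VOI: %d of %d voxels selected (%d x %d x %d grid)\n",
              sum(x$mask), prod(d), d[1], d[2], d[3]))
  invisible(x)
}

#' Number of selected voxels in a VOI
#' @param x A [voi].
#' @return Integer count.
#' @export
voi_count <- function(x) {
  stopifnot(inherits(x, "voi"))
  sum(x$mask)
}

#' Physical volume of a VOI in cm^3
#' @param x A [voi].
#' @param vol The [suv_volume] the mask is aligned to (supplies the spacing).
#' @return Volume in cm^3.
#' @export
voi_volume_cm3 <- function(x, vol) {
  check_alignment(x, vol)
  voi_count(x) * voxel_volume_cm3(vol)
}

check_alignment <- function(voi, vol) {
  stopifnot(inherits(voi, "voi"), inherits(vol, "suv_volume"))
  if (!identical(dim(voi$mask), dim(vol$values)))
    stop(sprintf("mask grid %s does not match volume grid %s",
                 paste(dim(voi$mask), collapse = "x"),
                 paste(dim(vol$values), collapse = "x")))
  invisible(TRUE)
}

# World coordinates (mm) of voxel centers along one axis.
axis_coords <- function(vol, axis) {
  n <- dim(vol$values)[axis]
  vol$origin_mm[axis] + (seq_len(n) - 1) * vol$spacing_mm[axis]
}

#' Read an SUV volume from a NIfTI-1 file
#'
#' Reads a 3D NIfTI image (`.nii` or `.nii.gz`), taking the voxel spacing
#' from the header `pixdim` and the world origin from the qform/sform
#' translation.
#'
#' @param path Path to a NIfTI file.
#' @return An [suv_volume].
#' @export
read_suv_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  vals <- array(as.vector(img), dim(img))
  suv_volume(vals, spacing_mm = RNifti::pixdim(img)[1:3], origin_mm = origin)
}

#' Write an SUV volume as NIfTI-1
#'
#' Values are stored as 32-bit float, spacing in the header `pixdim`, origin
#' in an axis-aligned RAS qform.
#'
#' @param vol An [suv_volume].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_suv_volume <- function(vol, path) {
  stopifnot(inherits(vol, "suv_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing_mm
  xf <- diag(c(vol$spacing_mm, 1))
  xf[1:3, 4] <- vol$origin_mm
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a VOI mask from NIfTI, checking alignment against a volume
#'
#' @param path Path to a NIfTI mask (any nonzero voxel is selected).
#' @param vol The [suv_volume] the mask must align with; an error names both
#'   grids if shape or spacing disagree.
#' @return A [voi].
#' @export
read_mask <- function(path, vol) {
  stopifnot(inherits(vol, "suv_volume"))
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim(img))
  if (!identical(dim(arr), dim(vol$values)))
    stop(sprintf("mask grid %s does not match volume grid %s",
                 paste(dim(arr), collapse = "x"),
                 paste(dim(vol$values), collapse = "x")))
  sp <- RNifti::pixdim(img)[1:3]
  if (max(abs(sp - vol$spacing_mm)) > 1e-4)
    stop(sprintf("mask spacing (%s) does not match volume spacing (%s)",
                 paste(format(sp), collapse = ", "),
                 paste(format(vol$spacing_mm), collapse = ", ")))
  voi(arr != 0)
}

#' Write a VOI mask as NIfTI (unsigned 8-bit, 0/1)
#'
#' @param x A [voi].
#' @param path Output path.
#' @param vol Optional [suv_volume] supplying spacing and origin for the
#'   header; defaults to unit spacing.
#' @return `path`, invisibly.
#' @export
write_mask <- function(x, path, vol = NULL) {
  stopifnot(inherits(x, "voi"))
  arr <- array(0L, dim(x$mask))
  arr[x$mask] <- 1L
  img <- RNifti::asNifti(arr)
  if (!is.null(vol)) {
    check_alignment(x, vol)
    RNifti::pixdim(img) <- vol$spacing_mm
    xf <- diag(c(vol$spacing_mm, 1))
    xf[1:3, 4] <- vol$origin_mm
    RNifti::qform(img) <- structure(xf, code = 2L)
  }
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
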