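#' Lesion specification for the synthetic phantom
#'
#' An axis-aligned ellipsoid of uniform tracer uptake, described in world
#' millimetre coordinates. Before reconstruction blur the lesion is a plateau
#' at `uptake_suv`; ground truth is voxel-center membership of the ellipsoid.
#'
#' @param center_mm Length-3 numeric, ellipsoid center (mm).
#' @param radii_mm Length-3 positive numeric, ellipsoid semi-axes (mm). A
#'   single value is recycled (sphere).
#' @param uptake_suv Positive plateau SUV before blur.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center_mm, radii_mm, uptake_suv) {
  center_mm <- as.numeric(center_mm)
  radii_mm <- rep_len(as.numeric(radii_mm), 3L)
  stopifnot(length(center_mm) == 3L)
  if (any(radii_mm <= 0)) stop("radii_mm must all be positive")
  if (length(uptake_suv) != 1L || uptake_suv <= 0)
    stop("uptake_suv must be a single positive value")
  structure(list(center_mm = center_mm, radii_mm = radii_mm,
                 uptake_suv = as.numeric(uptake_suv)),
            class = "lesion_spec")
}

#' Analytic ellipsoid volume of a lesion, in cm^3
#' @param lesion A [lesion_spec].
#' @return 4/3 pi abc in cm^3.
#' @export
lesion_volume_cm3 <- function(lesion) {
  stopifnot(inherits(lesion, "lesion_spec"))
  4 / 3 * pi * prod(lesion$radii_mm) / 1000
}

#' Phantom specification
#'
#' Defines a torso-like synthetic SUV volume: a low uniform background, one
#' or more avid lesions, optional physiological hot structures (e.g. a
#' cardiac analogue — avid but non-tumoral), an isotropic Gaussian
#' reconstruction point-spread blur given as FWHM in mm (6.0 and 4.8 mm are
#' typical clinical reconstruction filters), and additive Gaussian noise in
#' SUV space clipped at zero.
#'
#' @param grid_shape Length-3 integer, at least `c(8, 8, 4)`.
#' @param spacing_mm Length-3 positive numeric (a single value is recycled).
#' @param background_suv Nonnegative background SUV.
#' @param lesions List of [lesion_spec] (tumoral; ground-truth masks emitted).
#' @param physiological List of [lesion_spec] for avid non-tumoral structures.
#' @param psf_fwhm_mm Nonnegative blur FWHM in mm (0 disables blur).
#' @param noise_sd_suv Nonnegative noise standard deviation in SUV units.
#' @param seed Integer seed making the rendered phantom fully reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, spacing_mm, background_suv = 0.5,
                         lesions = list(), physiological = list(),
                         psf_fwhm_mm = 6.0, noise_sd_suv = 0,
                         seed = 1L) {
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(grid_shape < c(8L, 8L, 4L)))
    stop("grid_shape must be at least 8 x 8 x 4")
  if (any(spacing_mm <= 0)) stop("spacing_mm must be positive")
  if (background_suv < 0) stop("background_suv must be nonnegative")
  if (psf_fwhm_mm < 0) stop("psf_fwhm_mm must be nonnegative")
  if (noise_sd_suv < 0) stop("noise_sd_suv must be nonnegative")
  if (!is.list(lesions)) lesions <- list(lesions)
  if (!is.list(physiological)) physiological <- list(physiological)
  stopifnot(all(vapply(lesions, inherits, logical(1), "lesion_spec")),
            all(vapply(physiological, inherits, logical(1), "lesion_spec")))
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 background_suv = as.numeric(background_suv),
                 lesions = lesions, physiological = physiological,
                 psf_fwhm_mm = as.numeric(psf_fwhm_mm),
                 noise_sd_suv = as.numeric(noise_sd_suv),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "Phantom spec: %s grid @ %s mm, background %.2g SUV, %d lesion(s), %d physiological, FWHM %.1f mm, noise sd %.2g, seed %d\n",
    paste(x$grid_shape, collapse = "x"),
    paste(format(x$spacing_mm), collapse = "x"),
    x$background_suv, length(x$lesions), length(x$physiological),
    x$psf_fwhm_mm, x$noise_sd_suv, x$seed))
  invisible(x)
}

# Voxel-center ellipsoid membership mask on the spec grid.
ellipsoid_mask <- function(lesion, grid_shape, spacing_mm, origin_mm = c(0, 0, 0)) {
  cx <- origin_mm[1] + (seq_len(grid_shape[1]) - 1) * spacing_mm[1]
  cy <- origin_mm[2] + (seq_len(grid_shape[2]) - 1) * spacing_mm[2]
  cz <- origin_mm[3] + (seq_len(grid_shape[3]) - 1) * spacing_mm[3]
  ux <- ((cx - lesion$center_mm[1]) / lesion$radii_mm[1])^2
  uy <- ((cy - lesion$center_mm[2]) / lesion$radii_mm[2])^2
  uz <- ((cz - lesion$center_mm[3]) / lesion$radii_mm[3])^2
  m <- outer(outer(ux, uy, `+`), uz, `+`) <= 1
  m
}

#' Render a phantom specification into an SUV volume
#'
#' Voxels whose centers fall inside a lesion or physiological ellipsoid are
#' set to that structure's uptake, everything else to the background; the
#' field is then blurred with the Gaussian point-spread (sigma = FWHM/2.355
#' per axis, in voxel units) and zero-mean Gaussian noise is added and
#' clipped at zero. Ground-truth masks are the unblurred voxel-center
#' ellipsoid memberships. Fully deterministic given `spec$seed`.
#'
#' Overlapping structures (lesion-lesion, lesion-physiological or
#' physiological-physiological, at voxel resolution) are an error, since the
#' ground truth would be ambiguous, as is a structure whose bounding box
#' extends beyond the grid.
#'
#' @param spec A [phantom_spec].
#' @return An object of class `suv_phantom`: a list with `volume`
#'   ([suv_volume]), `lesion_masks` (list of [voi], unblurred ground truth),
#'   `physio_mask` ([voi], union of physiological structures) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  sp <- spec$spacing_mm
  extent_lo <- rep(0, 3)
  extent_hi <- (d - 1) * sp
  structures <- c(spec$lesions, spec$physiological)
  for (s in structures) {
    if (any(s$center_mm - s$radii_mm < extent_lo) ||
        any(s$center_mm + s$radii_mm > extent_hi))
      stop("structure extends beyond the grid: center ",
           paste(format(s$center_mm), collapse = ", "), " radii ",
           paste(format(s$radii_mm), collapse = ", "))
  }
  vals <- array(spec$background_suv, d)
  masks <- lapply(structures, ellipsoid_mask, grid_shape = d, spacing_mm = sp)
  occ <- Reduce(`+`, lapply(masks, function(m) m * 1L), array(0L, d))
  if (any(occ > 1L))
    stop("structures overlap at voxel resolution; ground truth would be ambiguous")
  for (i in seq_along(structures)) vals[masks[[i]]] <- structures[[i]]$uptake_suv
  if (spec$psf_fwhm_mm > 0) {
    sigma_vox <- spec$psf_fwhm_mm / (2 * sqrt(2 * log(2))) / sp
    vals <- gaussian_blur_3d(vals, sigma_vox)
  }
  if (spec$noise_sd_suv > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(spec$seed)
    vals <- vals + array(stats::rnorm(prod(d), sd = spec$noise_sd_suv), d)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    vals[vals < 0] <- 0
  }
  n_les <- length(spec$lesions)
  lesion_masks <- lapply(masks[seq_len(n_les)], voi)
  physio <- if (length(spec$physiological))
    Reduce(`|`, masks[n_les + seq_along(spec$physiological)])
  else array(FALSE, d)
  structure(list(volume = suv_volume(vals, sp),
                 lesion_masks = lesion_masks,
                 physio_mask = voi(physio),
                 spec = spec),
            class = "suv_phantom")
}

#' @export
print.suv_phantom <- function(x, ...) {
  cat("Synthetic SUV phantom\n")
  print(x$spec)
  print(x$volume)
  invisible(x)
}

#' Ground-truth total lesion volume of a phantom, in cm^3
#'
#' Voxel-center membership count times voxel volume, summed over lesions
#' (physiological structures excluded).
#'
#' @param phantom An `suv_phantom`.
#' @return Volume in cm^3.
#' @export
true_lesion_volume_cm3 <- function(phantom) {
  stopifnot(inherits(phantom, "suv_phantom"))
  sum(vapply(phantom$lesion_masks, voi_count, integer(1))) *
    voxel_volume_cm3(phantom$volume)
}
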