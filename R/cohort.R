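#' Sampler settings for synthetic phantom cohorts
#'
#' Describes the distributions from which cohort phantoms are drawn. The
#' defaults emulate a baseline FDG-PET staging cohort of localized lymphoma:
#' one to four avid lesions in a torso-like field of view, an occasional
#' bulky mass, a cardiac-analogue physiological hot structure near the
#' lesions (so that the single-region prism strategy can mistake it for
#' disease), reconstruction blur of 6.0 mm FWHM, and modest SUV-space noise.
#' Lesion uptakes and the background level are configuration, not clinical
#' claims.
#'
#' @param grid_shape,spacing_mm Phantom grid (default 64 x 64 x 48 voxels at
#'   3 mm isotropic, i.e. a 19.2 x 19.2 x 14.4 cm field of view).
#' @param background_range Uniform range for the background SUV.
#' @param n_lesions_range Integer range for the lesion count (uniform).
#' @param radius_range_mm Uniform range for the base lesion radius; per-axis
#'   semi-axes get an extra uniform `c(0.8, 1.25)` anisotropy factor.
#' @param bulky_prob Probability that one lesion is a bulky mass.
#' @param bulky_radius_range_mm Base-radius range for a bulky mass.
#' @param uptake_range Uniform range for lesion plateau SUV.
#' @param physio_prob Probability a physiological hot structure is present.
#' @param physio_suppressed_prob Probability the structure's uptake is
#'   metabolically suppressed (below tumoral levels); myocardial FDG uptake
#'   is effectively bimodal depending on dietary suppression.
#' @param physio_suppressed_range,physio_intense_range Uniform uptake ranges
#'   for the suppressed and intense modes.
#' @param physio_radius_range_mm Radius range of the structure.
#' @param psf_fwhm_mm Reconstruction blur FWHM in mm.
#' @param noise_sd_suv Additive SUV-space noise standard deviation.
#' @param separation_margin_mm Minimum clearance enforced between structure
#'   surfaces (keeps per-lesion regions resolvable after dilation).
#' @return A list of class `cohort_sampler`.
#' @export
cohort_sampler <- function(grid_shape = c(64, 64, 48), spacing_mm = 3,
                           background_range = c(0.5, 1.0),
                           n_lesions_range = c(1L, 4L),
                           radius_range_mm = c(10, 30),
                           bulky_prob = 0.09,
                           bulky_radius_range_mm = c(40, 55),
                           uptake_range = c(4, 15),
                           physio_prob = 0.8,
                           physio_suppressed_prob = 0.5,
                           physio_suppressed_range = c(1.2, 2.4),
                           physio_intense_range = c(14, 20),
                           physio_radius_range_mm = c(14, 22),
                           psf_fwhm_mm = 6.0,
                           noise_sd_suv = 0.2,
                           separation_margin_mm = 14) {
  structure(as.list(environment()), class = "cohort_sampler")
}

# Draw one phantom_spec from the sampler using the current RNG stream.
# Structures are placed by rejection so that all ellipsoids fit inside the
# grid and surfaces stay `separation_margin_mm` apart; if a draw cannot be
# placed after many tries it is dropped (large/bulky configurations).
sample_phantom_spec <- function(sampler, seed) {
  gs <- as.integer(rep_len(sampler$grid_shape, 3L))
  sp <- rep_len(as.numeric(sampler$spacing_mm), 3L)
  extent <- (gs - 1) * sp
  bg <- stats::runif(1, sampler$background_range[1], sampler$background_range[2])
  n_les <- sample(seq(sampler$n_lesions_range[1], sampler$n_lesions_range[2]), 1L)
  bulky <- stats::runif(1) < sampler$bulky_prob

  placed <- list()  # list of (center, radii)
  try_place <- function(radii, edge_mm = 6) {
    lo <- radii + edge_mm
    hi <- extent - radii - edge_mm
    if (any(hi <= lo)) return(NULL)
    for (try in 1:200) {
      ctr <- stats::runif(3, lo, hi)
      ok <- TRUE
      for (p in placed) {
        gap <- sqrt(sum((ctr - p$center)^2)) - max(radii) - max(p$radii)
        if (gap < sampler$separation_margin_mm) { ok <- FALSE; break }
      }
      if (ok) return(ctr)
    }
    NULL
  }

  # one uptake level per subject with modest per-lesion spread: lesions of a
  # single patient's lymphoma carry similar SUV, and plateau phantoms with
  # independent uptakes would make whole lesions flip in/out of a relative
  # threshold's mask between 41% and 50%, which graded real lesions do not do
  base_uptake <- stats::runif(1, sampler$uptake_range[1], sampler$uptake_range[2])
  lesions <- list()
  for (i in seq_len(n_les)) {
    base <- if (bulky && i == 1L)
      stats::runif(1, sampler$bulky_radius_range_mm[1], sampler$bulky_radius_range_mm[2])
    else
      stats::runif(1, sampler$radius_range_mm[1], sampler$radius_range_mm[2])
    radii <- base * stats::runif(3, 0.8, 1.25)
    ctr <- try_place(radii)
    if (is.null(ctr)) next
    placed[[length(placed) + 1L]] <- list(center = ctr, radii = radii)
    lesions[[length(lesions) + 1L]] <-
      lesion_spec(ctr, radii, base_uptake * stats::runif(1, 0.75, 1.25))
  }
  if (!length(lesions)) {  # always emit at least one small lesion
    radii <- sampler$radius_range_mm[1] * stats::runif(3, 0.8, 1.1)
    ctr <- extent / 2
    placed[[length(placed) + 1L]] <- list(center = ctr, radii = radii)
    lesions[[1L]] <- lesion_spec(ctr, radii,
                                 base_uptake * stats::runif(1, 0.75, 1.25))
  }

  physiological <- list()
  if (stats::runif(1) < sampler$physio_prob) {
    radii <- stats::runif(1, sampler$physio_radius_range_mm[1],
                          sampler$physio_radius_range_mm[2]) *
      stats::runif(3, 0.85, 1.15)
    # amid the lesions in-plane (near their centroid) and within their axial
    # extent, the way the heart sits between nodal stations: the single-ROI
    # prism then tends to capture it while slice-wise editing avoids it
    cen <- Reduce(`+`, lapply(lesions, `[[`, "center_mm")) / length(lesions)
    for (try in 1:600) {
      # progressively widen the search: crowded multi-lesion fields still get
      # their physiological structure, just pushed a little further out
      widen <- 1 + (try %/% 150)
      ctr <- c(cen[1] + stats::rnorm(1, 0, 10 * widen),
               cen[2] + stats::rnorm(1, 0, 10 * widen),
               cen[3] + stats::runif(1, -25 * widen, 25 * widen))
      ctr <- pmin(pmax(ctr, radii + 4), extent - radii - 4)
      ok <- TRUE
      for (p in placed) {
        gap <- sqrt(sum((ctr - p$center)^2)) - max(radii) - max(p$radii)
        if (gap < sampler$separation_margin_mm) { ok <- FALSE; break }
      }
      if (ok) {
        rng <- if (stats::runif(1) < sampler$physio_suppressed_prob)
          sampler$physio_suppressed_range else sampler$physio_intense_range
        physiological[[1L]] <- lesion_spec(ctr, radii,
                                           stats::runif(1, rng[1], rng[2]))
        break
      }
    }
  }

  phantom_spec(grid_shape = gs, spacing_mm = sp, background_suv = bg,
               lesions = lesions, physiological = physiological,
               psf_fwhm_mm = sampler$psf_fwhm_mm,
               noise_sd_suv = sampler$noise_sd_suv, seed = seed)
}

# Ground-truth voxel-count lesion volume of a spec, without rendering blur.
spec_true_volume_cm3 <- function(spec) {
  vv <- prod(spec$spacing_mm) / 1000
  sum(vapply(spec$lesions, function(l) {
    sum(ellipsoid_mask(l, spec$grid_shape, spec$spacing_mm))
  }, numeric(1))) * vv
}

#' Generate a synthetic cohort of phantoms with survival outcomes
#'
#' Draws `n` phantom specifications from a [cohort_sampler] and simulates a
#' progression-free-survival outcome per subject from an exponential
#' event-time model whose rate increases with the subject's true total
#' lesion volume, right-censored by a uniform follow-up window. Two hazard
#' links are available:
#' \describe{
#'   \item{`proportional`}{rate = `hazard_scale` x volume (cm^3), in
#'     events/month — the default link.}
#'   \item{`step`}{rate = `step_rates[1]` below `step_volume_cm3`,
#'     `step_rates[2]` above it; useful for cutoff-recovery experiments
#'     because the prognostic signal is a pure threshold on volume.}
#' }
#'
#' @param n Number of subjects (>= 1).
#' @param sampler A [cohort_sampler].
#' @param hazard `"proportional"` or `"step"`.
#' @param hazard_scale Rate per cm^3 per month for the proportional link.
#' @param step_volume_cm3,step_rates Step-link parameters.
#' @param followup_range_months Uniform censoring window, in months.
#' @param seed Integer root seed; the whole cohort (specs and outcomes) is a
#'   deterministic function of it.
#' @return An object of class `phantom_cohort`: list with `specs` (list of
#'   [phantom_spec]), `outcomes` (data.frame `subject_id`, `time_months`,
#'   `event`), `true_volume_cm3` (numeric), and the generation parameters.
#' @export
generate_cohort <- function(n, sampler = cohort_sampler(),
                            hazard = c("proportional", "step"),
                            hazard_scale = 3e-4,
                            step_volume_cm3 = NULL,
                            step_rates = c(0.002, 0.05),
                            followup_range_months = c(3, 104),
                            seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  hazard <- match.arg(hazard)
  if (hazard == "step" && is.null(step_volume_cm3))
    stop("step hazard requires `step_volume_cm3`")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  subject_seeds <- sample.int(.Machine$integer.max, n)
  specs <- vector("list", n)
  vols <- numeric(n)
  for (i in seq_len(n)) {
    specs[[i]] <- sample_phantom_spec(sampler, seed = subject_seeds[i])
    vols[i] <- spec_true_volume_cm3(specs[[i]])
  }
  rate <- switch(hazard,
                 proportional = hazard_scale * vols,
                 step = ifelse(vols > step_volume_cm3, step_rates[2], step_rates[1]))
  t_event <- ifelse(rate > 0, stats::rexp(n, rate = pmax(rate, 1e-12)), Inf)
  t_cens <- stats::runif(n, followup_range_months[1], followup_range_months[2])
  event <- rate > 0 & t_event <= t_cens
  time <- pmin(t_event, t_cens)
  outcomes <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    time_months = time,
    event = event,
    stringsAsFactors = FALSE)
  structure(list(specs = specs, outcomes = outcomes, true_volume_cm3 = vols,
                 hazard = hazard, hazard_scale = hazard_scale,
                 step_volume_cm3 = step_volume_cm3, step_rates = step_rates,
                 followup_range_months = followup_range_months,
                 sampler = sampler, seed = as.integer(seed)),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("Phantom cohort: %d subjects, %d events, true volume %.1f-%.1f cm^3 (median %.1f), %s hazard, seed %d\n",
              nrow(x$outcomes), sum(x$outcomes$event),
              min(x$true_volume_cm3), max(x$true_volume_cm3),
              stats::median(x$true_volume_cm3), x$hazard, x$seed))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Renders every phantom and writes, per subject, the SUV volume and each
#' ground-truth lesion mask plus the physiological mask as NIfTI (`.nii.gz`),
#' alongside `outcomes.csv` (`subject_id,time_months,event`) and a
#' `manifest.json` echoing every phantom specification including its seed.
#'
#' @param cohort A `phantom_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$specs)) {
    id <- cohort$outcomes$subject_id[i]
    ph <- generate_phantom(cohort$specs[[i]])
    write_suv_volume(ph$volume, file.path(dir, paste0(id, "_suv.nii.gz")))
    for (j in seq_along(ph$lesion_masks))
      write_mask(ph$lesion_masks[[j]],
                 file.path(dir, sprintf("%s_lesion%02d.nii.gz", id, j)),
                 vol = ph$volume)
    write_mask(ph$physio_mask, file.path(dir, paste0(id, "_physio.nii.gz")),
               vol = ph$volume)
  }
  utils::write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  manifest <- list(seed = cohort$seed, hazard = cohort$hazard,
                   hazard_scale = cohort$hazard_scale,
                   step_volume_cm3 = cohort$step_volume_cm3,
                   step_rates = cohort$step_rates,
                   followup_range_months = cohort$followup_range_months,
                   true_volume_cm3 = cohort$true_volume_cm3,
                   specs = lapply(cohort$specs, function(sp) {
                     sp <- unclass(sp)
                     sp$lesions <- lapply(sp$lesions, unclass)
                     sp$physiological <- lapply(sp$physiological, unclass)
                     sp
                   }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
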