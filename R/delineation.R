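#' Threshold specification
#'
#' Either an absolute SUV cutoff (e.g. 2.5) or a relative one, a fraction of
#' the regional SUVmax (e.g. 0.41 or 0.50). Voxel selection is strict:
#' a voxel belongs to the segmentation iff its SUV is strictly greater than
#' the applied threshold (see [suv_over_threshold] for the single predicate
#' encoding that convention).
#'
#' @param kind `"absolute"` or `"relative"`.
#' @param value Positive SUV for absolute; fraction in (0, 1) for relative.
#' @return An object of class `threshold_spec`.
#' @examples
#' threshold_spec("absolute", 2.5)
#' threshold_spec("relative", 0.41)
#' parse_threshold("rel:0.50")
#' @export
threshold_spec <- function(kind = c("absolute", "relative"), value) {
  kind <- match.arg(kind)
  value <- as.numeric(value)
  stopifnot(length(value) == 1L)
  if (kind == "absolute" && value <= 0)
    stop("absolute threshold must be positive")
  if (kind == "relative" && (value <= 0 || value >= 1))
    stop("relative threshold must lie in (0, 1)")
  structure(list(kind = kind, value = value), class = "threshold_spec")
}

#' @rdname threshold_spec
#' @param text A compact string, `"abs:2.5"` or `"rel:0.41"`.
#' @export
parse_threshold <- function(text) {
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("expected 'abs:<suv>' or 'rel:<fraction>', got ", text)
  kind <- switch(parts[1], abs = "absolute", rel = "relative",
                 stop("unknown threshold kind: ", parts[1]))
  threshold_spec(kind, as.numeric(parts[2]))
}

#' @export
format.threshold_spec <- function(x, ...) {
  if (x$kind == "absolute") sprintf("abs:%g", x$value)
  else sprintf("rel:%g", x$value)
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(if (x$kind == "absolute")
    sprintf("Absolute SUV threshold: SUV > %g\n", x$value)
    else sprintf("Relative threshold: SUV > %g%% of regional SUVmax\n", 100 * x$value))
  invisible(x)
}

#' The voxel-selection predicate
#'
#' One place encodes the package-wide convention that a voxel is selected
#' when its SUV is strictly over the threshold; switching to `>=` is a
#' one-line change here.
#'
#' @param suv Numeric vector of SUV values.
#' @param threshold_suv The applied threshold in SUV units.
#' @return Logical vector.
#' @export
suv_over_threshold <- function(suv, threshold_suv) {
  suv > threshold_suv
}

#' Apply a SUV threshold inside a VOI
#'
#' For an absolute threshold the applied cutoff is the given SUV; for a
#' relative one it is `value * max(SUV over the VOI)` (the regional SUVmax is
#' taken over the VOI, not the whole volume). The mask is the set of VOI
#' voxels whose SUV is strictly over the applied cutoff — pure voxelwise
#' selection, no connectivity filtering.
#'
#' @param vol An [suv_volume].
#' @param x A nonempty [voi].
#' @param t A [threshold_spec].
#' @return List with `mask` ([voi]) and `threshold_used_suv`.
#' @export
apply_threshold <- function(vol, x, t) {
  check_alignment(x, vol)
  stopifnot(inherits(t, "threshold_spec"))
  if (!any(x$mask)) stop("VOI is empty; nothing to threshold")
  thr <- if (t$kind == "absolute") t$value else {
    mx <- max(vol$values[x$mask])
    if (mx <= 0)
      stop("relative threshold undefined: VOI contains only zero SUV")
    t$value * mx
  }
  mask <- array(FALSE, dim(vol$values))
  mask[x$mask] <- suv_over_threshold(vol$values[x$mask], thr)
  list(mask = voi(mask), threshold_used_suv = thr)
}

#' Peak SUV over a 1 cm^3 sphere
#'
#' For every candidate center voxel in `scope`, averages the SUV of all
#' voxels whose centers lie within the sphere radius of the candidate's
#' center (default sphere volume 1.0 cm^3, radius ~6.2 mm), clipping the
#' sphere at grid edges (out-of-grid members are dropped from numerator and
#' denominator); returns the maximum such mean.
#'
#' @param vol An [suv_volume].
#' @param scope A nonempty [voi] of candidate centers.
#' @param sphere_volume_cm3 Averaging-sphere volume (cm^3).
#' @return SUVpeak as a single number.
#' @export
suv_peak <- function(vol, scope, sphere_volume_cm3 = 1.0) {
  check_alignment(scope, vol)
  if (!any(scope$mask)) stop("SUVpeak scope is empty")
  r_mm <- (3 * sphere_volume_cm3 * 1000 / (4 * pi))^(1 / 3)
  d <- dim(vol$values)
  off <- ball_offsets(r_mm, vol$spacing_mm)
  ctr <- which(scope$mask, arr.ind = TRUE)
  sums <- numeric(nrow(ctr))
  cnts <- numeric(nrow(ctr))
  n12 <- d[1] * d[2]
  for (m in seq_len(nrow(off))) {
    i <- ctr[, 1] + off[m, 1]
    j <- ctr[, 2] + off[m, 2]
    k <- ctr[, 3] + off[m, 3]
    ok <- i >= 1L & i <= d[1] & j >= 1L & j <= d[2] & k >= 1L & k <= d[3]
    idx <- i[ok] + (j[ok] - 1L) * d[1] + (k[ok] - 1L) * n12
    sums[ok] <- sums[ok] + vol$values[idx]
    cnts[ok] <- cnts[ok] + 1
  }
  max(sums / cnts)
}

#' Extract PET metrics from a segmentation mask
#'
#' TMTV is the mask voxel count times the voxel volume (cm^3); SUVmean and
#' SUVmax are the arithmetic mean and maximum over the mask; TLG is
#' SUVmean x TMTV; SUVpeak is computed over `peak_scope` (see [suv_peak]).
#'
#' @param vol An [suv_volume].
#' @param mask A nonempty [voi] — the thresholded segmentation.
#' @param peak_scope [voi] of SUVpeak candidate centers (often the VOI or the
#'   mask itself).
#' @param threshold_used_suv The applied cutoff, echoed into the result (and
#'   named in the empty-mask diagnostic).
#' @param sphere_volume_cm3 SUVpeak sphere volume.
#' @return An object of class `delineation_result`.
#' @export
compute_metrics <- function(vol, mask, peak_scope = mask,
                            threshold_used_suv = NA_real_,
                            sphere_volume_cm3 = 1.0) {
  check_alignment(mask, vol)
  if (!any(mask$mask))
    stop("empty segmentation mask (threshold ",
         format(threshold_used_suv), " SUV selected no voxels)")
  vv <- voxel_volume_cm3(vol)
  sel <- vol$values[mask$mask]
  tmtv <- length(sel) * vv
  m <- mean(sel)
  res <- list(
    mask = mask,
    tmtv_cm3 = tmtv,
    suv_mean = m,
    suv_max = max(sel),
    suv_peak = suv_peak(vol, peak_scope, sphere_volume_cm3),
    tlg_cm3 = m * tmtv,
    threshold_used_suv = threshold_used_suv)
  class(res) <- "delineation_result"
  res
}

#' @export
print.delineation_result <- function(x, ...) {
  cat(sprintf("Delineation (SUV > %s):\n", format(x$threshold_used_suv)))
  cat(sprintf("  TMTV    %10.3f cm^3  (%d voxels)\n", x$tmtv_cm3, voi_count(x$mask)))
  cat(sprintf("  SUVmean %10.3f\n", x$suv_mean))
  cat(sprintf("  SUVmax  %10.3f\n", x$suv_max))
  cat(sprintf("  SUVpeak %10.3f\n", x$suv_peak))
  cat(sprintf("  TLG     %10.3f cm^3\n", x$tlg_cm3))
  invisible(x)
}

#' @export
as.data.frame.delineation_result <- function(x, ...) {
  data.frame(tmtv_cm3 = x$tmtv_cm3, suv_mean = x$suv_mean,
             suv_max = x$suv_max, suv_peak = x$suv_peak,
             tlg_cm3 = x$tlg_cm3, threshold_used_suv = x$threshold_used_suv)
}

#' Delineate: threshold a VOI and extract metrics
#'
#' Composition of [apply_threshold] and [compute_metrics]. `peak_scope`
#' selects where SUVpeak candidate centers come from: `"voi"` scans the
#' whole VOI (SUVpeak is then identical across thresholds applied to the
#' same VOI), `"mask"` scans only the thresholded mask (SUVpeak then depends
#' on the threshold) — the two behaviours observed in different clinical
#' software.
#'
#' @inheritParams apply_threshold
#' @param peak_scope `"voi"` or `"mask"`.
#' @param sphere_volume_cm3 SUVpeak sphere volume (cm^3).
#' @return A `delineation_result`.
#' @export
delineate <- function(vol, x, t, peak_scope = c("voi", "mask"),
                      sphere_volume_cm3 = 1.0) {
  peak_scope <- match.arg(peak_scope)
  seg <- apply_threshold(vol, x, t)
  scope <- if (peak_scope == "voi") x else seg$mask
  compute_metrics(vol, seg$mask, peak_scope = scope,
                  threshold_used_suv = seg$threshold_used_suv,
                  sphere_volume_cm3 = sphere_volume_cm3)
}

#' Delineate a multi-lesion set
#'
#' Each lesion VOI is thresholded independently. For relative thresholds,
#' `suvmax_scope` chooses the reference SUVmax: `"per_lesion"` uses each
#' lesion's own VOI maximum (default), `"global"` the maximum over the union
#' of all lesion VOIs. Summary metrics: TMTV is the sum of per-lesion TMTVs;
#' SUVmean is the volume-weighted mean over the union of the per-lesion
#' masks; SUVmax the maximum over the union; TLG = SUVmean x TMTV; SUVpeak
#' over the union VOI or union mask per `peak_scope`. A lesion whose mask
#' comes out empty contributes zero with a warning rather than failing the
#' whole subject.
#'
#' @param vol An [suv_volume].
#' @param ls A [lesion_set] (nonempty, disjoint).
#' @param t A [threshold_spec].
#' @param suvmax_scope `"per_lesion"` or `"global"`.
#' @param peak_scope `"voi"` or `"mask"`.
#' @param sphere_volume_cm3 SUVpeak sphere volume (cm^3).
#' @return A `delineation_result` whose `mask` is the union of per-lesion
#'   masks, with attributes `per_lesion` (data.frame of per-lesion TMTV and
#'   applied cutoffs) and `suvmax_scope`.
#' @export
delineate_multiple <- function(vol, ls, t,
                               suvmax_scope = c("per_lesion", "global"),
                               peak_scope = c("voi", "mask"),
                               sphere_volume_cm3 = 1.0) {
  stopifnot(inherits(ls, "lesion_set"))
  suvmax_scope <- match.arg(suvmax_scope)
  peak_scope <- match.arg(peak_scope)
  union_voi <- union_lesions(ls)
  check_alignment(union_voi, vol)
  global_max <- max(vol$values[union_voi$mask])
  d <- dim(vol$values)
  union_mask <- array(FALSE, d)
  per <- data.frame(lesion = seq_along(ls$vois), n_voxels = 0L,
                    threshold_used_suv = NA_real_)
  for (i in seq_along(ls$vois)) {
    v <- ls$vois[[i]]
    thr <- if (t$kind == "absolute") t$value else {
      ref <- if (suvmax_scope == "global") global_max else max(vol$values[v$mask])
      t$value * ref
    }
    sel <- array(FALSE, d)
    sel[v$mask] <- suv_over_threshold(vol$values[v$mask], thr)
    n <- sum(sel)
    if (n == 0L)
      warning(sprintf("lesion %d: no voxel over SUV %.3g; contributes 0", i, thr))
    per$n_voxels[i] <- n
    per$threshold_used_suv[i] <- thr
    union_mask <- union_mask | sel
  }
  if (!any(union_mask))
    stop("no lesion survived thresholding (", format(t), ")")
  vv <- voxel_volume_cm3(vol)
  sel <- vol$values[union_mask]
  scope <- if (peak_scope == "voi") union_voi else voi(union_mask)
  res <- list(
    mask = voi(union_mask),
    tmtv_cm3 = length(sel) * vv,
    suv_mean = mean(sel),
    suv_max = max(sel),
    suv_peak = suv_peak(vol, scope, sphere_volume_cm3),
    tlg_cm3 = mean(sel) * length(sel) * vv,
    threshold_used_suv = if (t$kind == "absolute") t$value else NA_real_)
  class(res) <- "delineation_result"
  attr(res, "per_lesion") <- per
  attr(res, "suvmax_scope") <- suvmax_scope
  res
}
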