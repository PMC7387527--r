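# Automated "readers": derive the three VOI strategies from a phantom's
# ground truth, emulating how a human operator contours.

# 2D dilation of a logical matrix by a disk of radius_mm.
dilate_slice <- function(mask2d, spacing_mm, radius_mm) {
  if (radius_mm <= 0 || !any(mask2d)) return(mask2d)
  d <- dim(mask2d)
  nr <- pmax(0L, as.integer(ceiling(radius_mm / spacing_mm[1:2])))
  off <- as.matrix(expand.grid(i = -nr[1]:nr[1], j = -nr[2]:nr[2]))
  d2 <- (off[, 1] * spacing_mm[1])^2 + (off[, 2] * spacing_mm[2])^2
  off <- off[d2 <= radius_mm^2, , drop = FALSE]
  ctr <- which(mask2d, arr.ind = TRUE)
  out <- matrix(FALSE, d[1], d[2])
  for (m in seq_len(nrow(off))) {
    i <- ctr[, 1] + off[m, 1]
    j <- ctr[, 2] + off[m, 2]
    ok <- i >= 1L & i <= d[1] & j >= 1L & j <= d[2]
    out[cbind(i[ok], j[ok])] <- TRUE
  }
  out
}

#' Automated single-region prism VOI
#'
#' Emulates drawing one region on a single axial slice around all avid foci
#' and extrapolating it to the limiting slices: the in-plane convex hull of
#' the projected ground-truth lesion voxels, grown by a safety margin, is
#' extruded over the lesions' axial extent (plus margin). By construction
#' this prism can — and often does — swallow physiological hot structures
#' lying inside the footprint at other depths; that behaviour is the point
#' of modelling the strategy and is not corrected.
#'
#' @param phantom An `suv_phantom`.
#' @param margin_mm Contouring safety margin in mm.
#' @return A [voi].
#' @export
auto_prism_voi <- function(phantom, margin_mm = 6) {
  stopifnot(inherits(phantom, "suv_phantom"))
  vol <- phantom$volume
  sp <- vol$spacing_mm
  gt <- Reduce(`|`, lapply(phantom$lesion_masks, `[[`, "mask"))
  proj <- apply(gt, c(1, 2), any)
  ctr <- which(proj, arr.ind = TRUE)
  if (!nrow(ctr)) stop("phantom has no lesion voxels")
  px <- (ctr[, 1] - 1) * sp[1] + vol$origin_mm[1]
  py <- (ctr[, 2] - 1) * sp[2] + vol$origin_mm[2]
  # ring of points around every projected center so the hull covers the
  # full margin-grown footprint (1/cos(pi/8) corrects the octagon inradius)
  ang <- (0:7) * pi / 4
  rr <- margin_mm / cos(pi / 8) + max(sp[1:2]) / 2
  hx <- as.vector(outer(px, rr * cos(ang), `+`))
  hy <- as.vector(outer(py, rr * sin(ang), `+`))
  h <- grDevices::chull(hx, hy)
  zs <- which(apply(gt, 3, any))
  mz <- as.integer(ceiling(margin_mm / sp[3]))
  z_min <- max(1L, min(zs) - mz)
  z_max <- min(dim(gt)[3], max(zs) + mz)
  roi <- planar_roi(slice_index = zs[ceiling(length(zs) / 2)],
                    vertices_mm = cbind(hx[h], hy[h]))
  extrude_single_roi(roi, z_min, z_max, vol)
}

#' Automated slice-wise VOI
#'
#' Emulates slice-by-slice editing: on every slice the ground-truth lesion
#' footprint is grown by the margin and any physiological voxels on that
#' slice are erased, so only tumoral regions are kept.
#'
#' @inheritParams auto_prism_voi
#' @return A [voi].
#' @export
auto_slicewise_voi <- function(phantom, margin_mm = 6) {
  stopifnot(inherits(phantom, "suv_phantom"))
  vol <- phantom$volume
  gt <- Reduce(`|`, lapply(phantom$lesion_masks, `[[`, "mask"))
  rois <- list()
  for (z in which(apply(gt, 3, any))) {
    fp <- dilate_slice(gt[, , z], vol$spacing_mm, margin_mm) &
      !phantom$physio_mask$mask[, , z]
    rois[[length(rois) + 1L]] <- planar_roi(z, mask2d = fp)
  }
  stack_slicewise_rois(rois, vol)
}

#' Automated per-lesion VOIs
#'
#' One region per lesion: the 3D margin-grown ground-truth mask, minus
#' physiological voxels and any voxel of another lesion; contested voxels go
#' to the earlier lesion so the set stays disjoint.
#'
#' @inheritParams auto_prism_voi
#' @return A [lesion_set].
#' @export
auto_multiple_vois <- function(phantom, margin_mm = 6) {
  stopifnot(inherits(phantom, "suv_phantom"))
  vol <- phantom$volume
  other <- Reduce(`|`, lapply(phantom$lesion_masks, `[[`, "mask"))
  claimed <- array(FALSE, dim(vol$values))
  vois <- vector("list", length(phantom$lesion_masks))
  for (i in seq_along(phantom$lesion_masks)) {
    own <- phantom$lesion_masks[[i]]$mask
    m <- dilate_mask(own, vol$spacing_mm, margin_mm) &
      !phantom$physio_mask$mask & !(other & !own) & !claimed
    claimed <- claimed | m
    vois[[i]] <- voi(m)
  }
  lesion_set(vois)
}

#' Study configuration
#'
#' Describes one full comparison run: cohort source, contouring strategies,
#' thresholds, SUVpeak and SUVmax scoping, agreement scale and contouring
#' margin.
#'
#' @param cohort Either a `phantom_cohort` or a list of arguments for
#'   [generate_cohort] (must include `n` and `seed`).
#' @param strategies Subset of `"prism_single"`, `"slicewise_single"`,
#'   `"multiple_roi"`.
#' @param thresholds List of [threshold_spec] (or compact strings); default
#'   absolute 2.5 plus relative 41% and 50%.
#' @param peak_scope `"voi"` or `"mask"` (see [delineate]).
#' @param suvmax_scope `"per_lesion"` or `"global"` (multi-lesion relative
#'   thresholds; see [delineate_multiple]).
#' @param agreement_scale `"log"` or `"raw"`.
#' @param margin_mm Automated contouring margin.
#' @param horizon_months Optional ROC horizon (see [prognostic_analysis]).
#' @return A list of class `study_config`.
#' @export
study_config <- function(cohort,
                         strategies = c("prism_single", "slicewise_single",
                                        "multiple_roi"),
                         thresholds = list("abs:2.5", "rel:0.41", "rel:0.50"),
                         peak_scope = c("voi", "mask"),
                         suvmax_scope = c("per_lesion", "global"),
                         agreement_scale = c("log", "raw"),
                         margin_mm = 6,
                         horizon_months = NULL) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  if (length(strategies) < 1L) stop("need at least one strategy")
  thresholds <- lapply(thresholds, function(t)
    if (inherits(t, "threshold_spec")) t else parse_threshold(t))
  if (length(thresholds) < 1L) stop("need at least one threshold")
  structure(list(cohort = cohort, strategies = strategies,
                 thresholds = thresholds,
                 peak_scope = match.arg(peak_scope),
                 suvmax_scope = match.arg(suvmax_scope),
                 agreement_scale = match.arg(agreement_scale),
                 margin_mm = margin_mm,
                 horizon_months = horizon_months),
            class = "study_config")
}

config_digest <- function(cfg) {
  spec <- cfg
  if (inherits(spec$cohort, "phantom_cohort"))
    spec$cohort <- list(n = nrow(spec$cohort$outcomes), seed = spec$cohort$seed,
                        hazard = spec$cohort$hazard)
  txt <- jsonlite::toJSON(rapply(unclass(spec), unclass, how = "replace"),
                          auto_unbox = TRUE, digits = NA, force = TRUE)
  f <- tempfile()
  writeLines(as.character(txt), f)
  unname(tools::md5sum(f))
}

#' Run the full delineation comparison study
#'
#' Generates (or takes) a phantom cohort, delineates every subject under
#' every configured (strategy, threshold) arm, then computes pairwise
#' agreement statistics — every threshold pair within each strategy and
#' every strategy pair within each threshold — and a prognostic report
#' (ROC/Youden cutoff on TMTV, Kaplan-Meier split, log-rank) per arm.
#' A failing subject is logged and skipped, never fatal. Outputs are
#' byte-identical across reruns with the same configuration and seed.
#'
#' @param cfg A [study_config].
#' @param out_dir Optional directory; if given, writes `metrics.csv`,
#'   `agreement.csv`, `prognosis.json` and `manifest.json` (CSV files carry
#'   the config hash in a leading comment line).
#' @param verbose Emit a progress message per subject.
#' @return An object of class `tmtv_study`: `metrics` (one row per subject x
#'   strategy x threshold), `agreement` (one row per quantity x arm pair),
#'   `prognosis` (named list of `prognosis_report`), `failures`, `cohort`,
#'   `config`, `config_hash`.
#' @export
run_study <- function(cfg, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "study_config"))
  cohort <- if (inherits(cfg$cohort, "phantom_cohort")) cfg$cohort
  else do.call(generate_cohort, cfg$cohort)
  n <- nrow(cohort$outcomes)
  thr_labels <- vapply(cfg$thresholds, format, character(1))

  rows <- list()
  failures <- character(0)
  for (i in seq_len(n)) {
    id <- cohort$outcomes$subject_id[i]
    res <- tryCatch({
      ph <- generate_phantom(cohort$specs[[i]])
      vois <- list()
      if ("prism_single" %in% cfg$strategies)
        vois$prism_single <- auto_prism_voi(ph, cfg$margin_mm)
      if ("slicewise_single" %in% cfg$strategies)
        vois$slicewise_single <- auto_slicewise_voi(ph, cfg$margin_mm)
      if ("multiple_roi" %in% cfg$strategies)
        vois$multiple_roi <- auto_multiple_vois(ph, cfg$margin_mm)
      sub <- list()
      for (strat in cfg$strategies) {
        for (k in seq_along(cfg$thresholds)) {
          t <- cfg$thresholds[[k]]
          dr <- if (strat == "multiple_roi")
            delineate_multiple(ph$volume, vois$multiple_roi, t,
                               suvmax_scope = cfg$suvmax_scope,
                               peak_scope = cfg$peak_scope)
          else delineate(ph$volume, vois[[strat]], t,
                         peak_scope = cfg$peak_scope)
          sub[[length(sub) + 1L]] <- cbind(
            data.frame(subject_id = id, strategy = strat,
                       threshold = thr_labels[k], stringsAsFactors = FALSE),
            as.data.frame(dr),
            data.frame(true_volume_cm3 = cohort$true_volume_cm3[i],
                       time_months = cohort$outcomes$time_months[i],
                       event = cohort$outcomes$event[i]))
        }
      }
      do.call(rbind, sub)
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", id, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    if (verbose) message(sprintf("[%d/%d] %s done", i, n, id))
  }
  if (!length(rows)) stop("every subject failed: ",
                          paste(failures, collapse = "; "))
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL

  agreement <- study_agreement(metrics, cfg)
  prognosis <- study_prognosis(metrics, cohort$outcomes, cfg)

  out <- structure(list(metrics = metrics, agreement = agreement,
                        prognosis = prognosis, failures = failures,
                        cohort = cohort, config = cfg,
                        config_hash = config_digest(cfg)),
                   class = "tmtv_study")
  if (!is.null(out_dir)) write_study(out, out_dir)
  out
}

arm_values <- function(metrics, strategy, threshold, quantity) {
  sel <- metrics$strategy == strategy & metrics$threshold == threshold
  v <- metrics[sel, c("subject_id", quantity)]
  v[order(v$subject_id), ]
}

study_agreement <- function(metrics, cfg) {
  quantities <- c(tmtv = "tmtv_cm3", tlg = "tlg_cm3", suv_mean = "suv_mean",
                  suv_max = "suv_max", suv_peak = "suv_peak")
  thr_labels <- vapply(cfg$thresholds, format, character(1))
  pairs <- list()
  # within-strategy threshold pairs
  if (length(thr_labels) >= 2L)
    for (strat in cfg$strategies)
      for (p in utils::combn(thr_labels, 2, simplify = FALSE))
        pairs[[length(pairs) + 1L]] <-
          list(arm_a = paste(strat, p[1], sep = "|"),
               arm_b = paste(strat, p[2], sep = "|"),
               sa = strat, sb = strat, ta = p[1], tb = p[2],
               kind = "threshold_pair")
  # between-strategy pairs per threshold
  if (length(cfg$strategies) >= 2L)
    for (tl in thr_labels)
      for (p in utils::combn(cfg$strategies, 2, simplify = FALSE))
        pairs[[length(pairs) + 1L]] <-
          list(arm_a = paste(p[1], tl, sep = "|"),
               arm_b = paste(p[2], tl, sep = "|"),
               sa = p[1], sb = p[2], ta = tl, tb = tl,
               kind = "strategy_pair")
  if (!length(pairs)) return(NULL)
  out <- list()
  for (pr in pairs) {
    for (qn in names(quantities)) {
      va <- arm_values(metrics, pr$sa, pr$ta, quantities[[qn]])
      vb <- arm_values(metrics, pr$sb, pr$tb, quantities[[qn]])
      common <- intersect(va$subject_id, vb$subject_id)
      if (length(common) < 3L) next
      s <- paired_sample(common,
                         va[match(common, va$subject_id), 2],
                         vb[match(common, vb$subject_id), 2],
                         quantity = qn)
      row <- tryCatch(agreement_summary(s, cfg$agreement_scale),
                      error = function(e) NULL)
      if (is.null(row)) next
      out[[length(out) + 1L]] <- cbind(
        data.frame(kind = pr$kind, arm_a = pr$arm_a, arm_b = pr$arm_b,
                   stringsAsFactors = FALSE), row)
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

study_prognosis <- function(metrics, outcomes, cfg) {
  thr_labels <- vapply(cfg$thresholds, format, character(1))
  reports <- list()
  for (strat in cfg$strategies) {
    for (tl in thr_labels) {
      v <- arm_values(metrics, strat, tl, "tmtv_cm3")
      recs <- outcomes[match(v$subject_id, outcomes$subject_id), ]
      rep <- tryCatch(
        suppressWarnings(prognostic_analysis(recs, v$tmtv_cm3,
                                             cfg$horizon_months)),
        error = function(e) NULL)
      if (!is.null(rep)) reports[[paste(strat, tl, sep = "|")]] <- rep
    }
  }
  reports
}

write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash_line <- sprintf("# config_hash: %s", study$config_hash)
  write_commented_csv <- function(df, path) {
    con <- file(path, "w")
    writeLines(hash_line, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  write_commented_csv(study$metrics, file.path(out_dir, "metrics.csv"))
  if (!is.null(study$agreement))
    write_commented_csv(study$agreement, file.path(out_dir, "agreement.csv"))
  prog <- lapply(study$prognosis, function(p) list(
    auc = p$roc$auc, youden_cutoff = p$cutoff,
    youden_value = p$roc$youden_value,
    tie_break = p$roc$tie_break,
    n_high = p$n_high, n_low = p$n_low, n_roc = p$n_roc,
    log_rank_chi2 = p$log_rank$chi2, log_rank_p = p$log_rank$p,
    km_high = if (!is.null(p$km_high))
      list(time = p$km_high$time, surv = p$km_high$surv) else NULL,
    km_low = if (!is.null(p$km_low))
      list(time = p$km_low$time, surv = p$km_low$surv) else NULL))
  jsonlite::write_json(prog, file.path(out_dir, "prognosis.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cohort_seed <- study$cohort$seed
  manifest <- list(config_hash = study$config_hash,
                   seed = cohort_seed,
                   n_subjects = nrow(study$cohort$outcomes),
                   strategies = study$config$strategies,
                   thresholds = vapply(study$config$thresholds, format,
                                       character(1)),
                   peak_scope = study$config$peak_scope,
                   suvmax_scope = study$config$suvmax_scope,
                   agreement_scale = study$config$agreement_scale,
                   margin_mm = study$config$margin_mm,
                   package_version = as.character(utils::packageVersion("tmtvkit")),
                   failures = study$failures)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.tmtv_study <- function(x, ...) {
  cat(sprintf("TMTV comparison study: %d subjects, %d strategies x %d thresholds\n",
              length(unique(x$metrics$subject_id)),
              length(x$config$strategies), length(x$config$thresholds)))
  cat(sprintf("  metrics rows: %d; agreement rows: %s; failures: %d\n",
              nrow(x$metrics),
              if (is.null(x$agreement)) "none (needs >= 2 arms)"
              else nrow(x$agreement),
              length(x$failures)))
  agg <- stats::aggregate(tmtv_cm3 ~ strategy + threshold, data = x$metrics, mean)
  cat("  mean TMTV (cm^3) by arm:\n")
  print(agg, row.names = FALSE)
  invisible(x)
}

#' @export
summary.tmtv_study <- function(object, ...) {
  print(object)
  if (!is.null(object$agreement)) {
    cat("\nTMTV agreement (Pearson r, analysis scale):\n")
    print(object$agreement[object$agreement$quantity == "tmtv",
                           c("arm_a", "arm_b", "n", "bias", "r_log",
                             "p_two_tailed", "n_outliers")],
          row.names = FALSE)
  }
  for (nm in names(object$prognosis)) {
    cat("\n", nm, ": ", sep = "")
    p <- object$prognosis[[nm]]
    cat(sprintf("AUC %.3f, cutoff %.2f cm^3, log-rank p %.3g\n",
                p$roc$auc, p$cutoff, p$log_rank$p))
  }
  invisible(object)
}
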