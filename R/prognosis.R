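#' ROC curve with Youden-index optimal cutoff
#'
#' Candidate cutoffs are the midpoints between consecutive distinct sorted
#' scores, with -Inf/+Inf sentinels, listed in descending order; a subject is
#' called positive when its score is strictly greater than the cutoff
#' (consistent with the package-wide strict-> convention). AUC is the
#' trapezoid rule over the (1 - specificity, sensitivity) curve, which
#' equals the rank-sum (Mann-Whitney) statistic with ties counted 1/2. The
#' Youden cutoff maximises sensitivity + specificity - 1; exact ties are
#' broken toward the smallest cutoff (the more sensitive split).
#'
#' @param scores Numeric prognostic scores (e.g. TMTV in cm^3).
#' @param labels Logical (or 0/1) outcome labels; both classes must occur.
#' @return An object of class `roc_result` with fields `cutoffs` (descending),
#'   `sensitivity`, `specificity`, `auc`, `youden_cutoff`, `youden_value`,
#'   `n_pos`, `n_neg`.
#' @export
roc_with_youden <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels)) stop("scores/labels must not contain NA")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both outcome classes must be present (", n_pos, " positive, ",
         n_neg, " negative)")
  s <- sort(unique(scores))
  mids <- if (length(s) > 1L) (s[-1] + s[-length(s)]) / 2 else numeric(0)
  cutoffs <- sort(c(-Inf, mids, Inf), decreasing = TRUE)
  sens <- vapply(cutoffs, function(cc) mean(scores[labels] > cc), numeric(1))
  spec <- vapply(cutoffs, function(cc) mean(scores[!labels] <= cc), numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  j <- sens + spec - 1
  best <- max(j)
  youden_cutoff <- min(cutoffs[j >= best - 1e-12])
  structure(list(cutoffs = cutoffs, sensitivity = sens, specificity = spec,
                 auc = auc, youden_cutoff = youden_cutoff, youden_value = best,
                 n_pos = n_pos, n_neg = n_neg,
                 tie_break = "smallest cutoff"),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positive / %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  cat(sprintf("  Youden cutoff: score > %.4g (J = %.3f, ties -> %s)\n",
              x$youden_cutoff, x$youden_value, x$tie_break))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Outcome table constructor/validator
#'
#' @param subject_id Character ids.
#' @param time_months Positive follow-up times in months.
#' @param event Logical: progression or death observed.
#' @return A validated data.frame of class `outcome_table`.
#' @export
outcome_table <- function(subject_id, time_months, event) {
  time_months <- as.numeric(time_months)
  event <- as.logical(event)
  if (any(time_months <= 0)) stop("time_months must be positive")
  if (anyNA(time_months) || anyNA(event)) stop("outcomes must not contain NA")
  out <- data.frame(subject_id = as.character(subject_id),
                    time_months = time_months, event = event,
                    stringsAsFactors = FALSE)
  class(out) <- c("outcome_table", "data.frame")
  out
}

#' Split outcome records at a prognostic cutoff
#'
#' High group: score strictly greater than the cutoff (same convention as the
#' segmentation predicate); the partition is exhaustive and disjoint. An
#' empty side raises a warning, not an error — small cohorts with a high
#' cutoff legitimately produce very unbalanced splits.
#'
#' @param records Outcome data.frame (`subject_id`, `time_months`, `event`).
#' @param scores Numeric scores aligned to `records` rows.
#' @param cutoff The dichotomisation cutoff.
#' @return List with `high` and `low` data.frames.
#' @export
split_by_cutoff <- function(records, scores, cutoff) {
  if (nrow(records) != length(scores))
    stop("scores must align with records (", nrow(records), " rows vs ",
         length(scores), " scores)")
  hi <- scores > cutoff
  if (!any(hi)) warning("no subject above the cutoff; high group is empty")
  if (all(hi)) warning("no subject below the cutoff; low group is empty")
  list(high = records[hi, , drop = FALSE], low = records[!hi, , drop = FALSE])
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps `survival::survfit` for a single group. Subjects censored exactly at
#' an event time are counted at risk at that time (the standard convention).
#'
#' @param records Outcome data.frame (`time_months` > 0, `event` logical).
#' @return An object of class `km_curve`: `event_times` (increasing times at
#'   which events occurred), `survival` (non-increasing product-limit values
#'   at those times), `at_risk`, `n_events`, `n_censored`, plus the full step
#'   coordinates `time` / `surv` over all observed times and the underlying
#'   `survfit` fit.
#' @export
km_estimate <- function(records) {
  if (nrow(records) < 1L) stop("need at least one record")
  if (any(records$time_months <= 0)) stop("times must be positive")
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ 1,
    data = records)
  ev <- fit$n.event > 0
  structure(list(event_times = fit$time[ev],
                 survival = fit$surv[ev],
                 at_risk = fit$n.risk[ev],
                 n_events = as.integer(sum(fit$n.event)),
                 n_censored = as.integer(sum(fit$n.censor)),
                 time = fit$time, surv = fit$surv,
                 fit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d events, %d censored\n",
              x$n_events, x$n_censored))
  if (length(x$event_times)) {
    show <- utils::head(data.frame(time = x$event_times, at_risk = x$at_risk,
                                   survival = x$survival), 10)
    print(show, row.names = FALSE)
    if (length(x$event_times) > 10) cat("  ...\n")
  }
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  graphics::plot(x$fit, xlab = "Time (months)", ylab = "Survival", ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic (1 df chi-square) via `survival::survdiff`.
#' With no events in either group the test is undefined; a warning is issued
#' and chi2 = 0, p = 1 returned.
#'
#' @param groupA,groupB Outcome data.frames (`time_months`, `event`).
#' @return List with `chi2` and `p`.
#' @export
log_rank <- function(groupA, groupB) {
  if (nrow(groupA) < 1L || nrow(groupB) < 1L)
    stop("both groups must be nonempty")
  if (!any(groupA$event) && !any(groupB$event)) {
    warning("no events in either group; log-rank undefined, p = 1")
    return(list(chi2 = 0, p = 1))
  }
  df <- rbind(
    data.frame(time_months = groupA$time_months, event = groupA$event,
               group = "A"),
    data.frame(time_months = groupB$time_months, event = groupB$event,
               group = "B"))
  sd <- survival::survdiff(survival::Surv(time_months, event) ~ group, data = df)
  chi2 <- sd$chisq
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Prognostic analysis of one scored cohort
#'
#' The binary ROC label is "event observed during follow-up"; optionally,
#' subjects censored before `horizon_months` are excluded from the ROC (but
#' never from the survival curves), since their class is unknown. The cohort
#' is then split at the Youden cutoff and the two Kaplan-Meier curves are
#' compared by log-rank.
#'
#' @param records Outcome data.frame.
#' @param scores Prognostic scores aligned to records.
#' @param horizon_months Optional ROC horizon; default `NULL` (no exclusion,
#'   label = raw event flag).
#' @return List of class `prognosis_report`: `roc`, `cutoff`, `km_high`,
#'   `km_low`, `log_rank`, `n_high`, `n_low`, `n_roc`.
#' @export
prognostic_analysis <- function(records, scores, horizon_months = NULL) {
  stopifnot(nrow(records) == length(scores))
  keep <- rep(TRUE, nrow(records))
  if (!is.null(horizon_months))
    keep <- records$event | records$time_months >= horizon_months
  roc <- roc_with_youden(scores[keep], records$event[keep])
  grp <- split_by_cutoff(records, scores, roc$youden_cutoff)
  lr <- if (nrow(grp$high) >= 1L && nrow(grp$low) >= 1L)
    log_rank(grp$high, grp$low)
  else list(chi2 = NA_real_, p = NA_real_)
  structure(list(roc = roc, cutoff = roc$youden_cutoff,
                 km_high = if (nrow(grp$high)) km_estimate(grp$high) else NULL,
                 km_low = if (nrow(grp$low)) km_estimate(grp$low) else NULL,
                 log_rank = lr,
                 n_high = nrow(grp$high), n_low = nrow(grp$low),
                 n_roc = sum(keep)),
            class = "prognosis_report")
}

#' @export
print.prognosis_report <- function(x, ...) {
  print(x$roc)
  cat(sprintf("  split: %d high / %d low; log-rank chi2 = %.3f, p = %.4g\n",
              x$n_high, x$n_low, x$log_rank$chi2, x$log_rank$p))
  invisible(x)
}
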