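#' Paired sample of a PET quantity under two methods
#'
#' Holds one quantity (TMTV, TLG, SUVmean, SUVmax or SUVpeak) measured on the
#' same subjects by two methods — two software analogues, two thresholds, or
#' two contouring strategies — in matching order.
#'
#' @param labels Character subject ids.
#' @param a,b Numeric vectors, same length as `labels` (>= 3 pairs).
#' @param quantity Tag: one of `"tmtv"`, `"tlg"`, `"suv_mean"`, `"suv_max"`,
#'   `"suv_peak"` (free text allowed).
#' @return An object of class `paired_sample`.
#' @export
paired_sample <- function(labels, a, b, quantity = "tmtv") {
  a <- as.numeric(a); b <- as.numeric(b); labels <- as.character(labels)
  if (length(a) != length(b) || length(a) != length(labels))
    stop("labels, a and b must have equal length")
  if (length(a) < 3L) stop("need at least 3 pairs")
  if (anyNA(a) || anyNA(b)) stop("paired values must not contain NA")
  structure(list(labels = labels, a = a, b = b, quantity = quantity),
            class = "paired_sample")
}

#' @export
print.paired_sample <- function(x, ...) {
  cat(sprintf("Paired sample (%s): n = %d\n", x$quantity, length(x$a)))
  invisible(x)
}

#' Natural-log transform of a paired sample
#'
#' Applied elementwise to both arms; used because PET burden quantities are
#' typically right-skewed. The base (natural log) changes Bland-Altman bias
#' values but not t statistics, p values or Pearson correlations.
#'
#' @param s A [paired_sample] with all values > 0.
#' @return A log-transformed [paired_sample] (same quantity tag).
#' @export
log_transform <- function(s) {
  stopifnot(inherits(s, "paired_sample"))
  bad <- which(s$a <= 0 | s$b <= 0)
  if (length(bad))
    stop("nonpositive value(s) cannot be log-transformed for subject(s): ",
         paste(s$labels[bad], collapse = ", "))
  paired_sample(s$labels, log(s$a), log(s$b), s$quantity)
}

#' Paired two-tailed t test
#'
#' Student t on the pairwise differences `a - b`, sample SD (n-1
#' denominator), n-1 degrees of freedom, two-tailed p. Degenerate cases:
#' identical arms give t = 0, p = 1; zero-variance differences with nonzero
#' mean give p = 0 with a warning.
#'
#' @param s A [paired_sample].
#' @return List with `t_stat`, `p_two_tailed`, `df`, `mean_diff`.
#' @export
paired_t_test <- function(s) {
  stopifnot(inherits(s, "paired_sample"))
  d <- s$a - s$b
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t_stat = 0, p_two_tailed = 1, df = n - 1, mean_diff = 0))
    warning("differences have zero variance but nonzero mean; p reported as 0")
    return(list(t_stat = sign(mean(d)) * Inf, p_two_tailed = 0,
                df = n - 1, mean_diff = mean(d)))
  }
  tt <- stats::t.test(s$a, s$b, paired = TRUE)
  list(t_stat = unname(tt$statistic), p_two_tailed = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate))
}

#' Pearson correlation of a paired sample
#'
#' @param s A [paired_sample]; both arms must have nonzero variance.
#' @return The product-moment correlation in [-1, 1].
#' @export
pearson_r <- function(s) {
  stopifnot(inherits(s, "paired_sample"))
  if (stats::sd(s$a) == 0 || stats::sd(s$b) == 0)
    stop("Pearson correlation undefined: zero variance in one arm")
  stats::cor(s$a, s$b)
}

#' Bland-Altman agreement analysis
#'
#' Differences against means, with bias (mean difference), SD of the
#' differences, and normal-approximation limits of agreement at
#' bias +/- 1.96 SD. Pairs whose difference falls outside the limits are
#' flagged as outliers but never removed from the analysis. Computed on the
#' log scale by default (constant ratios then appear as constant
#' differences); `scale = "raw"` analyses the raw values.
#'
#' @param s A [paired_sample].
#' @param scale `"log"` (default) or `"raw"`.
#' @return An object of class `bland_altman` with fields `scale`, `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `outlier_flags`, and the plotted
#'   coordinates `means` / `diffs`.
#' @export
bland_altman <- function(s, scale = c("log", "raw")) {
  stopifnot(inherits(s, "paired_sample"))
  scale <- match.arg(scale)
  if (scale == "log") s <- log_transform(s)
  d <- s$a - s$b
  m <- (s$a + s$b) / 2
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  loa_low <- bias - 1.96 * sd_diff
  loa_high <- bias + 1.96 * sd_diff
  flags <- d < loa_low | d > loa_high
  structure(list(quantity = s$quantity, scale = scale, n = length(d),
                 bias = bias, sd_diff = sd_diff,
                 loa_low = loa_low, loa_high = loa_high,
                 outlier_flags = flags, labels = s$labels,
                 means = m, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (%s, %s scale): n = %d\n", x$quantity, x$scale, x$n))
  cat(sprintf("  bias %.4g, SD %.4g, limits of agreement [%.4g, %.4g]\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high))
  nf <- sum(x$outlier_flags)
  cat(sprintf("  %d pair(s) outside the agreement region (flagged, retained)\n", nf))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs,
                 xlab = sprintf("Mean (%s scale)", x$scale),
                 ylab = "Difference",
                 main = sprintf("Bland-Altman: %s", x$quantity), ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2, col = "grey40")
  if (any(x$outlier_flags))
    graphics::points(x$means[x$outlier_flags], x$diffs[x$outlier_flags],
                     pch = 4, cex = 1.4)
  invisible(x)
}

#' Full agreement summary for one paired sample
#'
#' Convenience wrapper producing one tidy row: n, Bland-Altman bias/SD/limits
#' and outlier count on the requested scale, Pearson r on both log and raw
#' values, and the paired t test on the analysis scale.
#'
#' @param s A [paired_sample].
#' @param scale Scale for Bland-Altman and the t test.
#' @return A one-row data.frame.
#' @export
agreement_summary <- function(s, scale = c("log", "raw")) {
  scale <- match.arg(scale)
  ba <- bland_altman(s, scale)
  s_t <- if (scale == "log") log_transform(s) else s
  tt <- paired_t_test(s_t)
  r_raw <- pearson_r(s)
  r_log <- if (all(s$a > 0 & s$b > 0)) pearson_r(log_transform(s)) else NA_real_
  data.frame(quantity = s$quantity, scale = scale, n = ba$n,
             bias = ba$bias, sd_diff = ba$sd_diff,
             loa_low = ba$loa_low, loa_high = ba$loa_high,
             n_outliers = sum(ba$outlier_flags),
             r_log = r_log, r_raw = r_raw,
             t_stat = tt$t_stat, p_two_tailed = tt$p_two_tailed,
             stringsAsFactors = FALSE)
}
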