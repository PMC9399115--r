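#' Test-retest and agreement statistics
#'
#' Connection-wise percentage change between acquisitions, Bland-Altman
#' limits of agreement, Lin's concordance correlation coefficient, Pearson
#' correlation with false-discovery-rate control, and bundle coverage
#' counting on a gray-white interface mask.
#'
#' @name metrics
NULL

#' Connection-wise percentage change
#'
#' Element-wise `(c2 - c1) / c1 * 100` over the connections valid in both
#' connectomes with non-zero baseline; everything else is flagged invalid
#' (never +/-Inf).
#'
#' @param c1,c2 two [scalar_connectome()] objects on the same scale,
#'   thresholds and region set (first and second acquisition).
#' @return an object of class `change_matrix` with fields `perCh` and
#'   `valid`.
#' @export
percent_change <- function(c1, c2) {
  stopifnot(inherits(c1, "scalar_connectome"),
            inherits(c2, "scalar_connectome"))
  if (!identical(c1$codes, c2$codes))
    stop("connectomes have different region sets")
  if (!identical(c1$scale, c2$scale))
    stop("connectomes have different scales")
  if (c1$p_thr != c2$p_thr || c1$c_thr != c2$c_thr)
    stop("connectomes were computed with different thresholds")
  valid <- c1$valid & c2$valid & !is.na(c1$mean) & c1$mean != 0
  perCh <- matrix(NA_real_, nrow(valid), ncol(valid))
  perCh[valid] <- (c2$mean[valid] - c1$mean[valid]) / c1$mean[valid] * 100
  structure(list(perCh = perCh, valid = valid, codes = c1$codes,
                 scale = c1$scale),
            class = "change_matrix")
}

#' Bland-Altman limits of agreement
#'
#' Bias is the mean paired difference `y - x`; the limits of agreement are
#' `bias +/- 1.96 * sd` with the sample (n-1) standard deviation.
#'
#' @param x,y paired numeric vectors of equal length (n >= 2), all finite.
#' @return an object of class `agreement` with `bias`, `loa_low`,
#'   `loa_high`, `sd`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 2L) stop("at least 2 pairs are required")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite")
  d <- y - x
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd = s, n = length(d)),
            class = "agreement")
}

#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' sample (n-1) moments, measuring agreement of paired measurements with
#' the identity line. The 95% confidence interval is obtained on the
#' Fisher z scale with Lin's asymptotic variance.
#'
#' @param x,y paired numeric vectors (n >= 3), both with non-zero
#'   variance.
#' @param conf confidence level (default 0.95).
#' @return an object of class `agreement` with `ccc`, `ci_low`,
#'   `ci_high`, `n`.
#' @export
lin_ccc <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("x and y must be paired")
  n <- length(x)
  if (n < 3L) stop("at least 3 pairs are required")
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 || vy == 0) stop("zero variance in x or y")
  sxy <- stats::cov(x, y)
  d <- mean(x) - mean(y)
  ccc <- 2 * sxy / (vx + vy + d^2)
  r <- sxy / sqrt(vx * vy)
  u <- d / sqrt(sqrt(vx * vy))
  z <- atanh(ccc)
  # Lin (1989) asymptotic variance of the z-transformed CCC
  sz2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
            2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
            ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  if (!is.finite(sz2) || sz2 < 0) {
    # degenerate perfect agreement: zero-width interval
    ci <- c(ccc, ccc)
  } else {
    ci <- tanh(z + c(-1, 1) * q * sqrt(sz2))
  }
  structure(list(ccc = ccc, ci_low = ci[1L], ci_high = ci[2L], n = n),
            class = "agreement")
}

#' @export
print.agreement <- function(x, ...) {
  if (!is.null(x$ccc)) {
    cat(sprintf("Lin's CCC = %.4f [%.4f, %.4f] (n = %d)\n",
                x$ccc, x$ci_low, x$ci_high, x$n))
  } else {
    cat(sprintf("Bland-Altman: bias = %.4g, LoA = [%.4g, %.4g] (n = %d)\n",
                x$bias, x$loa_low, x$loa_high, x$n))
  }
  invisible(x)
}

#' Pearson correlations with FDR control
#'
#' Computes the Pearson correlation and p-value for each paired set, then
#' flags significance after Benjamini-Hochberg correction across the sets
#' at level `q`. Sets with a constant vector are excluded from the
#' correction and flagged invalid.
#'
#' @param pair_sets list; each element a list or data frame with `x` and
#'   `y` components.
#' @param q FDR level in (0, 1); default 0.05.
#' @return data frame with `set`, `r`, `p`, `p_adj`, `fdr_significant`,
#'   `valid`.
#' @export
correlate_fdr <- function(pair_sets, q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  m <- length(pair_sets)
  r <- p <- rep(NA_real_, m)
  valid <- logical(m)
  for (k in seq_len(m)) {
    x <- pair_sets[[k]]$x
    y <- pair_sets[[k]]$y
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      message("set ", k, " has a constant vector or fewer than 3 pairs; ",
              "excluded from FDR correction")
      next
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    r[k] <- unname(ct$estimate)
    p[k] <- ct$p.value
    valid[k] <- TRUE
  }
  p_adj <- rep(NA_real_, m)
  p_adj[valid] <- stats::p.adjust(p[valid], method = "BH")
  data.frame(set = seq_len(m), r = r, p = p, p_adj = p_adj,
             fdr_significant = !is.na(p_adj) & p_adj <= q, valid = valid)
}

#' Bundle coverage of a gray-white interface
#'
#' For each non-zero voxel of the interface mask, counts the distinct
#' atlas bundles whose thresholded support contains it, and histograms
#' the counts overall and per voxel-class label (e.g. a gyral/sulcal
#' surrogate).
#'
#' @param a an `atlas_model`.
#' @param interface binary array on the atlas grid.
#' @param voxel_classes optional integer label array on the atlas grid
#'   (0 = unclassified).
#' @param p_thr probability threshold.
#' @return an object of class `coverage_result`: `counts` (array, zero
#'   outside the interface), `histogram` (named table) and
#'   `class_histograms` (list of tables by class label).
#' @export
coverage_map <- function(a, interface, voxel_classes = NULL, p_thr = 0.3) {
  stopifnot(inherits(a, "atlas_model"))
  interface <- as.array(interface) != 0
  .check_grid(a, interface)
  if (!is.null(voxel_classes)) {
    voxel_classes <- as.array(voxel_classes)
    .check_grid(a, voxel_classes)
  }
  counts <- export_bundle_count_volume(a, p_thr)
  counts[!interface] <- 0L
  vals <- counts[interface]
  histogram <- table(vals)
  class_histograms <- list()
  if (!is.null(voxel_classes)) {
    for (cl in setdiff(sort(unique(voxel_classes[interface])), 0L)) {
      sel <- interface & voxel_classes == cl
      class_histograms[[as.character(cl)]] <- table(counts[sel])
    }
  }
  structure(list(counts = counts, histogram = histogram,
                 class_histograms = class_histograms),
            class = "coverage_result")
}
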