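# Neurodegeneration cutpoints: the threshold is the crossing point of the
# estimated probability density functions of the cognitively-unimpaired
# and dementia groups -- the value at which the two class-conditional
# densities are equal, which minimizes classification error between the
# groups when they are equally weighted.

#' Derive a density-crossing cutpoint between two groups
#'
#' Gaussian kernel density estimates (Silverman's bandwidth per group) are
#' evaluated on a shared 2048-point grid spanning the pooled range plus 3
#' pooled SDs. The threshold is the crossing of the two densities between
#' the group medians, located by linear interpolation of the sign change.
#' If several crossings lie between the medians, the one with the smallest
#' balanced (equal-prior) misclassification rate is chosen, ties broken
#' toward the midpoint of the medians. When no crossing lies between the
#' medians (nested densities, or a crossing pushed past a sample median
#' by sampling noise), the default is an error suggesting the
#' empirical-error minimizer; `fallback = "empirical"` applies that
#' fallback -- an exhaustive threshold scan minimizing the balanced
#' misclassification rate -- instead.
#'
#' @param values_cu Biomarker values of the cognitively-unimpaired group.
#' @param values_ad Biomarker values of the dementia group.
#' @param polarity `"high_is_positive"` (diffusivity metrics) or
#'   `"low_is_positive"` (volume fractions, thickness).
#' @param biomarker Optional biomarker name stored with the result.
#' @param n_grid Density grid size.
#' @param fallback `"error"` (default) or `"empirical"`.
#' @return Object of class `cutpoint`: threshold, polarity, biomarker,
#'   n_cu, n_ad, bandwidths and the evaluation grid with both densities.
#' @export
density_crossing_cutpoint <- function(values_cu, values_ad,
                                      polarity = c("high_is_positive",
                                                   "low_is_positive"),
                                      biomarker = NA_character_,
                                      n_grid = 2048L,
                                      fallback = c("error", "empirical")) {
  polarity <- match.arg(polarity)
  fallback <- match.arg(fallback)
  values_cu <- values_cu[!is.na(values_cu)]
  values_ad <- values_ad[!is.na(values_ad)]
  if (length(values_cu) < 20L || length(values_ad) < 20L) {
    stop("need at least 20 values per group", call. = FALSE)
  }
  med_cu <- stats::median(values_cu)
  med_ad <- stats::median(values_ad)
  if (abs(med_cu - med_ad) < .Machine$double.eps) {
    stop("no crossing: the two groups have identical location; fall back to the empirical-error minimizer",
         call. = FALSE)
  }
  pooled <- c(values_cu, values_ad)
  pad <- 3 * stats::sd(pooled)
  lo <- min(pooled) - pad
  hi <- max(pooled) + pad
  bw_cu <- stats::bw.nrd0(values_cu)
  bw_ad <- stats::bw.nrd0(values_ad)
  grid <- seq(lo, hi, length.out = n_grid)
  f_cu <- stats::density(values_cu, bw = bw_cu, from = lo, to = hi,
                         n = n_grid)$y
  f_ad <- stats::density(values_ad, bw = bw_ad, from = lo, to = hi,
                         n = n_grid)$y
  dif <- f_cu - f_ad
  mlo <- min(med_cu, med_ad)
  mhi <- max(med_cu, med_ad)
  in_band <- which(grid[-n_grid] >= mlo & grid[-1] <= mhi)
  sgn <- sign(dif)
  cross_idx <- in_band[sgn[in_band] * sgn[in_band + 1L] < 0 |
                         sgn[in_band] == 0]
  method <- "density_crossing"
  if (length(cross_idx) == 0L) {
    if (fallback == "error") {
      stop("no crossing between the group medians (densities nested); fall back to the empirical-error minimizer",
           call. = FALSE)
    }
    threshold <- optimal_threshold_scan(values_cu, values_ad, polarity)$threshold
    method <- "empirical_minimizer"
  } else {
    roots <- vapply(cross_idx, function(i) {
      if (dif[i] == 0) return(grid[i])
      grid[i] + (grid[i + 1L] - grid[i]) * dif[i] / (dif[i] - dif[i + 1L])
    }, numeric(1))
    miscls <- vapply(roots, function(th) {
      misclassification_rate(values_cu, values_ad, th, polarity)
    }, numeric(1))
    best <- which(miscls == min(miscls))
    if (length(best) > 1L) {
      midpoint <- (med_cu + med_ad) / 2
      best <- best[which.min(abs(roots[best] - midpoint))]
    }
    threshold <- roots[best]
  }
  structure(list(biomarker = biomarker,
                 threshold = threshold,
                 method = method,
                 polarity = polarity,
                 n_cu = length(values_cu),
                 n_ad = length(values_ad),
                 bw_cu = bw_cu, bw_ad = bw_ad,
                 grid = grid, density_cu = f_cu, density_ad = f_ad),
            class = "cutpoint")
}

# Balanced (equal-prior) misclassification rate of a threshold: the mean
# of the two within-group error fractions. The crossing of the two
# class-conditional densities minimizes exactly this quantity, so it is
# the natural empirical counterpart regardless of the CU/AD size ratio.
misclassification_rate <- function(values_cu, values_ad, threshold, polarity) {
  if (polarity == "high_is_positive") {
    (mean(values_cu >= threshold) + mean(values_ad < threshold)) / 2
  } else {
    (mean(values_cu < threshold) + mean(values_ad >= threshold)) / 2
  }
}

# Exhaustive threshold scan minimizing the balanced misclassification
# rate; used as an independent check on (and fallback for) the KDE
# crossing.
optimal_threshold_scan <- function(values_cu, values_ad, polarity) {
  cand <- sort(unique(c(values_cu, values_ad)))
  cand <- c(cand, max(cand) + 1)
  err <- vapply(cand, function(th) {
    misclassification_rate(values_cu, values_ad, th, polarity)
  }, numeric(1))
  list(threshold = cand[which.min(err)], error_rate = min(err))
}

#' Classify values as neurodegeneration positive or negative
#'
#' Boundary semantics follow the dichotomization convention: under
#' `high_is_positive` a value equal to or greater than the threshold is
#' positive; under `low_is_positive` only values strictly below the
#' threshold are positive (a boundary value is negative).
#'
#' @param values Numeric biomarker values (NA propagates to NA).
#' @param cutpoint A `cutpoint` object.
#' @return Logical vector: TRUE = neurodegeneration positive.
#' @export
classify_n_status <- function(values, cutpoint) {
  stopifnot(inherits(cutpoint, "cutpoint"))
  if (cutpoint$polarity == "high_is_positive") {
    values >= cutpoint$threshold
  } else {
    values < cutpoint$threshold
  }
}

#' @export
print.cutpoint <- function(x, ...) {
  cat(sprintf("Cutpoint for %s: threshold = %.6g (%s), n_CU = %d, n_AD = %d\n",
              x$biomarker, x$threshold, x$polarity, x$n_cu, x$n_ad))
  invisible(x)
}
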