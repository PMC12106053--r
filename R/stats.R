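# Cohort statistics: diagnostic-group assignment from longitudinal
# follow-up, linear confound adjustment, pairwise group contrasts with
# Bonferroni correction, regional analyses under Benjamini-Hochberg FDR,
# and partial Pearson correlations for the CSF sub-study.

#' Assign diagnostic groups from longitudinal follow-up
#'
#' Applies the cohort rules: baseline dementia is AD; cognitively
#' unimpaired subjects must remain CU with at least `min_followup_years` of
#' follow-up; MCI subjects who progressed after the scan are converters
#' (event = 1, time = conversion interval); MCI subjects without conversion
#' need at least `min_followup_years` of follow-up to count as
#' non-converters (censored). Subjects failing all rules are excluded with
#' a reason code rather than dropped silently.
#'
#' @param records Data frame with `baseline_dx` (CU/MCI/dementia),
#'   `follow_up_years`, `conversion_interval_years` (NA if no conversion)
#'   and optionally `remained_cu` (default TRUE).
#' @param min_followup_years Minimum follow-up for CU and MCI
#'   non-converters (years).
#' @return The records with `group`, `included`, `exclusion_reason`,
#'   `time_days` and `event` columns.
#' @export
assign_groups <- function(records, min_followup_years = 2) {
  need <- c("baseline_dx", "follow_up_years", "conversion_interval_years")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop(sprintf("records are missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  conv <- records$conversion_interval_years
  if (any(!is.na(conv) & conv <= 0)) {
    stop("data inconsistency: conversion date on or before the MRI scan",
         call. = FALSE)
  }
  n <- nrow(records)
  remained <- if ("remained_cu" %in% names(records)) {
    records$remained_cu
  } else rep(TRUE, n)
  group <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  time_days <- rep(NA_real_, n)
  event <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    dx <- records$baseline_dx[i]
    fu <- records$follow_up_years[i]
    cv <- conv[i]
    if (dx == "dementia") {
      group[i] <- "AD"
    } else if (dx == "CU") {
      if (!isTRUE(remained[i])) {
        reason[i] <- "progressed from CU"
      } else if (is.na(fu) || fu < min_followup_years) {
        reason[i] <- "insufficient follow-up"
      } else {
        group[i] <- "CU"
        time_days[i] <- fu * 365.25
        event[i] <- 0L
      }
    } else if (dx == "MCI") {
      if (!is.na(cv)) {
        group[i] <- "MCI_C"
        time_days[i] <- cv * 365.25
        event[i] <- 1L
      } else if (is.na(fu) || fu < min_followup_years) {
        reason[i] <- "insufficient follow-up"
      } else {
        group[i] <- "MCI_NC"
        time_days[i] <- fu * 365.25
        event[i] <- 0L
      }
    } else {
      reason[i] <- sprintf("unknown baseline diagnosis '%s'", dx)
    }
  }
  records$group <- group
  records$included <- !is.na(group)
  records$exclusion_reason <- reason
  records$time_days <- time_days
  records$event <- event
  records
}

# Build a confound design matrix: continuous covariates mean-centred on the
# fitting subset, categorical covariates dummy-coded against the most
# frequent level in the fitting subset. Constant columns are dropped with a
# warning. Returns list(X, dropped).
confound_design <- function(data, covariates, fit_idx) {
  cols <- list("(Intercept)" = rep(1, nrow(data)))
  for (cv in covariates) {
    x <- data[[cv]]
    if (is.null(x)) {
      stop(sprintf("missing covariate column '%s'", cv), call. = FALSE)
    }
    if (is.numeric(x)) {
      if (length(unique(x[fit_idx])) < 2L) {
        warning(sprintf("covariate '%s' is constant in the fitting subset; dropped", cv))
        next
      }
      cols[[cv]] <- x - mean(x[fit_idx])
    } else {
      tab <- sort(table(x[fit_idx]), decreasing = TRUE)
      if (length(tab) < 2L) {
        warning(sprintf("covariate '%s' is constant in the fitting subset; dropped", cv))
        next
      }
      ref <- names(tab)[1]
      for (lv in setdiff(names(tab), ref)) {
        cols[[paste0(cv, lv)]] <- as.numeric(x == lv)
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

check_full_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design: collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  qrX
}

#' Adjust a biomarker for confounds by linear regression
#'
#' Fits a linear model of the biomarker on age, sex, scanner model and
#' b-value (configurable) on the fitting subset -- by default the CU and AD
#' subjects, i.e. the sample on which cutpoints are derived -- and returns,
#' for every subject, the residual plus the fitted value at reference
#' covariates (fitting-subset mean age/b-value, majority sex and scanner).
#' Applying the function to already-adjusted values is a no-op up to
#' numerical tolerance.
#'
#' @param data Cohort data frame.
#' @param value_col Name of the biomarker column.
#' @param covariates Covariate column names.
#' @param fit_subset Logical vector selecting the fitting rows; defaults to
#'   `group %in% c("CU", "AD")` when a `group` column exists, else all rows.
#' @return Numeric vector of adjusted values for all subjects.
#' @export
adjust_confounds <- function(data, value_col,
                             covariates = c("age", "sex", "scanner_model", "bvalue"),
                             fit_subset = NULL) {
  y <- data[[value_col]]
  if (is.null(y)) {
    stop(sprintf("missing biomarker column '%s'", value_col), call. = FALSE)
  }
  if (is.null(fit_subset)) {
    fit_subset <- if ("group" %in% names(data)) {
      data$group %in% c("CU", "AD")
    } else rep(TRUE, nrow(data))
  }
  fit_idx <- which(fit_subset & !is.na(y))
  X <- confound_design(data, covariates, fit_idx)
  check_full_rank(X[fit_idx, , drop = FALSE])
  beta <- qr.coef(qr(X[fit_idx, , drop = FALSE]), y[fit_idx])
  # reference covariates: centred continuous terms and dummy levels are all
  # zero at the reference point, so the reference prediction is the intercept
  fitted_all <- as.numeric(X %*% beta)
  y - fitted_all + beta[["(Intercept)"]]
}

#' Pairwise group comparisons from a covariate-adjusted linear model
#'
#' Fits value ~ group + covariates with the diagnostic group as a fixed
#' factor, then tests all pairwise differences of adjusted group means with
#' Bonferroni correction over the contrast family (6 contrasts for 4
#' groups).
#'
#' @param data Cohort data frame with a `group` column.
#' @param value_col Biomarker column name.
#' @param covariates Covariate column names (use
#'   `c("age","sex","scanner_model")` for macrostructural markers, which
#'   omit the b-value adjustment).
#' @param alpha Significance level for the `significant` flag.
#' @return Data frame: contrast, estimate (adjusted mean difference,
#'   second minus first), se, p_raw, p_adjusted, significant.
#' @export
group_glm <- function(data, value_col,
                      covariates = c("age", "sex", "scanner_model", "bvalue"),
                      alpha = 0.05) {
  y <- data[[value_col]]
  groups <- intersect(c("CU", "MCI_NC", "MCI_C", "AD"), unique(data$group))
  if (length(groups) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (any(table(data$group) < 3L)) {
    stop("need at least 3 subjects per group", call. = FALSE)
  }
  keep <- which(!is.na(y) & data$group %in% groups)
  dat <- data[keep, , drop = FALSE]
  y <- y[keep]
  Xc <- confound_design(dat, covariates, seq_len(nrow(dat)))
  G <- sapply(groups[-1], function(g) as.numeric(dat$group == g))
  colnames(G) <- paste0("group", groups[-1])
  X <- cbind(Xc[, 1, drop = FALSE], G, Xc[, -1, drop = FALSE])
  check_full_rank(X)
  fit <- stats::lm.fit(X, y)
  df_res <- nrow(X) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df_res
  XtXinv <- chol2inv(chol(crossprod(X)))
  pairs <- utils::combn(groups, 2)
  k <- ncol(pairs)
  res <- lapply(seq_len(k), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    L <- rep(0, ncol(X))
    names(L) <- colnames(X)
    if (a != groups[1]) L[paste0("group", a)] <- -1
    if (b != groups[1]) L[paste0("group", b)] <- 1
    est <- sum(L * fit$coefficients)
    se <- sqrt(sigma2 * as.numeric(t(L) %*% XtXinv %*% L))
    tval <- est / se
    p <- 2 * stats::pt(-abs(tval), df_res)
    data.frame(contrast = paste(b, "vs", a), estimate = est, se = se,
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- pmin(1, out$p_raw * k)
  out$significant <- out$p_adjusted < alpha
  out
}

#' Region-wise group comparisons with FDR control
#'
#' Runs [group_glm()] independently for every region and applies
#' Benjamini-Hochberg FDR within each contrast family across regions (the
#' family is the set of regions, per metric and contrast; metrics are
#' analysed in separate calls).
#'
#' @param regional Data frame with `subject_id`, `region` and `value`
#'   columns (one row per subject x region; use region names that encode
#'   hemisphere if per-hemisphere analysis is wanted).
#' @param cohort Cohort data frame with `subject_id`, `group` and covariates.
#' @param covariates Covariate column names.
#' @param q FDR level.
#' @return Data frame: region, contrast, estimate, p_raw, q_value,
#'   significant.
#' @export
regional_glm <- function(regional, cohort,
                         covariates = c("age", "sex", "scanner_model", "bvalue"),
                         q = 0.05) {
  regs <- unique(regional$region)
  res <- lapply(regs, function(rg) {
    sub <- regional[regional$region == rg, c("subject_id", "value")]
    dat <- merge(cohort, sub, by = "subject_id")
    out <- group_glm(dat, "value", covariates)
    out$region <- rg
    out
  })
  out <- do.call(rbind, res)
  out$q_value <- NA_real_
  out$significant <- NA
  for (ct in unique(out$contrast)) {
    sel <- out$contrast == ct
    fdr <- bh_fdr(out$p_raw[sel], q = q)
    out$q_value[sel] <- fdr$q_values
    out$significant[sel] <- fdr$reject
  }
  out[, c("region", "contrast", "estimate", "se", "p_raw", "q_value",
          "significant")]
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR procedure: q-values via [stats::p.adjust()] and the
#' rejection set of the largest k with p_(k) <= k q / m.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @param q FDR level.
#' @return List with `q_values` and logical `reject`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("invalid input: p-values must lie in [0, 1]", call. = FALSE)
  }
  qv <- stats::p.adjust(p_values, method = "BH")
  list(q_values = qv, reject = qv <= q)
}

#' Partial Pearson correlation
#'
#' Pearson correlation of two variables after residualizing both on the
#' covariates (e.g. age, sex and assay methodology for the CSF analyses),
#' with the two-sided p-value from the t transform on n - 2 - k degrees of
#' freedom (k = number of covariate design columns).
#'
#' @param x,y Numeric vectors.
#' @param covariates Data frame of covariates, or NULL for the plain
#'   Pearson correlation.
#' @return List with `r`, `p`, `df` and `n`.
#' @export
partial_pearson <- function(x, y, covariates = NULL) {
  ok <- !is.na(x) & !is.na(y)
  if (!is.null(covariates)) {
    ok <- ok & stats::complete.cases(covariates)
  }
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  k <- 0L
  sd_x0 <- stats::sd(x)
  sd_y0 <- stats::sd(y)
  if (!is.null(covariates)) {
    cv <- covariates[ok, , drop = FALSE]
    X <- confound_design(cv, names(cv), seq_len(n))
    k <- ncol(X) - 1L
    if (n <= k + 2L) {
      stop("too few observations for the requested covariates", call. = FALSE)
    }
    x <- stats::residuals(stats::lm.fit(X, x))
    y <- stats::residuals(stats::lm.fit(X, y))
  }
  if (stats::sd(x) <= 1e-10 * max(sd_x0, 1e-300) ||
      stats::sd(y) <= 1e-10 * max(sd_y0, 1e-300)) {
    stop("undefined correlation: zero variance after residualization",
         call. = FALSE)
  }
  r <- stats::cor(x, y)
  df <- n - 2L - k
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df, n = n)
}
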