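# Product-limit survival estimation and log-rank testing, implemented from
# first principles: Kaplan-Meier curves with Greenwood variance, median
# survival with confidence intervals by inversion of the pointwise
# survival CI, restricted mean survival limited to the largest observed
# time, the k-group Mantel-Cox log-rank test, pairwise log-rank
# comparisons across (possibly overlapping) biomarker classifications,
# and yearly cumulative-proportion tables.

#' Kaplan-Meier product-limit fit
#'
#' Events are processed before censorings at tied times: the at-risk count
#' at time t includes every subject with observed time >= t.
#'
#' @param time_days Positive observation times.
#' @param event Event indicator (1 = progression, 0 = censored).
#' @param label Optional group label stored with the curve.
#' @return Object of class `km_curve` with per-unique-time counts
#'   (`at_risk`, `events`, `censored`), the survival steps `surv`,
#'   Greenwood variance `greenwood_var`, and the raw data.
#' @export
km_fit <- function(time_days, event, label = NA_character_) {
  if (length(time_days) == 0L) {
    stop("empty curve: no observations", call. = FALSE)
  }
  if (any(is.na(time_days)) || any(time_days <= 0)) {
    stop("times must be positive and non-missing", call. = FALSE)
  }
  event <- as.integer(event)
  if (any(!event %in% c(0L, 1L))) {
    stop("event must be 0/1", call. = FALSE)
  }
  ut <- sort(unique(time_days))
  tf <- factor(time_days, levels = ut)
  counts <- as.numeric(table(tf))
  events <- as.numeric(rowsum(as.numeric(event), tf))
  censored <- counts - events
  n_total <- length(time_days)
  at_risk <- n_total - c(0, cumsum(counts))[seq_along(ut)]
  frac <- ifelse(at_risk > 0, 1 - events / at_risk, 1)
  surv <- cumprod(frac)
  gw_term <- ifelse(at_risk > events, events / (at_risk * (at_risk - events)), 0)
  greenwood_var <- surv^2 * cumsum(gw_term)
  structure(list(time = ut, at_risk = at_risk, events = events,
                 censored = censored, surv = surv,
                 greenwood_var = greenwood_var,
                 n = length(time_days), n_events = sum(event),
                 label = label,
                 data = data.frame(time_days = time_days, event = event)),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Right-continuous step convention: S(t) is the survival just after t,
#' with S(t) = 1 before the first observed time.
#'
#' @param curve A `km_curve`.
#' @param times Evaluation times (>= 0).
#' @return Numeric vector of survival probabilities.
#' @export
km_surv <- function(curve, times) {
  idx <- findInterval(times, curve$time)
  ifelse(idx == 0L, 1, curve$surv[pmax(idx, 1L)])
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve%s: n = %d, events = %d\n",
              if (is.na(x$label)) "" else paste0(" [", x$label, "]"),
              x$n, x$n_events))
  invisible(x)
}

# Pointwise CI of S(t) on the log(-log) or plain scale.
km_pointwise_ci <- function(curve, conf_level = 0.95,
                            conf_type = c("loglog", "plain")) {
  conf_type <- match.arg(conf_type)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  s <- curve$surv
  se <- sqrt(curve$greenwood_var)
  if (conf_type == "plain") {
    lower <- pmax(0, s - z * se)
    upper <- pmin(1, s + z * se)
  } else {
    lower <- upper <- rep(NA_real_, length(s))
    ok <- s > 0 & s < 1
    se_g <- se[ok] / (s[ok] * abs(log(s[ok])))
    lower[ok] <- s[ok]^exp(z * se_g)
    upper[ok] <- s[ok]^exp(-z * se_g)
    lower[s == 0] <- 0
    upper[s == 0] <- 0
    lower[s == 1] <- 1
    upper[s == 1] <- 1
  }
  list(lower = lower, upper = upper)
}

#' Median and restricted-mean summaries of a Kaplan-Meier curve
#'
#' The median is the smallest observed time at which S(t) <= 0.5 (missing
#' if the curve never reaches 0.5). Its confidence interval inverts the
#' pointwise CI of S (log(-log) transform by default): the lower bound is
#' the first time the lower CI of S drops to 0.5 or below, the upper
#' bound the first time the upper CI does. The restricted mean is the area under
#' the curve limited to the largest observed time (even if censored), with
#' its standard error.
#'
#' @param curve A `km_curve`.
#' @param conf_level Confidence level.
#' @param conf_type `"loglog"` (default) or `"plain"` CI transform.
#' @return List of class `km_summary`: median_days, median_ci,
#'   restricted_mean_days, restricted_mean_se, n, n_events.
#' @export
km_summary <- function(curve, conf_level = 0.95,
                       conf_type = c("loglog", "plain")) {
  conf_type <- match.arg(conf_type)
  median_days <- if (any(curve$surv <= 0.5)) {
    curve$time[which(curve$surv <= 0.5)[1]]
  } else NA_real_
  ci <- km_pointwise_ci(curve, conf_level, conf_type)
  first_leq <- function(v) {
    hit <- which(!is.na(v) & v <= 0.5)
    if (length(hit) == 0L) NA_real_ else curve$time[hit[1]]
  }
  median_ci <- c(lower = first_leq(ci$lower), upper = first_leq(ci$upper))
  # restricted mean: integrate the step function up to the largest time
  tmax <- max(curve$time)
  steps <- c(0, curve$time)
  sv <- c(1, curve$surv)
  rmean <- sum(sv[-length(sv)] * diff(steps))
  # Greenwood-type variance: sum over event times of A_i^2 d_i / (n_i (n_i - d_i))
  ev <- which(curve$events > 0)
  var_rm <- 0
  if (length(ev) > 0L) {
    m <- length(curve$time)
    seg <- curve$surv[-m] * diff(curve$time)      # area of each step
    # area from each time point to tmax, by reverse accumulation
    area_after <- c(rev(cumsum(rev(seg))), 0)
    area_from <- area_after[ev]
    d <- curve$events[ev]
    n <- curve$at_risk[ev]
    term <- ifelse(n > d, d / (n * (n - d)), 0)
    var_rm <- sum(area_from^2 * term)
  }
  structure(list(median_days = median_days, median_ci = median_ci,
                 restricted_mean_days = rmean,
                 restricted_mean_se = sqrt(var_rm),
                 tmax_days = tmax,
                 n = curve$n, n_events = curve$n_events,
                 conf_level = conf_level, conf_type = conf_type),
            class = "km_summary")
}

#' @export
print.km_summary <- function(x, ...) {
  cat(sprintf("median %.1f days (%.0f%% CI %.1f-%.1f); restricted mean %.1f (SE %.1f) to %.0f days; n = %d, events = %d\n",
              x$median_days, 100 * x$conf_level, x$median_ci[1],
              x$median_ci[2], x$restricted_mean_days,
              x$restricted_mean_se, x$tmax_days, x$n, x$n_events))
  invisible(x)
}

#' Mantel-Cox log-rank test
#'
#' At each event time the observed events per group are compared with
#' their expectation under the hypergeometric null given the at-risk
#' counts; the quadratic form of (O - E) against the accumulated
#' covariance gives a chi-square statistic with (k - 1) degrees of
#' freedom.
#'
#' @param time_days Observation times.
#' @param event Event indicator (1 = event).
#' @param group Group labels (>= 2 distinct).
#' @return Object of class `logrank_result`: chi_square, df, p_value and a
#'   per-group table of n, observed and expected events.
#' @export
logrank <- function(time_days, event, group) {
  group <- as.character(group)
  glev <- unique(group)
  k <- length(glev)
  if (k < 2L) {
    stop("invalid input: log-rank needs at least 2 groups", call. = FALSE)
  }
  event <- as.integer(event)
  if (sum(event) < 1L) {
    stop("invalid input: no events observed", call. = FALSE)
  }
  et <- sort(unique(time_days[event == 1L]))
  O <- E <- stats::setNames(rep(0, k), glev)
  V <- matrix(0, k, k, dimnames = list(glev, glev))
  for (t in et) {
    atrisk <- time_days >= t
    N <- sum(atrisk)
    d <- sum(event == 1L & time_days == t)
    if (N <= 0 || d == 0) next
    ng <- vapply(glev, function(g) sum(atrisk & group == g), numeric(1))
    dg <- vapply(glev, function(g) {
      sum(event == 1L & time_days == t & group == g)
    }, numeric(1))
    O <- O + dg
    E <- E + d * ng / N
    if (N > 1) {
      c1 <- d * (N - d) / (N^2 * (N - 1))
      V <- V + c1 * (diag(ng * N, k) - outer(ng, ng)) / 1
    }
  }
  diff_ <- (O - E)[-k]
  Vsub <- V[-k, -k, drop = FALSE]
  chi <- tryCatch(
    as.numeric(t(diff_) %*% solve(Vsub, diff_)),
    error = function(e) {
      as.numeric(t(diff_) %*% MASS::ginv(Vsub) %*% diff_)
    })
  df <- k - 1L
  structure(list(chi_square = chi, df = df,
                 p_value = stats::pchisq(chi, df, lower.tail = FALSE),
                 table = data.frame(group = glev,
                                    n = as.numeric(table(factor(group, glev))),
                                    observed = as.numeric(O),
                                    expected = as.numeric(E)),
                 variance = V),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank (Mantel-Cox): chi-square = %.3f, df = %d, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Pairwise log-rank tests across biomarker classifications
#'
#' For each pair of measures, compares the survival of the selected arm
#' (positive or negative) as classified by one measure against the same
#' arm as classified by the other. Subjects classified into the arm by
#' both measures appear in both groups; the test is applied to the stacked
#' data, replicating the between-measure comparison procedure (the
#' independence assumption of the log-rank test is knowingly stretched;
#' see the package vignette).
#'
#' @param nstatus Data frame of logical columns (TRUE = positive), one per
#'   measure, one row per subject.
#' @param time_days,event Survival data aligned with `nstatus` rows.
#' @param arm `"positive"` or `"negative"`: which curves to compare.
#' @return Data frame: measure_a, measure_b, chi_square, df, p_value
#'   (NA row when a measure's arm is empty).
#' @export
pairwise_logrank <- function(nstatus, time_days, event,
                             arm = c("positive", "negative")) {
  arm <- match.arg(arm)
  measures <- names(nstatus)
  if (length(measures) < 2L) {
    stop("need at least 2 measures", call. = FALSE)
  }
  want <- arm == "positive"
  pairs <- utils::combn(measures, 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ia <- which(nstatus[[a]] == want)
    ib <- which(nstatus[[b]] == want)
    if (length(ia) == 0L || length(ib) == 0L) {
      return(data.frame(measure_a = a, measure_b = b, chi_square = NA_real_,
                        df = NA_integer_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    tt <- c(time_days[ia], time_days[ib])
    ee <- c(event[ia], event[ib])
    gg <- rep(c(a, b), c(length(ia), length(ib)))
    if (identical(sort(ia), sort(ib))) {
      # identical membership: the curves coincide exactly
      return(data.frame(measure_a = a, measure_b = b, chi_square = 0,
                        df = 1L, p_value = 1, stringsAsFactors = FALSE))
    }
    lr <- logrank(tt, ee, gg)
    data.frame(measure_a = a, measure_b = b, chi_square = lr$chi_square,
               df = lr$df, p_value = lr$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Cumulative proportion surviving at fixed times
#'
#' Evaluates the curve on a (typically yearly) time grid with the
#' right-continuous step convention, alongside the number of participants
#' still at risk at each time.
#'
#' @param curve A `km_curve`.
#' @param times Non-negative, increasing evaluation times (days).
#' @return Data frame: time_days, proportion_surviving, n_at_risk.
#' @export
cps_table <- function(curve, times) {
  if (any(times < 0) || is.unsorted(times)) {
    stop("times must be non-negative and increasing", call. = FALSE)
  }
  data.frame(time_days = times,
             proportion_surviving = km_surv(curve, times),
             n_at_risk = vapply(times, function(t) {
               sum(curve$data$time_days >= t)
             }, numeric(1)))
}

#' Convert days to years
#'
#' Days divided by 365.25, rounded to one decimal -- the convention used
#' when reporting median conversion times in years.
#'
#' @param days Numeric days.
#' @param digits Decimal places (default 1).
#' @return Numeric years.
#' @export
days_to_years <- function(days, digits = 1) {
  round(days / 365.25, digits)
}
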