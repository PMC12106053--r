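# Synthetic cohort generation: group-calibrated biomarkers, demographic
# covariates, CSF values with requested correlations to the imaging
# metrics, and progression-to-dementia survival outcomes for the MCI
# participants.

COHORT_GROUPS <- c("CU", "MCI_NC", "MCI_C", "AD")
COHORT_BIOMARKERS <- c("perppd_sig", "angler_sig", "parlpd_sig",
                       "hvf", "ct_sig", "cvf")

#' Default cohort calibration: biomarker moments and covariate model
#'
#' `default_biomarker_means()` / `default_biomarker_sds()` give the
#' per-group Gaussian moments the simulator is calibrated to (signature
#' diffusivity metrics at their published group values; placeholder,
#' user-configurable moments for the macrostructural markers, for which
#' no per-group SDs are published). `default_covariate_model()` gives the
#' demographic distributions and `zero_covariate_effects()` a template of
#' all-zero covariate coefficients.
#'
#' @return Matrices (biomarker x group), a list of distributions, or a
#'   named list of coefficient vectors respectively.
#' @name cohort_defaults
NULL

#' @rdname cohort_defaults
#' @export
default_biomarker_means <- function() {
  m <- rbind(
    perppd_sig = c(1.986, 2.044, 2.172, 2.179),
    angler_sig = c(0.935, 0.949, 1.001, 1.014),
    parlpd_sig = c(0.619, 0.639, 0.649, 0.648),
    hvf        = c(0.0027, 0.0024, 0.0023, 0.0021),
    ct_sig     = c(2.70, 2.60, 2.50, 2.40),
    cvf        = c(0.320, 0.310, 0.305, 0.295))
  colnames(m) <- COHORT_GROUPS
  m
}

#' @rdname cohort_defaults
#' @export
default_biomarker_sds <- function() {
  m <- rbind(
    perppd_sig = c(0.17, 0.27, 0.22, 0.30),
    angler_sig = c(0.04, 0.04, 0.05, 0.06),
    parlpd_sig = c(0.05, 0.08, 0.06, 0.08),
    hvf        = c(3e-4, 3e-4, 3e-4, 3e-4),
    ct_sig     = c(0.15, 0.15, 0.15, 0.15),
    cvf        = c(0.02, 0.02, 0.02, 0.02))
  colnames(m) <- COHORT_GROUPS
  m
}

#' @rdname cohort_defaults
#' @export
default_covariate_model <- function() {
  list(age_mean = c(CU = 65.4, MCI_NC = 73.1, MCI_C = 75.6, AD = 73.3),
       age_sd = c(CU = 9.7, MCI_NC = 8.1, MCI_C = 7.6, AD = 8.9),
       female_prob = c(CU = 0.65, MCI_NC = 0.464, MCI_C = 0.395, AD = 0.461),
       scanner_levels = c("siemens_3t", "ge_3t"),
       scanner_prob = c(0.6, 0.4),
       bvalue_levels = c(1000, 2000, 3000),
       bvalue_prob = c(0.7, 0.2, 0.1),
       followup_mean = c(CU = 7.1, MCI_NC = 4.7, MCI_C = 5.7, AD = NA),
       followup_sd = c(CU = 2.7, MCI_NC = 2.2, MCI_C = 2.8, AD = NA))
}

#' @rdname cohort_defaults
#' @export
zero_covariate_effects <- function() {
  eff <- lapply(COHORT_BIOMARKERS, function(b) {
    c(age = 0, sex_female = 0, scanner = 0, bvalue = 0)
  })
  names(eff) <- COHORT_BIOMARKERS
  eff
}

#' Specification of a synthetic cohort
#'
#' Biomarkers are Gaussian per diagnostic group with the given moments
#' (defaults calibrated to the study conditions the package emulates:
#' signature metrics with their published group means/SDs, and
#' user-configurable placeholder moments for the macrostructural markers).
#' Covariate effects are linear coefficients injected into each biomarker
#' (zero by default, so group moments are exactly the configured ones).
#' MCI survival uses exponential event times with distinct medians for the
#' latent neurodegeneration-positive/negative subgroups and independent
#' uniform administrative censoring.
#'
#' @param n_per_group Named counts for CU, MCI_NC, MCI_C, AD.
#' @param biomarker_means,biomarker_sds biomarker x group matrices.
#' @param covariate_model List of covariate distributions (see
#'   `default_covariate_model`).
#' @param covariate_effects Named list (per biomarker) of linear
#'   coefficients for age (per year from 70), sex (female), scanner
#'   (non-reference) and b-value (per 1000 s/mm^2 from 1000).
#' @param survival_medians_days Named medians (days) for the latent N+ and
#'   N- MCI subgroups.
#' @param censor_horizon_days Upper bound of the uniform censoring time.
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(CU = 474, MCI_NC = 110,
                                        MCI_C = 86, AD = 156),
                        biomarker_means = default_biomarker_means(),
                        biomarker_sds = default_biomarker_sds(),
                        covariate_model = default_covariate_model(),
                        covariate_effects = zero_covariate_effects(),
                        survival_medians_days = c(n_pos = 777, n_neg = 2447),
                        censor_horizon_days = 9 * 365.25,
                        seed = 1L) {
  if (!all(COHORT_GROUPS %in% names(n_per_group)) || any(n_per_group < 0)) {
    stop("invalid cohort spec: n_per_group needs non-negative CU, MCI_NC, MCI_C, AD",
         call. = FALSE)
  }
  bad <- setdiff(rownames(biomarker_means), COHORT_BIOMARKERS)
  if (length(bad) > 0L || is.null(rownames(biomarker_means))) {
    stop(sprintf("invalid cohort spec: unknown biomarker name(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  bad <- setdiff(names(covariate_effects), COHORT_BIOMARKERS)
  if (length(bad) > 0L) {
    stop(sprintf("invalid cohort spec: unknown biomarker name(s) in effects: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (any(biomarker_sds <= 0)) {
    stop("invalid cohort spec: all biomarker SDs must be > 0", call. = FALSE)
  }
  if (any(survival_medians_days <= 0) || censor_horizon_days <= 0) {
    stop("invalid cohort spec: survival medians and censor horizon must be > 0",
         call. = FALSE)
  }
  structure(list(n_per_group = n_per_group[COHORT_GROUPS],
                 biomarker_means = biomarker_means,
                 biomarker_sds = biomarker_sds,
                 covariate_model = covariate_model,
                 covariate_effects = covariate_effects,
                 survival_medians_days = survival_medians_days,
                 censor_horizon_days = censor_horizon_days,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower | x >= upper)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower | x[bad] >= upper]
  }
  x
}

biomarker_bounds <- function(b) {
  switch(b,
         hvf = , cvf = c(0, 1),
         c(0, Inf))
}

#' Generate a synthetic cohort
#'
#' Draws one record per subject: diagnostic group, covariates, the six
#' biomarkers (group-Gaussian plus injected covariate effects, truncated at
#' physical bounds), a latent neurodegeneration status for MCI subjects
#' (PerpPD+ signature above the midpoint of the generative CU and AD means),
#' and progression-free survival for MCI subjects (exponential event times
#' by latent status, uniform censoring).
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with one row per subject.
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  cm <- spec$covariate_model
  rows <- lapply(COHORT_GROUPS, function(g) {
    n <- spec$n_per_group[[g]]
    if (n == 0L) return(NULL)
    age <- stats::rnorm(n, cm$age_mean[[g]], cm$age_sd[[g]])
    sex <- ifelse(stats::runif(n) < cm$female_prob[[g]], "female", "male")
    scanner <- sample(cm$scanner_levels, n, replace = TRUE, prob = cm$scanner_prob)
    bvalue <- sample(cm$bvalue_levels, n, replace = TRUE, prob = cm$bvalue_prob)
    data.frame(group = g,
               baseline_dx = switch(g, CU = "CU", AD = "dementia", "MCI"),
               age = age, sex = sex, scanner_model = scanner, bvalue = bvalue,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  n_all <- nrow(df)
  df$subject_id <- sprintf("S%04d", seq_len(n_all))
  for (b in COHORT_BIOMARKERS) {
    mu <- spec$biomarker_means[b, df$group]
    sd <- spec$biomarker_sds[b, df$group]
    eff <- spec$covariate_effects[[b]]
    shift <- rep(0, n_all)
    if (!is.null(eff)) {
      shift <- eff[["age"]] * (df$age - 70) +
        eff[["sex_female"]] * (df$sex == "female") +
        eff[["scanner"]] * (df$scanner_model != cm$scanner_levels[1]) +
        eff[["bvalue"]] * (df$bvalue - 1000) / 1000
    }
    bounds <- biomarker_bounds(b)
    x <- stats::rnorm(n_all, mu, sd) + shift
    bad <- which(x <= bounds[1] | x >= bounds[2])
    while (length(bad) > 0L) {
      x[bad] <- stats::rnorm(length(bad), mu[bad], sd[bad]) + shift[bad]
      bad <- bad[x[bad] <= bounds[1] | x[bad] >= bounds[2]]
    }
    df[[b]] <- x
  }
  # latent neurodegeneration status from the generative group separation
  midpoint <- (spec$biomarker_means["perppd_sig", "CU"] +
               spec$biomarker_means["perppd_sig", "AD"]) / 2
  df$latent_n_pos <- NA
  mci <- df$baseline_dx == "MCI"
  df$latent_n_pos[mci] <- df$perppd_sig[mci] >= midpoint
  # survival of MCI subjects
  df$time_days <- NA_real_
  df$event <- NA_integer_
  if (any(mci)) {
    med <- ifelse(df$latent_n_pos[mci],
                  spec$survival_medians_days[["n_pos"]],
                  spec$survival_medians_days[["n_neg"]])
    tev <- stats::rexp(sum(mci), rate = log(2) / med)
    cen <- stats::runif(sum(mci), 0, spec$censor_horizon_days)
    df$time_days[mci] <- pmax(pmin(tev, cen), 0.5)
    df$event[mci] <- as.integer(tev <= cen)
  }
  # follow-up bookkeeping for group-assignment exercises
  df$follow_up_years <- NA_real_
  cu <- df$group == "CU"
  nc <- df$group == "MCI_NC"
  cv <- df$group == "MCI_C"
  df$follow_up_years[cu] <- rtrunc_norm(sum(cu), cm$followup_mean[["CU"]],
                                        cm$followup_sd[["CU"]], lower = 2)
  df$follow_up_years[nc] <- rtrunc_norm(sum(nc), cm$followup_mean[["MCI_NC"]],
                                        cm$followup_sd[["MCI_NC"]], lower = 2)
  df$follow_up_years[cv] <- rtrunc_norm(sum(cv), cm$followup_mean[["MCI_C"]],
                                        cm$followup_sd[["MCI_C"]], lower = 0.1)
  df$conversion_interval_years <- NA_real_
  df$conversion_interval_years[mci & df$event == 1L] <-
    df$time_days[mci & df$event == 1L] / 365.25
  rownames(df) <- NULL
  df[, c("subject_id", "group", "baseline_dx", "age", "sex", "scanner_model",
         "bvalue", "follow_up_years", "conversion_interval_years",
         COHORT_BIOMARKERS, "latent_n_pos", "time_days", "event")]
}

#' Calibration survival medians for the four compared measures
#'
#' The median progression-free survival times (days) of the
#' neurodegeneration-positive and -negative MCI arms that the cohort
#' simulator and the scaled replication runs are calibrated to, for each
#' of the four compared measures (PerpPD+ signature, HVF, CT signature,
#' CVF).
#'
#' @return Data frame: measure, arm ("n_pos"/"n_neg"), median_days.
#' @export
reference_survival_medians <- function() {
  data.frame(
    measure = rep(c("perppd_sig", "hvf", "ct_sig", "cvf"), each = 2L),
    arm = rep(c("n_pos", "n_neg"), 4L),
    median_days = c(777, 2447, 1305, 2514, 935, 2447, 1893, 2118),
    stringsAsFactors = FALSE)
}

default_csf_targets <- function() {
  list(abeta42 = c(perppd_sig = -0.289),
       ptau181 = c(perppd_sig = 0.277),
       t_tau = c(perppd_sig = 0.339))
}

csf_units <- function() {
  list(abeta42 = c(mean = 700, sd = 250),
       ptau181 = c(mean = 60, sd = 25),
       t_tau = c(mean = 400, sd = 180))
}

#' Add CSF biomarkers with requested correlations to imaging metrics
#'
#' Each CSF variable is constructed as a linear combination of the
#' standardized target metrics plus independent noise, with weights solved
#' so the population correlations match the requested values given the
#' empirical correlation structure of the metrics. An assay-method label
#' (ELISA / Luminex) is assigned per subject.
#'
#' @param cohort Data frame from [gen_cohort()].
#' @param targets Named list: per CSF variable, a named vector of target
#'   correlations with biomarker columns (all |r| < 1).
#' @param seed Integer seed.
#' @return The cohort with CSF columns and `assay` appended.
#' @export
gen_csf <- function(cohort, targets = default_csf_targets(), seed = 1L) {
  set.seed(seed)
  n <- nrow(cohort)
  units <- csf_units()
  for (v in names(targets)) {
    tg <- targets[[v]]
    if (any(abs(tg) >= 1)) {
      stop("invalid CSF target: |r| must be < 1", call. = FALSE)
    }
    mets <- names(tg)
    bad <- setdiff(mets, names(cohort))
    if (length(bad) > 0L) {
      stop(sprintf("invalid CSF target: unknown metric(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    Z <- scale(as.matrix(cohort[, mets, drop = FALSE]))
    R <- stats::cor(Z)
    w <- tryCatch(solve(R, tg), error = function(e) {
      stop("infeasible correlation target: singular metric correlation matrix",
           call. = FALSE)
    })
    explained <- sum(w * tg)
    if (explained >= 1) {
      stop(sprintf(
        "infeasible correlation target for %s: implied variance %.3f >= 1 (not positive semidefinite)",
        v, explained), call. = FALSE)
    }
    z <- as.numeric(Z %*% w) + sqrt(1 - explained) * stats::rnorm(n)
    u <- if (v %in% names(units)) units[[v]] else c(mean = 0, sd = 1)
    cohort[[v]] <- u[["mean"]] + u[["sd"]] * z
  }
  cohort$assay <- sample(c("ELISA", "Luminex"), n, replace = TRUE)
  cohort
}

#' Simulate dichotomized MCI survival arms
#'
#' Two-arm exponential survival generator used for scaled replication runs:
#' arm sizes and median event times default to the at-risk structure the
#' package's survival analysis targets (42 neurodegeneration-positive with
#' median 777 days, 154 negative with median 2447 days), with independent
#' uniform administrative censoring.
#'
#' @param n_pos,n_neg Arm sizes.
#' @param median_pos_days,median_neg_days Exponential medians (days).
#' @param censor_horizon_days Upper bound of uniform censoring; `Inf`
#'   disables censoring.
#' @return Data frame: arm ("n_pos"/"n_neg"), time_days, event.
#' @export
simulate_survival_arms <- function(n_pos = 42, n_neg = 154,
                                   median_pos_days = 777,
                                   median_neg_days = 2447,
                                   censor_horizon_days = 9 * 365.25) {
  if (min(median_pos_days, median_neg_days) <= 0 || censor_horizon_days <= 0) {
    stop("medians and censor horizon must be > 0", call. = FALSE)
  }
  arm <- rep(c("n_pos", "n_neg"), c(n_pos, n_neg))
  med <- ifelse(arm == "n_pos", median_pos_days, median_neg_days)
  tev <- stats::rexp(length(arm), rate = log(2) / med)
  if (is.finite(censor_horizon_days)) {
    cen <- stats::runif(length(arm), 0, censor_horizon_days)
  } else {
    cen <- rep(Inf, length(arm))
  }
  data.frame(arm = arm,
             time_days = pmax(pmin(tev, cen), .Machine$double.eps),
             event = as.integer(tev <= cen),
             stringsAsFactors = FALSE)
}
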