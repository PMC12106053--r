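# End-to-end orchestration: acquisition filtering, confound adjustment,
# cutpoint derivation on CU/AD, classification of the MCI participants,
# and the per-measure survival comparison, with a structured, fully
# reproducible report.

SURVIVAL_MEASURES <- c("perppd_sig", "hvf", "ct_sig", "cvf")

measure_polarity <- function(measure) {
  if (measure %in% c("perppd_sig", "angler_sig", "parlpd_sig")) {
    "high_is_positive"
  } else {
    "low_is_positive"
  }
}

measure_covariates <- function(measure) {
  # macrostructural markers omit the b-value adjustment
  if (measure %in% c("hvf", "ct_sig", "cvf")) {
    c("age", "sex", "scanner_model")
  } else {
    c("age", "sex", "scanner_model", "bvalue")
  }
}

#' Run configuration for the analysis pipeline
#'
#' @param mode `"synthetic"` (generate a cohort from `cohort`) or
#'   `"files"` (read the cohort from `cohort_csv`).
#' @param cohort A [cohort_spec()] for synthetic mode.
#' @param cohort_csv Path to a cohort CSV for files mode.
#' @param measures Biomarkers carried into the survival comparison.
#' @param fit_subset `"cu_ad"` (default: confound models fitted on the
#'   cutpoint-derivation sample) or `"all"`.
#' @param alpha Significance level; `fdr_q` FDR level.
#' @param seed Integer seed; recorded in the report.
#' @param out Optional output directory for report files.
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"),
                       cohort = cohort_spec(),
                       cohort_csv = NULL,
                       measures = SURVIVAL_MEASURES,
                       fit_subset = c("cu_ad", "all"),
                       alpha = 0.05, fdr_q = 0.05,
                       seed = 1L, out = NULL) {
  mode <- match.arg(mode)
  fit_subset <- match.arg(fit_subset)
  if (mode == "files") {
    if (is.null(cohort_csv) || !file.exists(cohort_csv)) {
      stop("files mode requires an existing cohort_csv", call. = FALSE)
    }
  }
  structure(list(mode = mode, cohort = cohort, cohort_csv = cohort_csv,
                 measures = measures, fit_subset = fit_subset,
                 alpha = alpha, fdr_q = fdr_q,
                 seed = as.integer(seed), out = out),
            class = "run_config")
}

#' Apply the acquisition exclusion rules
#'
#' Removes records with slice thickness > 3 mm, b-value > 3000 s/mm^2 or a
#' 1.5 T field strength (strict inequalities: 3 mm, b = 3000 and 3 T are
#' retained). Per-rule exclusion counts are attached as the
#' `"exclusion_counts"` attribute.
#'
#' @param records Data frame with `slice_thickness_mm`, `bvalue` and
#'   `field_strength_t` columns (missing columns skip the rule).
#' @return Filtered records with an `exclusion_counts` attribute.
#' @export
apply_acquisition_filter <- function(records) {
  n <- nrow(records)
  bad_slice <- if ("slice_thickness_mm" %in% names(records)) {
    !is.na(records$slice_thickness_mm) & records$slice_thickness_mm > 3
  } else rep(FALSE, n)
  bad_b <- if ("bvalue" %in% names(records)) {
    !is.na(records$bvalue) & records$bvalue > 3000
  } else rep(FALSE, n)
  bad_field <- if ("field_strength_t" %in% names(records)) {
    !is.na(records$field_strength_t) & records$field_strength_t < 3
  } else rep(FALSE, n)
  counts <- c("slice thickness > 3 mm" = sum(bad_slice),
              "b-value > 3000" = sum(bad_b),
              "1.5T scanner" = sum(bad_field))
  out <- records[!(bad_slice | bad_b | bad_field), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusion_counts") <- counts
  out
}

#' Run the full analysis pipeline
#'
#' Sequences the stages: cohort (generated or read), acquisition filter,
#' group descriptives, covariate-adjusted group comparisons for all
#' biomarkers (Bonferroni over the contrast family), confound adjustment
#' of the survival measures, density-crossing cutpoints on the CU and AD
#' groups, neurodegeneration classification of the MCI participants, and
#' per-measure Kaplan-Meier / log-rank survival analysis with yearly
#' cumulative-proportion tables and pairwise log-rank matrices. The run is
#' fully determined by the configuration and seed.
#'
#' @param config A [run_config()].
#' @return List of class `pipeline_report`; written to `config$out` as CSV
#'   and JSON files when an output directory is given.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "cohort"
  report <- tryCatch({
    cohort <- if (config$mode == "synthetic") {
      spec <- config$cohort
      spec$seed <- as.integer((spec$seed + config$seed * 1000L) %% .Machine$integer.max)
      gen_cohort(spec)
    } else {
      read_cohort_csv(config$cohort_csv)
    }
    cohort <- apply_acquisition_filter(cohort)

    stage <- "descriptives"
    descriptives <- do.call(rbind, lapply(split(cohort, cohort$group), function(d) {
      data.frame(group = d$group[1], n = nrow(d),
                 age_mean = mean(d$age), age_sd = stats::sd(d$age),
                 female_n = sum(d$sex == "female"),
                 stringsAsFactors = FALSE)
    }))
    rownames(descriptives) <- NULL

    stage <- "group comparisons"
    biom <- intersect(COHORT_BIOMARKERS, names(cohort))
    comparisons <- do.call(rbind, lapply(biom, function(b) {
      out <- group_glm(cohort, b, measure_covariates(b), alpha = config$alpha)
      cbind(biomarker = b, out)
    }))

    stage <- "confound adjustment"
    fit_subset <- if (config$fit_subset == "cu_ad") {
      cohort$group %in% c("CU", "AD")
    } else rep(TRUE, nrow(cohort))
    adjusted <- cohort
    for (m in config$measures) {
      adjusted[[paste0(m, "_adj")]] <-
        adjust_confounds(cohort, m, measure_covariates(m), fit_subset)
    }

    stage <- "cutpoints"
    cu <- adjusted$group == "CU"
    ad <- adjusted$group == "AD"
    cutpoints <- lapply(config$measures, function(m) {
      density_crossing_cutpoint(adjusted[[paste0(m, "_adj")]][cu],
                                adjusted[[paste0(m, "_adj")]][ad],
                                polarity = measure_polarity(m),
                                biomarker = m, fallback = "empirical")
    })
    names(cutpoints) <- config$measures

    stage <- "classification"
    mci <- adjusted$baseline_dx == "MCI" & !is.na(adjusted$time_days)
    nstatus <- as.data.frame(lapply(config$measures, function(m) {
      classify_n_status(adjusted[[paste0(m, "_adj")]][mci], cutpoints[[m]])
    }), col.names = config$measures)

    stage <- "survival"
    time_days <- adjusted$time_days[mci]
    event <- adjusted$event[mci]
    yearly <- seq(0, 9) * 365.25
    survival <- lapply(config$measures, function(m) {
      pos <- nstatus[[m]]
      fit_pos <- km_fit(time_days[pos], event[pos], label = "N+")
      fit_neg <- km_fit(time_days[!pos], event[!pos], label = "N-")
      list(measure = m,
           n_pos = sum(pos), n_neg = sum(!pos),
           summary_pos = km_summary(fit_pos),
           summary_neg = km_summary(fit_neg),
           logrank = logrank(time_days, event,
                             ifelse(pos, "N+", "N-")),
           cps_pos = cps_table(fit_pos, yearly),
           cps_neg = cps_table(fit_neg, yearly))
    })
    names(survival) <- config$measures
    pairwise <- list(
      positive = pairwise_logrank(nstatus, time_days, event, "positive"),
      negative = pairwise_logrank(nstatus, time_days, event, "negative"))

    list(seed = config$seed, mode = config$mode,
         n_subjects = nrow(cohort), n_mci_survival = sum(mci),
         exclusions = attr(cohort, "exclusion_counts"),
         descriptives = descriptives, comparisons = comparisons,
         cutpoints = cutpoints, nstatus = nstatus,
         survival = survival, pairwise = pairwise,
         cohort = adjusted)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  class(report) <- "pipeline_report"
  if (!is.null(config$out)) {
    write_report(report, config$out)
  }
  report
}

survival_summary_table <- function(report) {
  do.call(rbind, lapply(report$survival, function(sv) {
    row <- function(arm, sm, n) {
      data.frame(measure = sv$measure, arm = arm, n = n,
                 median_days = sm$median_days,
                 median_ci_lower = sm$median_ci[["lower"]],
                 median_ci_upper = sm$median_ci[["upper"]],
                 restricted_mean_days = sm$restricted_mean_days,
                 restricted_mean_se = sm$restricted_mean_se,
                 stringsAsFactors = FALSE)
    }
    out <- rbind(row("N+", sv$summary_pos, sv$n_pos),
                 row("N-", sv$summary_neg, sv$n_neg))
    out$logrank_chi_square <- sv$logrank$chi_square
    out$logrank_p <- sv$logrank$p_value
    out
  }))
}

#' Write a pipeline report to disk
#'
#' Emits deterministic CSV tables (descriptives, group comparisons,
#' survival summaries, cumulative proportions, pairwise log-rank) plus
#' cutpoint JSONs and a JSON run summary.
#'
#' @param report A `pipeline_report`.
#' @param out Output directory (created if needed).
#' @return `out`, invisibly.
#' @export
write_report <- function(report, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$descriptives, file.path(out, "descriptives.csv"),
                   row.names = FALSE)
  utils::write.csv(report$comparisons, file.path(out, "group_comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(survival_summary_table(report),
                   file.path(out, "survival_summary.csv"), row.names = FALSE)
  cps <- do.call(rbind, lapply(report$survival, function(sv) {
    rbind(cbind(measure = sv$measure, arm = "N+", sv$cps_pos),
          cbind(measure = sv$measure, arm = "N-", sv$cps_neg))
  }))
  utils::write.csv(cps, file.path(out, "cumulative_proportions.csv"),
                   row.names = FALSE)
  utils::write.csv(rbind(cbind(arm = "positive", report$pairwise$positive),
                         cbind(arm = "negative", report$pairwise$negative)),
                   file.path(out, "pairwise_logrank.csv"), row.names = FALSE)
  for (m in names(report$cutpoints)) {
    write_cutpoint_json(report$cutpoints[[m]],
                        file.path(out, sprintf("cutpoint_%s.json", m)))
  }
  jsonlite::write_json(list(seed = report$seed, mode = report$mode,
                            n_subjects = report$n_subjects,
                            n_mci_survival = report$n_mci_survival),
                       file.path(out, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report: %d subjects, %d MCI in survival analysis\n",
              x$n_subjects, x$n_mci_survival))
  st <- survival_summary_table(x)
  print(st[, c("measure", "arm", "n", "median_days", "logrank_chi_square",
               "logrank_p")], row.names = FALSE)
  invisible(x)
}
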