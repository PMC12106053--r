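# Group assignment, confound adjustment, pairwise GLM contrasts,
# Benjamini-Hochberg FDR and partial correlations.

test_that("group assignment applies the follow-up and conversion rules", {
  rec <- data.frame(
    baseline_dx = c("MCI", "MCI", "CU", "dementia", "CU", "MCI"),
    follow_up_years = c(1.9, 3.5, 7.1, NA, 1.5, 4.0),
    conversion_interval_years = c(NA, 2.9, NA, NA, NA, NA),
    remained_cu = c(NA, NA, TRUE, NA, TRUE, NA))
  out <- assign_groups(rec)
  expect_false(out$included[1])                       # MCI, 1.9 y follow-up
  expect_equal(out$exclusion_reason[1], "insufficient follow-up")
  expect_equal(out$group[2], "MCI_C")                 # converted at 2.9 y
  expect_equal(out$time_days[2], 2.9 * 365.25)
  expect_equal(out$event[2], 1L)
  expect_equal(out$group[3], "CU")                    # stable CU, censored
  expect_equal(out$event[3], 0L)
  expect_equal(out$group[4], "AD")
  expect_false(out$included[5])                       # CU, 1.5 y follow-up
  expect_equal(out$group[6], "MCI_NC")

  rec$conversion_interval_years[2] <- -0.5
  expect_error(assign_groups(rec), "inconsistency")
})

test_that("progressing CU subjects are excluded with a reason", {
  rec <- data.frame(baseline_dx = "CU", follow_up_years = 5,
                    conversion_interval_years = NA, remained_cu = FALSE)
  out <- assign_groups(rec)
  expect_false(out$included)
  expect_match(out$exclusion_reason, "progressed")
})

make_stats_cohort <- function(n = 400, seed = 31, beta_age = 0) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("S%04d", 1:n),
    group = sample(c("CU", "AD"), n, replace = TRUE),
    age = rnorm(n, 70, 8),
    sex = sample(c("female", "male"), n, replace = TRUE),
    scanner_model = sample(c("siemens", "ge"), n, replace = TRUE),
    bvalue = sample(c(1000, 2000), n, replace = TRUE),
    y = rnorm(n, 2, 0.2) + beta_age * (rnorm(n, 70, 8) * 0))
}

test_that("confound adjustment is a near no-op when covariates are inert", {
  co <- make_stats_cohort(seed = 32)
  adj <- adjust_confounds(co, "y")
  expect_lt(mean(abs(adj - co$y)), 2 * 0.2 / sqrt(nrow(co)) * 4)
  expect_equal(mean(adj), mean(co$y), tolerance = 0.05)
})

test_that("an injected age slope is removed by adjustment", {
  set.seed(33)
  n <- 2000
  co <- data.frame(group = sample(c("CU", "AD"), n, TRUE),
                   age = rnorm(n, 70, 8),
                   sex = sample(c("female", "male"), n, TRUE),
                   scanner_model = "siemens",
                   bvalue = 1000)
  co$y <- 2 + 0.05 * (co$age - 70) + rnorm(n, 0, 0.2)
  suppressWarnings(adj <- adjust_confounds(co, "y",
                                           covariates = c("age", "sex")))
  expect_lt(abs(cor(adj, co$age)), 0.05)
  expect_gt(abs(cor(co$y, co$age)), 0.5)
})

test_that("adjustment is idempotent and preserves constants", {
  co <- make_stats_cohort(seed = 34)
  adj1 <- adjust_confounds(co, "y")
  co$adj1 <- adj1
  adj2 <- adjust_confounds(co, "adj1")
  expect_lt(max(abs(adj2 - adj1)) / max(abs(adj1)), 1e-10)

  co$const <- 5
  adjc <- adjust_confounds(co, "const")
  expect_equal(adjc, rep(5, nrow(co)))
})

test_that("collinear designs raise an error naming the offending column", {
  co <- make_stats_cohort(seed = 35)
  co$age_copy <- co$age
  expect_error(adjust_confounds(co, "y", covariates = c("age", "age_copy")),
               "age_copy")
})

test_that("group_glm emits 6 Bonferroni-corrected contrasts for 4 groups", {
  set.seed(36)
  n <- 240
  co <- data.frame(group = rep(c("CU", "MCI_NC", "MCI_C", "AD"), each = n / 4),
                   age = rnorm(n, 70, 8),
                   sex = sample(c("female", "male"), n, TRUE),
                   scanner_model = sample(c("siemens", "ge"), n, TRUE),
                   bvalue = sample(c(1000, 2000), n, TRUE))
  co$y <- rnorm(n, 2, 0.2) + 0.3 * (co$group == "AD")
  out <- group_glm(co, "y")
  expect_equal(nrow(out), 6)
  expect_equal(out$p_adjusted, pmin(1, out$p_raw * 6))
  expect_true(out$significant[out$contrast == "AD vs CU"])
})

test_that("with no covariates and balanced groups the contrasts match pooled t tests", {
  set.seed(37)
  co <- data.frame(group = rep(c("CU", "AD"), each = 6),
                   y = c(rnorm(6, 0), rnorm(6, 1)))
  out <- group_glm(co, "y", covariates = character(0))
  tt <- t.test(y ~ group, data = co, var.equal = TRUE)
  expect_equal(out$p_raw, tt$p.value, tolerance = 1e-12)
  expect_equal(abs(out$estimate), abs(diff(tt$estimate))[[1]],
               tolerance = 1e-12)
})

test_that("null simulations keep the Bonferroni family-wise error near alpha", {
  set.seed(38)
  reps <- 400
  fw <- 0
  for (i in seq_len(reps)) {
    co <- data.frame(group = rep(c("CU", "MCI_NC", "MCI_C", "AD"), each = 10),
                     y = rnorm(40))
    out <- group_glm(co, "y", covariates = character(0))
    fw <- fw + any(out$significant)
  }
  rate <- fw / reps
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / reps))
})

test_that("bh_fdr agrees with the explicit step-up oracle", {
  fdr <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_true(all(fdr$reject))               # p_(4) = 0.04 <= 4*0.05/4
  fdr2 <- bh_fdr(c(0.04, 0.04, 0.04, 0.5))
  expect_false(any(fdr2$reject))             # 0.04 > 3*0.05/4
  expect_false(any(bh_fdr(rep(1, 5))$reject))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(39)
  for (i in 1:1000) {
    m <- sample(1:10, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_identical(bh_fdr(p)$reject, bh_oracle(p))
  }
})

test_that("regional_glm ranks injected effects first and reduces to raw p for one region", {
  set.seed(40)
  n <- 200
  cohort <- data.frame(subject_id = sprintf("S%03d", 1:n),
                       group = rep(c("CU", "AD"), each = n / 2),
                       age = rnorm(n, 70, 8),
                       sex = sample(c("female", "male"), n, TRUE),
                       scanner_model = sample(c("siemens", "ge"), n, TRUE),
                       bvalue = sample(c(1000, 2000), n, TRUE))
  regions <- dk_regions()[1:30]
  hot <- regions[1:10]
  regional <- do.call(rbind, lapply(regions, function(rg) {
    eff <- if (rg %in% hot) 1.0 else 0
    data.frame(subject_id = cohort$subject_id, region = rg,
               value = rnorm(n, 0, 0.5) + eff * (cohort$group == "AD"))
  }))
  out <- regional_glm(regional, cohort)
  ad_cu <- out[out$contrast == "AD vs CU", ]
  top10 <- ad_cu$region[order(ad_cu$q_value, ad_cu$p_raw)][1:10]
  expect_setequal(top10, hot)
  expect_true(all(ad_cu$significant[ad_cu$region %in% hot]))

  one <- regional_glm(regional[regional$region == regions[12], ], cohort)
  expect_equal(one$q_value, one$p_raw)
})

test_that("partial correlations residualize shared covariates", {
  expect_equal(partial_pearson(1:10, 1:10)$r, 1)
  set.seed(41)
  n <- 5000
  z <- rnorm(n)
  x <- z + rnorm(n)
  y <- z + rnorm(n)
  pp <- partial_pearson(x, y, data.frame(z = z))
  expect_lt(abs(pp$r), 0.05)
  expect_equal(pp$df, n - 3L)
  expect_gt(abs(cor(x, y)), 0.3)
  expect_error(partial_pearson(z, z * 0 + z, data.frame(z = z)),
               "zero variance")
})

test_that("the CSF generator's headline correlation is recovered at study scale", {
  set.seed(42)
  spec <- cohort_spec(n_per_group = c(CU = 120, MCI_NC = 10, MCI_C = 15,
                                      AD = 20), seed = 43)
  rs <- replicate(30, {
    co <- gen_cohort(spec)
    aug <- gen_csf(co, seed = sample.int(1e6, 1))
    partial_pearson(aug$t_tau, aug$perppd_sig,
                    data.frame(age = aug$age, sex = aug$sex,
                               assay = aug$assay))$r
  })
  expect_equal(mean(rs), 0.339, tolerance = 0.05)
})
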