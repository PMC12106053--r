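# Kaplan-Meier estimation, median/restricted-mean summaries, log-rank
# tests and cumulative-proportion tables, checked against hand-computed
# product-limit values, brute-force oracles and the survival package.

test_that("km_fit reproduces the hand-computed product-limit curve", {
  f <- km_fit(c(5, 8, 12, 20, 25), c(1, 0, 1, 0, 1))
  expect_equal(km_surv(f, c(5, 12, 25)), c(0.8, 8 / 15, 0))
  expect_equal(km_surv(f, 0), 1)
  s <- km_summary(f)
  expect_equal(s$median_days, 25)   # S first reaches 0.5 at the last event
})

test_that("degenerate curves follow their contracts", {
  f <- km_fit(c(3, 7, 9), c(0, 0, 0))
  expect_true(all(f$surv == 1))
  s <- km_summary(f)
  expect_true(is.na(s$median_days))
  expect_true(is.finite(s$restricted_mean_days))

  # no censoring: S(t) is exactly the empirical survivor function
  set.seed(1)
  t <- sample(1:50, 30, replace = TRUE)
  f2 <- km_fit(t, rep(1, 30))
  grid <- c(0.5, 10, 25.5, 49, 50)
  expect_equal(km_surv(f2, grid),
               vapply(grid, function(g) mean(t > g), numeric(1)))

  expect_error(km_fit(numeric(0), integer(0)), "empty curve")
  expect_error(km_fit(c(1, -2), c(1, 1)), "positive")
})

test_that("km_fit matches the brute-force oracle exactly on random instances", {
  set.seed(2)
  for (i in 1:300) {
    n <- sample(1:8, 1)
    t <- sample(1:10, n, replace = TRUE)
    e <- rbinom(n, 1, 0.6)
    f <- km_fit(t, e)
    o <- km_oracle(t, e)
    expect_equal(km_surv(f, o$time), o$surv, tolerance = 1e-10)
  }
})

test_that("curve, Greenwood SE and median CI match the survival package", {
  skip_if_not_installed("survival")
  set.seed(3)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    t <- stats::rexp(n, log(2) / 777)
    e <- stats::rbinom(n, 1, 0.6)
    if (sum(e) == 0) next
    f <- km_fit(t, e)
    sf <- survival::survfit(survival::Surv(t, e) ~ 1, conf.type = "log-log")
    expect_equal(km_surv(f, sf$time), sf$surv, tolerance = 1e-12)
    se_ref <- sf$std.err * sf$surv   # NaN where S = 0 (0 * Inf)
    fin <- is.finite(se_ref)
    expect_equal(sqrt(f$greenwood_var)[match(sf$time, f$time)][fin],
                 se_ref[fin], tolerance = 1e-10)
    q <- stats::quantile(sf, 0.5)
    s <- km_summary(f)
    expect_equal(unname(s$median_days), unname(as.numeric(q$quantile)))
    expect_equal(unname(s$median_ci[["lower"]]), unname(as.numeric(q$lower)))
    expect_equal(unname(s$median_ci[["upper"]]), unname(as.numeric(q$upper)))
    tab <- summary(sf, rmean = max(t))$table
    expect_equal(s$restricted_mean_days, unname(tab[["rmean"]]),
                 tolerance = 1e-10)
    expect_equal(s$restricted_mean_se, unname(tab[["se(rmean)"]]),
                 tolerance = 1e-10)
  }
})

test_that("km median recovers the exponential quantile at scale", {
  set.seed(4)
  t <- stats::rexp(1e5, rate = log(2) / 777)
  s <- km_summary(km_fit(t, rep(1L, 1e5)))
  expect_equal(s$median_days, 777, tolerance = 0.02)
})

test_that("logrank reproduces the hand-worked two-group example", {
  # A = {1,2,3} all events, B = {4,5,6} all events:
  # O_A = 3, E_A = 3/6 + 2/5 + 1/4 = 1.15, V = 0.25 + 0.24 + 0.1875
  lr <- logrank(1:6, rep(1, 6), rep(c("A", "B"), each = 3))
  expect_equal(lr$table$observed[lr$table$group == "A"], 3)
  expect_equal(lr$table$expected[lr$table$group == "A"], 1.15)
  expect_equal(lr$chi_square, (3 - 1.15)^2 / 0.6775, tolerance = 1e-12)
  expect_equal(sum(lr$table$observed), sum(lr$table$expected),
               tolerance = 1e-9)
})

test_that("logrank degenerate and error cases behave", {
  t <- c(1, 3, 5, 7)
  e <- c(1, 0, 1, 1)
  lr <- logrank(c(t, t), c(e, e), rep(c("A", "B"), each = 4))
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  expect_error(logrank(t, e, rep("A", 4)), "2 groups")
  expect_error(logrank(t, c(0, 0, 0, 0), rep(c("A", "B"), 2)), "no events")
})

test_that("logrank matches the brute-force oracle and survdiff", {
  set.seed(5)
  checked <- 0
  for (i in 1:400) {
    n <- sample(4:8, 1)
    t <- sample(1:10, n, replace = TRUE)
    e <- rbinom(n, 1, 0.7)
    g <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(g)) < 2 || sum(e) == 0) next
    lr <- logrank(t, e, g)
    expect_equal(lr$chi_square, logrank_oracle_2g(t, e, g), tolerance = 1e-10)
    checked <- checked + 1
  }
  expect_gt(checked, 200)
  skip_if_not_installed("survival")
  set.seed(6)
  for (i in 1:20) {
    n <- 40
    t <- stats::rexp(n, 1 / 100)
    e <- rbinom(n, 1, 0.7)
    g <- sample(c("a", "b", "c"), n, replace = TRUE)
    if (sum(e) == 0) next
    lr <- logrank(t, e, g)
    sd_ <- survival::survdiff(survival::Surv(t, e) ~ g)
    expect_equal(lr$chi_square, unname(sd_$chisq), tolerance = 1e-8)
    expect_equal(lr$df, 2L)
  }
})

test_that("the two-arm scaled design separates at high power", {
  set.seed(7)
  hits <- 0
  for (i in 1:40) {
    d <- simulate_survival_arms()
    lr <- logrank(d$time_days, d$event, d$arm)
    hits <- hits + (lr$p_value < 0.001)
  }
  expect_gt(hits / 40, 0.75)
})

test_that("pairwise log-rank covers combinatorics, identity and power", {
  set.seed(8)
  n <- 200
  t <- stats::rexp(n, 1 / 1000)
  e <- rbinom(n, 1, 0.8)
  cls <- data.frame(m1 = rbinom(n, 1, 0.4) == 1,
                    m2 = rbinom(n, 1, 0.4) == 1,
                    m3 = rbinom(n, 1, 0.4) == 1,
                    m4 = rbinom(n, 1, 0.4) == 1)
  out <- pairwise_logrank(cls, t, e, "positive")
  expect_equal(nrow(out), 6)       # 4 measures -> 6 pairs
  cls2 <- cls; cls2$m2 <- cls2$m1  # identical classifications
  out2 <- pairwise_logrank(cls2, t, e, "positive")
  expect_equal(out2$chi_square[out2$measure_a == "m1" &
                                 out2$measure_b == "m2"], 0)
  # empty arm flagged not-computable
  cls3 <- cls; cls3$m3 <- FALSE
  out3 <- pairwise_logrank(cls3, t, e, "positive")
  expect_true(is.na(out3$chi_square[out3$measure_a == "m1" &
                                      out3$measure_b == "m3"]))

  # measure 1 selects a genuinely faster-progressing positive arm than
  # measure 2: their pairwise test should usually reject
  hits <- 0
  reps <- 40
  for (i in seq_len(reps)) {
    fast <- rbinom(n, 1, 0.35) == 1
    slow <- rbinom(n, 1, 0.35) == 1
    tt <- stats::rexp(n, ifelse(fast, 3 / 1000, 1 / 1000))
    cc <- stats::runif(n, 0, 3000)
    d <- data.frame(time = pmin(tt, cc), event = as.integer(tt <= cc))
    pr <- pairwise_logrank(data.frame(m1 = fast, m2 = slow),
                           d$time, d$event, "positive")
    hits <- hits + (pr$p_value[1] < 0.05)
  }
  expect_gt(hits / reps, 0.7)
})

test_that("cps_table reads the step function and at-risk counts correctly", {
  f <- km_fit(c(5, 8, 12, 20, 25), c(1, 0, 1, 0, 1))
  tab <- cps_table(f, c(0, 10, 30))
  expect_equal(tab$proportion_surviving, c(1.0, 0.8, 0.0))
  expect_equal(tab$n_at_risk[1], 5)
  expect_error(cps_table(f, c(5, 3)), "increasing")
})

test_that("day-to-year conversion rounds to one decimal", {
  expect_equal(days_to_years(777), 2.1)
  expect_equal(days_to_years(2447), 6.7)
  expect_equal(days_to_years(365.25), 1)
})
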