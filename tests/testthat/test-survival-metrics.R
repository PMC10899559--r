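test_that("the concordance index equals brute-force pair enumeration", {
  withr::with_seed(17, {
    for (k in 1:100) {
      n <- sample(5:20, 1)
      df <- tibble::tibble(score = rnorm(n), os_months = round(rexp(n, 0.08), 2),
                           event = rbinom(n, 1, 0.7))
      if (sum(df$event) == 0) df$event[1] <- 1
      got <- c_index(df, n_boot = 0)$c_index
      expect_equal(got, brute_cindex(df$score, df$os_months, df$event),
                   tolerance = 1e-12)
    }
  })
  # perfect ordering gives 1; all-equal scores give one half
  df <- tibble::tibble(score = c(4, 3, 2, 1), os_months = 1:4, event = 1)
  expect_equal(c_index(df, n_boot = 0)$c_index, 1)
  df$score <- 1
  expect_equal(c_index(df, n_boot = 0)$c_index, 0.5)
  # complementarity for tie-free data
  withr::with_seed(3, {
    df2 <- tibble::tibble(score = rnorm(12), os_months = rexp(12), event = rbinom(12, 1, 0.8))
    df2$event[1] <- 1
    cp <- c_index(df2, n_boot = 0)$c_index
    df2$score <- -df2$score
    expect_equal(c_index(df2, n_boot = 0)$c_index + cp, 1, tolerance = 1e-12)
  })
  # bootstrap CI brackets the estimate and is seeded
  withr::with_seed(9, {
    df3 <- tibble::tibble(score = rnorm(40), os_months = rexp(40, 0.1),
                          event = rbinom(40, 1, 0.8))
  })
  ci1 <- c_index(df3, n_boot = 200, seed = 5)
  ci2 <- c_index(df3, n_boot = 200, seed = 5)
  expect_identical(ci1, ci2)
  expect_lte(ci1$conf_low, ci1$c_index)
  expect_gte(ci1$conf_high, ci1$c_index)
})

test_that("the one-year AUC is the Mann-Whitney statistic with censored-before-12 excluded", {
  # hand set of 6: cases die < 12 months, one patient censored early is excluded
  df <- tibble::tibble(score = c(0.9, 0.8, 0.4, 0.3, 0.2, 0.6),
                       os_months = c(5, 9, 20, 30, 15, 8),
                       event = c(1, 1, 0, 1, 0, 0))  # last: censored at 8 -> excluded
  out <- auc_one_year(df, n_boot = 0)
  cases <- c(0.9, 0.8); controls <- c(0.4, 0.3, 0.2)
  rank_auc <- mean(outer(cases, controls, ">") + 0.5 * outer(cases, controls, "=="))
  expect_equal(out$auc, rank_auc)
  expect_equal(out$n_excluded, 1L)
  # monotone-transform invariance
  df2 <- df; df2$score <- exp(3 * df$score) - 1
  expect_equal(auc_one_year(df2, n_boot = 0)$auc, out$auc)
  # scores equal to labels give AUC 1
  df3 <- tibble::tibble(score = c(1, 1, 0, 0), os_months = c(5, 6, 20, 25),
                        event = c(1, 1, 0, 0))
  expect_equal(auc_one_year(df3, n_boot = 0)$auc, 1)
  # random scores on a large cohort sit at 1/2 within sampling error
  withr::with_seed(12, {
    df4 <- tibble::tibble(score = rnorm(2000),
                          os_months = rexp(2000, 1 / 15),
                          event = rbinom(2000, 1, 0.8))
  })
  expect_lt(abs(auc_one_year(df4, n_boot = 0)$auc - 0.5), 0.04)
  df5 <- tibble::tibble(score = 1:3, os_months = c(20, 25, 30), event = 1)
  expect_error(auc_one_year(df5, n_boot = 0), "class is empty")
})

test_that("the Youden cutoff equals an exhaustive threshold scan", {
  scan_oracle <- function(s, y) {
    us <- sort(unique(s))
    cand <- (us[-1] + us[-length(us)]) / 2
    j <- sapply(cand, function(ct) mean(s[y == 1] > ct) + mean(s[y == 0] <= ct) - 1)
    cand[which.max(j)]
  }
  withr::with_seed(23, {
    for (k in 1:100) {
      n <- sample(10:60, 1)
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
      s <- rnorm(n, mean = y)
      expect_equal(as.numeric(youden_cutoff(tibble::tibble(score = s, y = y))),
                   scan_oracle(s, y))
    }
  })
  # perfectly separated: the midpoint of the gap
  df <- tibble::tibble(score = c(0.1, 0.2, 0.8, 0.9), y = c(0, 0, 1, 1))
  expect_equal(as.numeric(youden_cutoff(df)), 0.5)
  expect_equal(attr(youden_cutoff(df), "youden"), 1)
  expect_error(youden_cutoff(tibble::tibble(score = rep(1, 4), y = c(0, 1, 0, 1))),
               "single distinct")
})

test_that("the Kaplan-Meier curve is the product-limit estimator", {
  # three deaths at 1, 2, 3
  km <- km_curve(tibble::tibble(os_months = 1:3, event = 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # censoring after the last event leaves survival unchanged
  km2 <- km_curve(tibble::tibble(os_months = c(1, 2, 3, 10), event = c(1, 1, 1, 0)))
  expect_equal(km2$surv, c(3 / 4 * 1, 3 / 4 * 2 / 3, 3 / 4 * 2 / 3 * 1 / 2, 3 / 4 * 2 / 3 * 1 / 2))
  # all censored: survival stays at one
  km3 <- km_curve(tibble::tibble(os_months = c(2, 5, 9), event = 0))
  expect_true(all(km3$surv == 1))
  # non-increasing, starts at or below 1
  withr::with_seed(2, {
    km4 <- km_curve(tibble::tibble(os_months = rexp(50, 0.1),
                                   event = rbinom(50, 1, 0.6)))
  })
  expect_true(all(diff(km4$surv) <= 1e-12))
  expect_lte(max(km4$surv), 1)
  # mixed hand case: the curve at the last event equals the product of factors
  t <- c(3, 5, 5, 8, 11); e <- c(1, 0, 1, 1, 0)
  km5 <- km_curve(tibble::tibble(os_months = t, event = e))
  expect_equal(min(km5$surv), (1 - 1 / 5) * (1 - 1 / 4) * (1 - 1 / 2))
})

test_that("the log-rank test matches the observed-minus-expected table arithmetic", {
  # identical groups: statistic 0, p 1
  df <- tibble::tibble(os_months = rep(c(2, 4, 6), 2), event = 1,
                       group = rep(c("a", "b"), each = 3))
  lr <- logrank_test(df)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)
  # hand 2xk table
  dfh <- tibble::tibble(os_months = c(1, 2, 3, 4, 5, 6), event = c(1, 1, 1, 1, 0, 1),
                        group = c("a", "b", "a", "b", "a", "b"))
  hand <- local({
    t <- dfh$os_months; e <- dfh$event; g <- dfh$group
    O <- 0; E <- 0; V <- 0
    for (tt in sort(unique(t[e == 1]))) {
      at_risk <- t >= tt
      n <- sum(at_risk); n1 <- sum(at_risk & g == "a")
      d <- sum(t == tt & e == 1); d1 <- sum(t == tt & e == 1 & g == "a")
      O <- O + d1
      E <- E + d * n1 / n
      if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O - E)^2 / V
  })
  expect_equal(logrank_test(dfh)$statistic, hand, tolerance = 1e-10)
  expect_error(logrank_test(dplyr::mutate(df, group = "a")), "2 nonempty")
})

test_that("strongly separated groups are detected with high power", {
  withr::with_seed(31, {
    hits <- 0
    for (k in 1:100) {
      g <- rep(c("low", "high"), each = 100)
      t <- c(rexp(100, 0.03), rexp(100, 0.12))  # hazard ratio 4
      cens <- rexp(200, 0.02)
      df <- tibble::tibble(os_months = pmin(t, cens),
                           event = as.integer(t < cens), group = g)
      if (logrank_test(df)$p_value < 0.05) hits <- hits + 1
    }
    expect_gte(hits, 95)
  })
})

test_that("evaluate_cohort assembles the full metric suite", {
  withr::with_seed(41, {
    n <- 120
    risk <- runif(n)
    t <- rexp(n, 0.05 * exp(2 * risk))
    cens <- rexp(n, 0.03)
    df <- tibble::tibble(patient_id = sprintf("P%03d", 1:n), score = risk,
                         os_months = pmin(t, cens), event = as.integer(t < cens))
  })
  res <- evaluate_cohort(df, cutoff = 0.5, n_boot = 50, seed = 2)
  expect_s3_class(res, "cohort_result")
  expect_gt(res$c_index$c_index, 0.5)
  expect_equal(res$per_patient$risk_group, ifelse(df$score > 0.5, "high", "low"))
  expect_lt(res$logrank$p_value, 0.05)
  expect_gt(res$hazard_ratio$hr, 1)
  g <- glance(res)
  expect_true(all(c("c_index", "auc_1yr", "hr", "logrank_p") %in% names(g)))
  km <- res$km
  expect_s3_class(km, "km_curve")
  expect_setequal(unique(km$group), c("high", "low"))
  # autoplot smoke checks
  expect_s3_class(ggplot2::autoplot(km), "ggplot")
})
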