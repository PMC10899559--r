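simulate_ph <- function(n, beta, seed, censor_rate = 0.02) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    t <- rexp(n, 0.05 * exp(beta * x))
    cens <- rexp(n, censor_rate)
    tibble::tibble(ldlm_score = x, os_months = pmin(t, cens),
                   event = as.integer(t < cens))
  })
}

test_that("the Cox fit recovers a unit coefficient from synthetic PH data", {
  df <- simulate_ph(1000, beta = 1, seed = 61)
  fit <- fit_nomogram(df, use_tdlm = FALSE, covariates = character())
  expect_lt(abs(fit$coefficients[["ldlm_score"]] - 1), 0.15)
})

test_that("under a null coefficient the estimates are small and p-values uniform", {
  betas <- numeric(40); ps <- numeric(40)
  for (k in 1:40) {
    df <- simulate_ph(150, beta = 0, seed = 700 + k)
    fit <- fit_nomogram(df, use_tdlm = FALSE, covariates = character())
    betas[k] <- fit$coefficients[["ldlm_score"]]
    ps[k] <- tidy(fit)$p_value[1]
  }
  expect_lt(abs(mean(betas)), 0.05)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

# two noisy readouts of one latent risk plus clinical covariates
make_fusion_data <- function(n, seed) {
  withr::with_seed(seed, {
    z <- rnorm(n)
    t <- rexp(n, 0.05 * exp(z))
    cens <- rexp(n, 0.02)
    tibble::tibble(
      ldlm_score = z + rnorm(n, sd = 0.9),
      tdlm_score = z + rnorm(n, sd = 0.9),
      recist = factor(sample(c("PR", "SD", "PD"), n, replace = TRUE),
                      levels = c("CR", "PR", "SD", "PD")),
      sex = sample(c("male", "female"), n, replace = TRUE),
      her2_status = sample(c("3+", "2+/FISH+"), n, replace = TRUE),
      os_months = pmin(t, cens),
      event = as.integer(t < cens))
  })
}

test_that("the without-marker variant drops exactly the marker coefficient", {
  df <- make_fusion_data(200, seed = 81)
  f1 <- fit_nomogram(df, use_tdlm = TRUE)
  f0 <- fit_nomogram(df, use_tdlm = FALSE)
  expect_equal(length(f1$coefficients), length(f0$coefficients) + 1)
  expect_false("tdlm_score" %in% names(f0$coefficients))
  expect_equal(f0$variant, "without-marker-score")
})

test_that("the linear predictor is exactly the coefficient-weighted covariate sum", {
  df <- make_fusion_data(150, seed = 82)
  fit <- fit_nomogram(df)
  sc <- nomo_score(fit, df)
  lp_fit <- unname(predict(fit$fit, newdata = as.data.frame(df), type = "lp",
                           reference = "zero"))
  expect_equal(sc$lp, lp_fit, tolerance = 1e-10)
  # monotonicity: increasing a positive-coefficient covariate lowers survival
  b <- fit$coefficients[["ldlm_score"]]
  d2 <- df[1, ]; d2$ldlm_score <- d2$ldlm_score + sign(b) * 2
  expect_lt(nomo_score(fit, d2)$surv_1yr, nomo_score(fit, df[1, ])$surv_1yr)
  # unseen factor level errors
  d3 <- df[1, ]; d3$sex <- "other"
  expect_error(nomo_score(fit, d3), "unseen level")
})

test_that("a patient at the covariate means gets the baseline one-year survival", {
  df <- simulate_ph(400, beta = 0.8, seed = 83)
  fit <- fit_nomogram(df, use_tdlm = FALSE, covariates = character())
  at_mean <- tibble::tibble(ldlm_score = mean(df$ldlm_score))
  expect_equal(nomo_score(fit, at_mean)$surv_1yr, fit$baseline_survival_1yr,
               tolerance = 1e-10)
})

test_that("points round-trip to the linear predictor within 1e-6", {
  df <- make_fusion_data(150, seed = 84)
  fit <- fit_nomogram(df)
  sc <- nomo_score(fit, df)
  lp_back <- lesiontime:::points_to_lp(fit, sc$points)
  expect_equal(lp_back, sc$lp, tolerance = 1e-6)
})

test_that("fused scores beat the best single covariate over simulation seeds", {
  wins <- 0
  for (k in 1:20) {
    df <- make_fusion_data(220, seed = 900 + k)
    tr <- df[1:150, ]; te <- df[151:220, ]
    fit <- fit_nomogram(tr, covariates = character())
    lp_te <- nomo_score(fit, te)$lp
    cf <- function(s) c_index(tibble::tibble(score = s, os_months = te$os_months,
                                             event = te$event), n_boot = 0)$c_index
    fused <- cf(lp_te)
    single <- max(cf(te$ldlm_score), cf(te$tdlm_score))
    if (fused >= single) wins <- wins + 1
  }
  expect_gte(wins, 11)  # a majority of 20 seeds
})

test_that("the calibration curve and Hosmer-Lemeshow test behave on hand cases", {
  # predictions of one half against a 50% event rate: curve point near (0.5, 0.5)
  withr::with_seed(91, {
    n <- 200
    ev <- rbinom(n, 1, 0.5)
    cal <- calibration_curve(rep(0.5, n) + rnorm(n, sd = 1e-6),
                             time = ifelse(ev == 1, 6, 100), event = ev)
  })
  expect_equal(mean(cal$curve$pred_surv), 0.5, tolerance = 1e-3)
  expect_equal(sum(cal$curve$n * cal$curve$obs_surv) / sum(cal$curve$n), 0.5,
               tolerance = 0.15)
  # hand 2-bin chi-square
  pred <- c(rep(0.2, 10), rep(0.8, 10))
  ev <- c(rep(1, 9), 0, rep(0, 8), 1, 1)  # deaths: 9/10 and 2/10
  cal2 <- calibration_curve(pred, time = ifelse(ev == 1, 6, 100), event = ev,
                            n_bins = 2)
  hand <- (9 - 10 * 0.8)^2 / (10 * 0.8 * 0.2) + (2 - 10 * 0.2)^2 / (10 * 0.2 * 0.8)
  expect_equal(cal2$test$statistic, hand, tolerance = 1e-10)
  expect_error(calibration_curve(runif(10), runif(10), rbinom(10, 1, 0.5)),
               "n >= 20")
  expect_s3_class(ggplot2::autoplot(cal2), "ggplot")
})

test_that("the Hosmer-Lemeshow p-value is approximately uniform under correct calibration", {
  ps <- numeric(200)
  withr::with_seed(95, {
    for (k in 1:200) {
      n <- 300
      x <- rnorm(n)
      ev <- rbinom(n, 1, stats::plogis(-0.3 + 0.8 * x))
      fitp <- fitted(stats::glm(ev ~ x, family = stats::binomial()))
      cal <- calibration_curve(1 - fitp, time = ifelse(ev == 1, 6, 100),
                               event = ev)
      ps[k] <- cal$test$p_value
    }
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
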