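test_that("survival labels implement the 12-month rule with indeterminate censoring", {
  lab <- survival_labels(c(5, 20, 8, 14, 11.9), c(1, 0, 0, 1, 1))
  expect_equal(lab$class, c("poor", "good", "indeterminate", "good", "poor"))
  expect_equal(lab$y, c(1, 0, NA, 0, 1))
})

test_that("cross-entropy matches closed forms and skips indeterminate patients", {
  lab <- survival_labels(c(5, 20, 30, 6), c(1, 0, 1, 1))
  expect_equal(ce_loss(c(1, 0, 0, 1), lab), 0)            # perfect fit
  expect_equal(ce_loss(rep(0.5, 4), lab), log(2))         # maximal uncertainty
  # hand-summed batch of 3
  lab3 <- survival_labels(c(5, 20, 30), c(1, 0, 1))
  r3 <- c(0.8, 0.3, 0.1)
  hand <- -(log(0.8) + log(0.7) + log(0.9)) / 3
  expect_equal(ce_loss(r3, lab3), hand, tolerance = 1e-12)
  # excluding indeterminate equals the filtered computation
  lab4 <- survival_labels(c(5, 20, 3, 30), c(1, 0, 0, 1))
  r4 <- c(0.8, 0.3, 0.99, 0.1)
  expect_equal(ce_loss(r4, lab4), ce_loss(r4[-3], lab4[-3, ]))
  lab_all_ind <- survival_labels(c(3, 4), c(0, 0))
  expect_error(ce_loss(c(0.5, 0.5), lab_all_ind), "indeterminate")
})

test_that("the survival loss is the Breslow Cox partial likelihood", {
  # identical scores, two patients, one event: -log(1/2)
  expect_equal(surv_loss(c(0.3, 0.3), c(5, 10), c(1, 0)), log(2), tolerance = 1e-12)
  # shift invariance
  withr::with_seed(2, {
    s <- rnorm(8); t <- rexp(8, 0.1); e <- rbinom(8, 1, 0.7); e[1] <- 1
    expect_equal(surv_loss(s, t, e), surv_loss(s + 13.7, t, e), tolerance = 1e-8)
  })
  # hand-enumerated batch of 4 (times 2 < 5 < 7 < 9, events at 2, 5, 9)
  s <- c(1.2, -0.4, 0.5, 0.1); t <- c(5, 2, 9, 7); e <- c(1, 1, 1, 0)
  hand <- -(
    (-0.4 - log(exp(1.2) + exp(-0.4) + exp(0.5) + exp(0.1))) +
      (1.2 - log(exp(1.2) + exp(0.5) + exp(0.1))) +
      (0.5 - log(exp(0.5)))
  ) / 3
  expect_equal(surv_loss(s, t, e), hand, tolerance = 1e-12)
  expect_error(surv_loss(c(1, 2), c(3, 4), c(0, 0)), "surv_batch_size")
})

test_that("the survival loss agrees with an independent brute-force enumeration", {
  brute <- function(s, t, e) {
    # direct Breslow partial likelihood: loop over event times
    ll <- 0
    for (tt in sort(unique(t[e == 1]))) {
      d <- which(t == tt & e == 1)
      rs <- which(t >= tt)
      ll <- ll + sum(s[d]) - length(d) * log(sum(exp(s[rs])))
    }
    -ll / sum(e)
  }
  withr::with_seed(5, {
    for (k in 1:20) {
      n <- sample(2:8, 1)
      s <- rnorm(n)
      t <- sample(1:6, n, replace = TRUE)  # forces ties
      e <- rbinom(n, 1, 0.7)
      if (sum(e) == 0) e[1] <- 1
      expect_equal(surv_loss(s, t, e), brute(s, t, e), tolerance = 1e-8)
    }
  })
})

test_that("training is seeded-deterministic and the total is the sum of the losses", {
  sim <- tiny_cohort(n = 20, seed = 91, followup_missing_prob = 0.1)
  m <- tiny_model(input = "image", d_model = 16, d_feat = 16, patch_px = 32,
                  n_heads = 2, n_layers = 1)
  fe <- cohort_features(m, sim$records)
  out <- tibble::tibble(patient_id = fe$patient_id,
                        os_months = sim$truth$os_months,
                        event = sim$truth$event)
  m1 <- train_risk_model(m, feats = fe, outcomes = out, epochs = 3,
                         batch_size = 10, seed = 4)
  m2 <- train_risk_model(m, feats = fe, outcomes = out, epochs = 3,
                         batch_size = 10, seed = 4)
  expect_identical(m1$par, m2$par)
  expect_identical(m1$fit$history, m2$fit$history)
  h <- m1$fit$history
  expect_equal(h$total, h$ce + h$surv, tolerance = 1e-12)
  expect_error(train_risk_model(m, feats = fe, outcomes = out,
                                use_ce = FALSE, use_surv = FALSE),
               "at least one loss")
})

test_that("a short smoke run reduces the loss and ablations produce distinct models", {
  sim <- tiny_cohort(n = 20, seed = 92, followup_missing_prob = 0.1)
  m <- tiny_model(input = "image", d_model = 16, d_feat = 16, patch_px = 32,
                  n_heads = 2, n_layers = 1)
  fe <- cohort_features(m, sim$records)
  out <- tibble::tibble(patient_id = fe$patient_id,
                        os_months = sim$truth$os_months,
                        event = sim$truth$event)
  mt <- train_risk_model(m, feats = fe, outcomes = out, epochs = 5,
                         batch_size = 20, lr = 5e-3, seed = 1)
  h <- mt$fit$history
  expect_lt(tail(h$total, 1), h$total[1])
  # loss ablation switches give three different checkpoints
  m_ce <- train_risk_model(m, feats = fe, outcomes = out, use_surv = FALSE,
                           epochs = 2, seed = 1)
  m_sv <- train_risk_model(m, feats = fe, outcomes = out, use_ce = FALSE,
                           epochs = 2, seed = 1)
  m_both <- train_risk_model(m, feats = fe, outcomes = out, epochs = 2, seed = 1)
  expect_false(identical(m_ce$par, m_sv$par))
  expect_false(identical(m_ce$par, m_both$par))
  expect_true(all(is.na(m_ce$fit$history$surv)))
  expect_true(all(is.na(m_sv$fit$history$ce)))
  # tidy/glance expose the history
  expect_equal(nrow(tidy(m_both)), 2)
  expect_true(glance(m_both)$trained)
})
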