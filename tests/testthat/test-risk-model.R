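test_that("feature extraction is deterministic, dimension-correct and non-constant", {
  m <- tiny_model(input = "image", d_model = 16, d_feat = 12, patch_px = 32)
  patch <- structure(list(array = array(runif(32 * 32 * 3), c(32, 32, 3)),
                          lesion_id = 1L, timepoint = 0L, site = "liver"),
                     class = "image_patch")
  f1 <- extract_features(m, patch)
  f2 <- extract_features(m, patch)
  expect_identical(f1, f2)
  expect_length(f1, 12)
  expect_true(all(is.finite(f1)))
  z0 <- extract_features(m, array(0, c(32, 32, 3)))
  z1 <- extract_features(m, array(1, c(32, 32, 3)))
  expect_gt(max(abs(z0 - z1)), 0)
  expect_error(extract_features(m, array(0, c(16, 16, 3))), "32 x 32 x 3")
})

test_that("object aggregation is invariant to lesion order and masked padding", {
  # property-tested over many random configurations
  for (k in 1:25) {
    m <- tiny_model(seed = k, d_model = 8 * (1 + k %% 2), n_heads = 2,
                    n_layers = 1 + k %% 2)
    d <- m$config$d_model
    P <- 2; O <- 2 + k %% 4
    L <- random_embedding(P, O, d, seed = 100 + k)
    obj <- matrix(TRUE, P, O)
    base <- lesion_pool(m, L, obj)$vector
    perm <- sample(O)
    shuf <- lesion_pool(m, L[, perm, , drop = FALSE], obj[, perm, drop = FALSE])$vector
    expect_equal(shuf, base, tolerance = 1e-5)
    # append masked padding objects with arbitrary content
    pad <- withr::with_seed(k, array(rnorm(P * 3 * d, sd = 5), c(P, 3, d)))
    L2 <- array(0, c(P, O + 3, d))
    L2[, 1:O, ] <- L; L2[, (O + 1):(O + 3), ] <- pad
    obj2 <- cbind(obj, matrix(FALSE, P, 3))
    padded <- lesion_pool(m, L2, obj2)$vector
    expect_equal(padded, base, tolerance = 1e-5)
  }
  # a single lesion still aggregates to a defined output
  m <- tiny_model(seed = 2, d_model = 8, n_heads = 2)
  one <- lesion_pool(m, random_embedding(1, 1, 8, seed = 9), matrix(TRUE, 1, 1))
  expect_true(all(is.finite(one$vector)))
})

test_that("temporal pooling is order-sensitive iff the position embedding is on", {
  for (k in 1:25) {
    m <- tiny_model(seed = 200 + k, d_model = 8, n_heads = 2,
                    n_layers = 1 + k %% 2, n_timepoints = 5)
    E <- random_embedding(3, 5, 8, seed = 300 + k)
    mask <- matrix(TRUE, 3, 5)
    perm <- c(2, 1, 3, 5, 4)
    off_base <- temporal_pool(m, E, mask, add_positions = FALSE)$pooled
    off_perm <- temporal_pool(m, E[, perm, , drop = FALSE], mask,
                              add_positions = FALSE)$pooled
    expect_equal(off_perm, off_base, tolerance = 1e-5)
    on_base <- temporal_pool(m, E, mask, add_positions = TRUE)$pooled
    on_perm <- temporal_pool(m, E[, perm, , drop = FALSE], mask,
                             add_positions = TRUE)$pooled
    expect_gt(max(abs(on_perm - on_base)), 1e-6)
  }
})

test_that("a single valid timepoint ignores the content of masked slots", {
  m <- tiny_model(seed = 5, d_model = 8, n_heads = 2, n_timepoints = 4)
  E1 <- random_embedding(2, 4, 8, seed = 1)
  E2 <- E1
  withr::with_seed(2, E2[, 2:4, ] <- rnorm(2 * 3 * 8, sd = 10))
  mask <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 4, byrow = TRUE)
  p1 <- temporal_pool(m, E1, mask)$pooled
  p2 <- temporal_pool(m, E2, mask)$pooled
  expect_identical(p1, p2)
  expect_error(temporal_pool(m, E1, matrix(FALSE, 2, 4)), "valid timepoint")
})

test_that("the softmax risk head behaves like a two-class probability", {
  m <- tiny_model(seed = 3, d_model = 8)
  withr::with_seed(8, {
    v <- matrix(rnorm(100 * 8), 100, 8)
    out <- predict_risk(m, v)
    expect_true(all(out$risk >= 0 & out$risk <= 1))
    # the two class probabilities are complementary
    p_good <- 1 / (1 + exp(out$logit_poor - out$logit_good))
    expect_equal(out$risk + p_good, rep(1, 100), tolerance = 1e-12)
  })
  # symmetric logits give risk one half
  m0 <- m
  m0$par[["head.W2"]][] <- 0
  m0$par[["head.b2"]][] <- 0
  expect_equal(predict_risk(m0, matrix(rnorm(8), 1))$risk, 0.5)
})

test_that("a patient missing the second follow-up scores identically at 2F and 1F horizons", {
  sim <- tiny_cohort(n = 10, seed = 44, followup_missing_prob = 0.5)
  m <- tiny_model(input = "image", d_model = 16, d_feat = 16, patch_px = 32,
                  n_heads = 2)
  fe <- cohort_features(m, sim$records)
  r2 <- predict_cohort(m, feats = fe, horizon = "2F")
  r1 <- predict_cohort(m, feats = fe, horizon = "1F")
  n_fup <- vapply(sim$records, function(r) sum(r$timepoints_present) - 1L, integer(1))
  miss2 <- which(n_fup <= 1)
  expect_gt(length(miss2), 0)
  expect_identical(r2$risk[miss2], r1$risk[miss2])
  # and a patient WITH 2F scores differently once it is unmasked
  has2 <- which(n_fup >= 2)
  if (length(has2) > 0) expect_false(any(r2$risk[has2] == r1$risk[has2]))
})

test_that("the baseline horizon ignores later scans entirely", {
  sim <- tiny_cohort(n = 4, seed = 8, followup_missing_prob = 0)
  m <- tiny_model(input = "image", d_model = 16, d_feat = 16, patch_px = 32,
                  n_heads = 2)
  fe <- cohort_features(m, sim$records)
  bs <- predict_cohort(m, feats = fe, horizon = "BS")
  # corrupt every follow-up feature: the baseline prediction cannot change
  fe2 <- fe
  fe2$F[, , 2:5, ] <- 99
  bs2 <- predict_cohort(m, feats = fe2, horizon = "BS")
  expect_identical(bs$risk, bs2$risk)
})

test_that("gradient flows into the aggregation token", {
  m <- tiny_model(seed = 6, d_model = 8, n_heads = 2)
  withr::with_seed(10, {
    F <- array(rnorm(2 * 2 * 5 * m$config$d_feat), c(2, 2, 5, m$config$d_feat))
  })
  fwd <- lesiontime:::model_forward(m, F, matrix(TRUE, 2, 2),
                                    array(TRUE, c(2, 2, 5)), collect = TRUE)
  g <- lesiontime:::model_backward(m, fwd, matrix(c(1, -1, 1, -1), 2, 2))
  expect_gt(sqrt(sum(g$agg^2)), 0)
})

test_that("duplicate lesions are scored but flagged", {
  sim <- tiny_cohort(n = 1, seed = 12)
  rec <- sim$records[[1]]
  rec$lesions <- c(rec$lesions, rec$lesions[1])  # same lesion twice
  rec$lesions[[length(rec$lesions)]]$lesion_id <- 99L
  m <- tiny_model(input = "image", d_model = 16, d_feat = 16, patch_px = 32,
                  n_heads = 2)
  expect_message(fe <- cohort_features(m, list(rec)), "duplicate")
  out <- predict_cohort(m, feats = fe, horizon = "2F")
  expect_true(is.finite(out$risk))
})

test_that("model checkpoints round-trip through disk", {
  m <- tiny_model(seed = 9, d_model = 8)
  f <- withr::local_tempfile(fileext = ".rds")
  save_risk_model(m, f)
  m2 <- load_risk_model(f)
  expect_identical(m$par, m2$par)
  expect_identical(m$config, m2$config)
})
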