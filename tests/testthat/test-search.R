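test_that("roc_auc matches the pairwise Mann-Whitney oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T)), 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  withr::with_seed(42, {
    for (rep in 1:50) {
      n <- sample(6:20, 1)
      scores <- sample(round(rnorm(n), 1)) # rounding forces ties
      labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
      expect_equal(xvent:::.auc_cpp(scores, as.integer(labels)),
                   oracle_auc(scores, labels))
    }
  })
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("AUC complements under negation and is rank-invariant", {
  withr::with_seed(11, {
    scores <- rnorm(30)
    labels <- rep(c(TRUE, FALSE), 15)
  })
  expect_equal(roc_auc(scores, labels) + roc_auc(-scores, labels), 1)
  expect_identical(roc_auc(scores, labels), roc_auc(exp(scores), labels))
  expect_identical(roc_auc(scores, labels), roc_auc(rank(scores), labels))
})

test_that("the ridge logistic fit agrees with glm at vanishing penalty", {
  withr::with_seed(19, {
    X <- matrix(rnorm(200), 100, 2)
    y <- as.numeric(runif(100) < plogis(0.5 + X %*% c(1, -0.5)))
  })
  beta <- xvent:::.ridge_logistic_cpp(X, y, 1e-10)
  ref <- unname(coef(glm(y ~ X, family = binomial())))
  expect_equal(as.numeric(beta), ref, tolerance = 1e-4)
})

test_that("count_composites is exact", {
  expect_identical(count_composites(154, 4), 23141965)
  expect_identical(count_composites(4, 4), 15)
  # brute-force enumeration oracle
  n_subsets <- sum(sapply(1:3, function(r) ncol(combn(10, r))))
  expect_equal(count_composites(10, 3), n_subsets)
  expect_equal(n_subsets, 175)
  expect_error(count_composites(0, 1), "invalid")
  expect_error(count_composites(5, 6), "invalid")
})

test_that("cv_auc is calibrated, deterministic, and order-invariant", {
  cb <- small_cohort()
  ct <- contrast_spec("copd_gold12", "control")
  # a feature identical across subjects is uninformative
  ch <- cb$cohort
  ch$expansion_mean <- 1
  r0 <- cv_auc(ch, "expansion_mean", ct, repeats = 20L, seed = 3L)
  expect_equal(r0$auc_mean, 0.5, tolerance = 0.02)
  # determinism under a fixed seed
  r1 <- cv_auc(cb$cohort, "flow_i9_sd", ct, repeats = 20L, seed = 3L)
  r2 <- cv_auc(cb$cohort, "flow_i9_sd", ct, repeats = 20L, seed = 3L)
  expect_identical(r1$fold_aucs, r2$fold_aucs)
  expect_length(r1$fold_aucs, 3L * 20L)
  # invariance to subject row order (shuffling is internal)
  withr::with_seed(9, perm <- sample(nrow(cb$cohort)))
  r3 <- cv_auc(cb$cohort[perm, ], "flow_i9_sd", ct, repeats = 20L, seed = 3L)
  expect_identical(r1$fold_aucs, r3$fold_aucs)
  # integer catalogue ids resolve to the same feature
  id <- cb$bank$biomarker_id[cb$bank$name == "flow_i9_sd"]
  r4 <- cv_auc(cb$cohort, id, ct, repeats = 20L, seed = 3L)
  expect_identical(r1$fold_aucs, r4$fold_aucs)
  expect_error(cv_auc(cb$cohort[1:9, ], "flow_i9_sd", ct, k = 8L),
               "at least k")
})

test_that("exhaustive search reproduces independent brute-force ranking", {
  bank4 <- enumerate_bank(statistics = "mean", n_intervals = 2L,
                          n_variants = 1L)
  withr::with_seed(23, {
    n <- 24
    y <- rep(c("a", "b"), each = n / 2)
    ch <- tibble::tibble(
      subject_id = sprintf("s%02d", 1:n),
      group_label = y,
      expansion_mean = rnorm(n, ifelse(y == "a", 1, 0)),
      flow_i1_mean = rnorm(n, ifelse(y == "a", 0.5, 0)),
      flow_i2_mean = rnorm(n),
      osc_v1_mean = rnorm(n, ifelse(y == "a", 0.3, 0))
    )
  })
  ct <- contrast_spec("a", "b")
  res <- search_composites(ch, ct, max_dim = 4L, repeats = 20L, seed = 5L,
                           budget = 100L, bank = bank4)
  expect_true(attr(res, "exhaustive"))
  expect_equal(attr(res, "n_evaluated"), 15L) # 2^4 - 1 subsets
  # brute force: evaluate every subset with cv_auc at the same seed
  feats <- c("expansion_mean", "flow_i1_mean", "flow_i2_mean", "osc_v1_mean")
  subsets <- unlist(lapply(1:4, function(d) combn(feats, d, simplify = FALSE)),
                    recursive = FALSE)
  brute <- vapply(subsets, function(s) {
    cv_auc(ch, s, ct, repeats = 20L, seed = 5L, bank = bank4)$auc_mean
  }, numeric(1))
  key <- vapply(subsets, function(s) paste(sort(s), collapse = "+"), "")
  res_key <- vapply(strsplit(res$features, " \\+ "), function(s) {
    paste(sort(s), collapse = "+")
  }, "")
  expect_equal(res$auc_mean, unname(brute[match(res_key, key)]),
               tolerance = 1e-12)
  # ranking is by auc desc, then smaller dimension
  expect_true(all(diff(res$auc_mean) <= 1e-12))
  same <- which(abs(diff(res$auc_mean)) < 1e-12)
  expect_true(all(res$dim[same + 1] >= res$dim[same]))
})

test_that("the staged search keeps singleton metrics at full repeats", {
  cb <- small_cohort()
  ct <- contrast_spec("copd_gold12", "control")
  res <- search_composites(cb$cohort, ct, max_dim = 2L, repeats = 20L,
                           seed = 2L, beam = 5L, top = 50L, budget = 200L)
  expect_false(attr(res, "exhaustive"))
  bb <- attr(res, "best_by_dim")
  expect_equal(nrow(bb), 2L)
  # dimension-1 entries agree with a direct cv_auc call
  direct <- cv_auc(cb$cohort, "flow_i9_sd", ct, repeats = 20L, seed = 2L)
  row <- res[res$features == "flow_i9_sd", ]
  if (nrow(row) == 1) expect_equal(row$auc_mean, direct$auc_mean)
  expect_error(search_composites(cb$cohort, ct, budget = 10L), "budget")
})

test_that("4DH scores are a thresholded linear predictor", {
  cb <- small_cohort()
  ct <- contrast_spec("copd_gold12", "control")
  m <- fit_4dh(cb$cohort, c("flow_i9_sd", "osc_v2_mean"), ct)
  expect_true(all(is.finite(m$scores$score)))
  # the full-data decision boundary separates the groups it was fit on
  expect_gt(m$auc, 0.5)
  # monotonicity: raising a positively weighted feature raises the score
  wpos <- names(which(m$weights > 0))[1]
  if (!is.na(wpos)) {
    ch2 <- cb$cohort
    ch2[[wpos]] <- ch2[[wpos]] + m$scale[wpos]
    s2 <- score_4dh(m, ch2)
    expect_true(all(s2$score > m$scores$score[
      match(s2$subject_id, m$scores$subject_id)] + 1e-9))
  }
  # fixed external threshold semantics: scores above 2.21 are abnormal
  m221 <- fit_4dh(cb$cohort, c("flow_i9_sd", "osc_v2_mean"), ct,
                  threshold = 2.21)
  expect_identical(m221$scores$abnormal, m221$scores$score > 2.21)
  # determinism
  m2 <- fit_4dh(cb$cohort, c("flow_i9_sd", "osc_v2_mean"), ct)
  expect_identical(m$weights, m2$weights)
  expect_identical(m$scores, m2$scores)
})
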