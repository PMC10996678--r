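test_that("mRMR picks the informative feature and shuns duplicates", {
  withr::with_seed(1, {
    labels <- rep(c("HC", "AD"), each = 15)
    single <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "only"))
    expect_identical(mrmr_select(single, labels, 1), "only")

    x <- matrix(rnorm(30 * 6), 30, 6,
                dimnames = list(NULL, sprintf("f%d", 1:6)))
    x[, 1] <- ifelse(labels == "AD", 2, 0) + rnorm(30, sd = 0.4)
    x <- cbind(x, dup = x[, 1])            # exact copy of the signal column
    sel <- mrmr_select(x, labels, 3)
    expect_true(sel[1] %in% c("f1", "dup"))
    # the duplicate is fully redundant with the first pick: never second
    expect_false(sel[2] %in% c("f1", "dup"))

    expect_warning(mrmr_select(cbind(x, flat = 1), labels, 3), "constant")
    expect_error(mrmr_select(x, rep("HC", 30), 2),
                 class = "ignitr_parameter_error")
  })
})

test_that("mRMR greedy selection equals exhaustive search for m = 2", {
  # greedy score oracle: for 5 features and m = 2, the greedy pick maximizes
  # relevance first, then relevance minus redundancy with the first pick
  withr::with_seed(2, {
    for (rep in 1:10) {
      labels <- rep(c("A", "B"), each = 12)
      x <- matrix(rnorm(24 * 5), 24, 5,
                  dimnames = list(NULL, sprintf("f%d", 1:5)))
      x[, 2] <- ifelse(labels == "B", 1.5, 0) + rnorm(24, sd = 0.8)
      disc <- apply(x, 2, ignitr:::discretize_feature)
      y <- as.integer(factor(labels))
      rel <- apply(disc, 2, ignitr:::mutual_information, y = y)
      first <- which.max(rel)
      score2 <- vapply(1:5, function(j)
        if (j == first) -Inf
        else rel[j] - ignitr:::mutual_information(disc[, j], disc[, first]),
        numeric(1))
      expect_identical(mrmr_select(x, labels, 2),
                       colnames(x)[c(first, which.max(score2))])
    }
  })
})

test_that("a planted informative feature ranks first in nearly all draws", {
  wins <- vapply(1:100, function(r) {
    withr::with_seed(1000 + r, {
      labels <- rep(c("HC", "AD"), c(17, 10))
      x <- matrix(rnorm(27 * 20), 27, 20,
                  dimnames = list(NULL, sprintf("f%02d", 1:20)))
      x[, 7] <- ifelse(labels == "AD", 2, 0) + rnorm(27, sd = 0.5)
      mrmr_select(x, labels, 1) == "f07"
    })
  }, logical(1))
  expect_gte(sum(wins), 95)
})

test_that("kNN votes match the all-pairs distance oracle", {
  withr::with_seed(3, {
    train <- matrix(rnorm(20 * 4), 20, 4)
    labels <- rep(c("HC", "AD"), each = 10)
    test <- matrix(rnorm(6 * 4), 6, 4)
    for (k in c(1, 3, 5)) {
      got <- knn_predict(train, labels, test, k)
      mu <- colMeans(train); sdv <- apply(train, 2, sd)
      tr <- scale(train, mu, sdv); te <- scale(test, mu, sdv)
      for (i in 1:6) {
        d <- apply(tr, 1, function(row) sqrt(sum((row - te[i, ])^2)))
        nb <- order(d)[1:k]
        expect_equal(unname(got$scores[i, "AD"]), mean(labels[nb] == "AD"))
      }
    }
  })
  # coincident point with k = 1 returns its own label with full score
  got <- knn_predict(matrix(1:8, 4, 2), c("a", "b", "a", "b"),
                     matrix(c(2, 6), 1, 2), 1)
  expect_identical(got$predicted, "b")
  expect_equal(unname(got$scores[1, "b"]), 1)
  # tie votes resolve towards the smaller class label
  tie <- knn_predict(matrix(c(0, 10, 0, 10), 2, 2), c("b", "a"),
                     matrix(c(5, 5), 1, 2), 2)
  expect_identical(tie$predicted, "a")
  expect_error(knn_predict(matrix(1:4, 2), c("a", "b"), matrix(1:2, 1), 3),
               class = "ignitr_parameter_error")
})

test_that("well-separated clusters classify perfectly", {
  withr::with_seed(4, {
    x <- rbind(matrix(rnorm(40, 0, 0.3), 10, 4),
               matrix(rnorm(40, 5, 0.3), 10, 4))
    labels <- rep(c("HC", "AD"), each = 10)
    got <- knn_predict(x[c(1:8, 11:18), ], labels[c(1:8, 11:18)],
                       x[c(9:10, 19:20), ], 3)
    expect_identical(got$predicted, c("HC", "HC", "AD", "AD"))
  })
})

test_that("nested cross-validation is deterministic and leak-free", {
  dat <- make_classification_data(n_a = 10, n_b = 8, n_noise = 30,
                                  n_signal = 8, seed = 5)
  cfg <- study_config(seed = 17, n_features = 5)
  r1 <- nested_cv(dat$x, dat$labels, cfg, inner_reps = 10)
  r2 <- nested_cv(dat$x, dat$labels, cfg, inner_reps = 10)
  expect_identical(r1$test_scores, r2$test_scores)
  expect_identical(r1$selected_features, r2$selected_features)
  expect_true(all(r1$best_k_per_fold %in% 2:5))

  # leakage audit: corrupting the held-out subject's label must not change
  # that fold's feature selection or tuned k
  for (fold in c(1, 11)) {
    flipped <- dat$labels
    flipped[fold] <- setdiff(unique(dat$labels), flipped[fold])
    r3 <- nested_cv(dat$x, flipped, cfg, inner_reps = 10)
    expect_identical(r3$selected_features[[fold]],
                     r1$selected_features[[fold]])
    expect_identical(r3$best_k_per_fold[fold], r1$best_k_per_fold[fold])
  }

  expect_error(nested_cv(dat$x, rep(c("a", "b", "c"), 6), cfg),
               class = "ignitr_parameter_error")
  expect_error(nested_cv(dat$x, c("a", rep("b", 17)), cfg),
               class = "ignitr_stratification_error")
})

test_that("pooled LOOCV AUC equals the brute-force rank statistic", {
  dat <- make_classification_data(n_a = 9, n_b = 7, n_noise = 20,
                                  n_signal = 6, seed = 6)
  cfg <- study_config(seed = 23, n_features = 4)
  rep1 <- nested_cv(dat$x, dat$labels, cfg, inner_reps = 8)
  expect_equal(rep1$test_auc / 100,
               oracle_auc(dat$labels, rep1$test_scores, rep1$positive))
})

test_that("feature attribution concentrates on the signal", {
  dat <- make_classification_data(n_a = 10, n_b = 8, n_noise = 10,
                                  n_signal = 2, gap = 2.5, sd_sig = 0.4,
                                  seed = 7)
  feats <- c(dat$signal_features[1], "noise01", "noise02")
  fa <- feature_attribution(dat$x, dat$labels, feats, k = 3, n_rep = 15,
                            seed = 8)
  expect_identical(attr(fa, "method"), "permutation_importance")
  expect_identical(fa$feature[1], dat$signal_features[1])
  expect_gt(fa$importance[1], 0.1)

  # single-feature model: all attribution on that feature
  solo <- feature_attribution(dat$x, dat$labels, dat$signal_features[1],
                              k = 3, n_rep = 10, seed = 9)
  expect_identical(nrow(solo), 1L)
  expect_gt(solo$importance[1], 0.1)

  # pure-noise model: attributions hover around zero
  null_fa <- feature_attribution(dat$x, dat$labels,
                                 c("noise03", "noise04", "noise05"),
                                 k = 3, n_rep = 15, seed = 10)
  expect_lt(max(abs(null_fa$importance)), 0.15)
})

test_that("the feature table concatenates the four regional measures", {
  prof <- data.frame(region_id = c("R1", "R2"), ignition = c(0.5, 0.6),
                     node_metastability = c(0.09, 0.08), n_events = 5L)
  class(prof) <- c("ignition_profile", "data.frame")
  burden <- data.frame(region_id = c("R2", "R1"), abeta = c(1.4, 1.2),
                       tau = c(1.6, 1.5))
  ft <- build_feature_table(list(A = prof), list(A = burden))
  expect_identical(dim(ft), c(1L, 8L))
  expect_equal(ft[1, "R1_abeta"], 1.2)     # aligned despite shuffled burden
  expect_equal(ft[1, "R2_metastability"], 0.08)
})
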