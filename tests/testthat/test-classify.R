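# Feature tables with a single informative term (hbond); all other terms 0.
gaussian_features <- function(n, mean_shift, seed, class) {
  set.seed(seed)
  df <- data.frame(pair_id = sprintf("%s%04d", class, seq_len(n)),
                   model_rank = 1L)
  for (col in energy_feature_names()) df[[col]] <- 0
  df$hbond <- rnorm(n, mean = mean_shift)
  df
}

test_that("train_classifier separates separable classes and is seed-deterministic", {
  pos <- gaussian_features(120, 0, seed = 1, class = "p")
  neg <- gaussian_features(120, 8, seed = 2, class = "n")  # far apart
  m1 <- train_classifier(pos[1:100, ], neg[1:100, ], n_trees = 100, seed = 9)
  p_pos <- predict(m1, pos[101:120, ])
  p_neg <- predict(m1, neg[101:120, ])
  expect_gt(min(p_pos), 0.9)
  expect_lt(max(p_neg), 0.1)
  m2 <- train_classifier(pos[1:100, ], neg[1:100, ], n_trees = 100, seed = 9)
  expect_equal(predict(m1, rbind(pos[101:120, ], neg[101:120, ])),
               predict(m2, rbind(pos[101:120, ], neg[101:120, ])))
  expect_error(train_classifier(pos[0, ], neg), "non-empty")
})

test_that("permuted labels give chance-level cross-validated AUC", {
  set.seed(33)
  pool <- gaussian_features(200, 0, seed = 3, class = "x")
  idx <- sample(200, 100)
  cv <- cross_validate(pool[idx, ], pool[-idx, ], k = 5, n_trees = 100, seed = 4)
  expect_lt(abs(cv$roc$auc - 0.5), 0.12)
})

test_that("cross_validate stratifies folds and scores every example once", {
  pos <- gaussian_features(53, 0, seed = 5, class = "p")
  neg <- gaussian_features(47, 2, seed = 6, class = "n")
  cv <- cross_validate(pos, neg, k = 10, n_trees = 50, seed = 7)
  expect_length(cv$scores, 100)
  expect_true(all(cv$scores >= 0 & cv$scores <= 1))
  fold_pos <- table(cv$fold[1:53])
  fold_neg <- table(cv$fold[54:100])
  expect_lte(diff(range(fold_pos)), 1)
  expect_lte(diff(range(fold_neg)), 1)
  expect_equal(sort(unique(cv$fold)), 1:10)
  expect_error(cross_validate(pos, neg, k = 1), "k must be")
})

test_that("10-fold CV on two-Gaussian classes approaches the analytic AUC", {
  delta <- 2
  pos <- gaussian_features(2000, delta, seed = 8, class = "p")
  neg <- gaussian_features(2000, 0, seed = 9, class = "n")
  cv <- cross_validate(pos, neg, k = 10, n_trees = 500, seed = 10)
  expect_lt(abs(cv$roc$auc - pnorm(delta / sqrt(2))), 0.03)
})

test_that("roc_curve endpoints, limits, and the hand-counted AUC", {
  r <- roc_curve(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))
  expect_equal(r$auc, 0.75)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  # perfect and uninformative scores
  expect_equal(roc_curve(c(1, 1, 0, 0), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_curve(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("roc_curve AUC equals the pair-comparison oracle on random data", {
  set.seed(21)
  for (case in 1:5) {
    n <- sample(20:200, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- rnorm(n) + labels * runif(1, 0, 2)
    expect_equal(roc_curve(scores, labels)$auc, oracle_auc(scores, labels),
                 tolerance = 1e-10)
  }
})

test_that("select_threshold_max_mcc finds separating and midpoint thresholds", {
  # separable: MCC 1 at the top of the gap; lowest admissible value returned
  scores <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  labels <- c(0, 0, 0, 1, 1, 1)
  sel <- select_threshold_max_mcc(scores, labels)
  expect_equal(sel$metrics$mcc, 1)
  expect_equal(sel$threshold, 0.3)
  # all scores equal: MCC 0 at that value
  flat <- select_threshold_max_mcc(rep(0.4, 8), rep(c(0, 1), 4))
  expect_equal(flat$metrics$mcc, 0)
  expect_equal(flat$threshold, 0.4)
  # balanced symmetric Gaussians: optimum near the midpoint of the means
  set.seed(12)
  s <- c(rnorm(2000, 0), rnorm(2000, 2))
  l <- rep(c(0, 1), each = 2000)
  mid <- select_threshold_max_mcc(s, l)
  expect_lt(abs(mid$threshold - 1), 0.3)
  # agreement with a dense brute-force grid scan, within one score gap
  grid <- seq(min(s), max(s), length.out = 2000)
  grid_mcc <- vapply(grid, function(t) {
    pred <- s > t
    classify_metrics(sum(pred & l == 1), sum(pred & l == 0),
                     sum(!pred & l == 0), sum(!pred & l == 1))$mcc
  }, numeric(1))
  expect_gte(mid$metrics$mcc, max(grid_mcc) - 1e-9)
  expect_error(select_threshold_max_mcc(1:5, rep(1, 5)), "both classes")
})

test_that("aggregate_topn applies the strict any-of-top-n rule", {
  rule <- decision_rule(0.13, top_n = 3)
  expect_true(aggregate_topn(c(0.05, 0.20, 0.10), rule))
  expect_false(aggregate_topn(c(0.05, 0.12), decision_rule(0.13, 2)))
  # second model invisible at top_n = 1
  expect_false(aggregate_topn(c(0.12, 0.90), decision_rule(0.13, 1)))
  # strictly greater: probability equal to the threshold is not a call
  expect_false(aggregate_topn(c(0.13), rule))
  expect_error(aggregate_topn(numeric(0), rule), "empty")
  expect_error(decision_rule(1.2, 1), "\\[0, 1\\]")
  expect_error(decision_rule(0.5, 0), "top_n")
})

test_that("top-n positive sets are nested, so TPR and FPR are non-decreasing in n", {
  set.seed(44)
  n_pairs <- 120
  probs <- matrix(runif(n_pairs * 5), nrow = n_pairs)
  truth <- rbinom(n_pairs, 1, 0.4)
  rates <- t(vapply(1:5, function(n) {
    rule <- decision_rule(0.6, n)
    calls <- apply(probs, 1, aggregate_topn, rule = rule)
    c(tpr = mean(calls[truth == 1]), fpr = mean(calls[truth == 0]))
  }, numeric(2)))
  expect_true(all(diff(rates[, "tpr"]) >= 0))
  expect_true(all(diff(rates[, "fpr"]) >= 0))
})

test_that("decide_pairs groups by pair, orders by rank and records the decision", {
  scored <- data.frame(
    pair_id = c("b", "b", "a", "a", "a"),
    model_rank = c(2, 1, 3, 1, 2),
    prob = c(0.9, 0.05, 0.5, 0.01, 0.02))
  out <- decide_pairs(scored, decision_rule(0.13, top_n = 2))
  expect_equal(out$decision[out$pair_id == "b"], TRUE)    # rank-2 model 0.9
  expect_equal(out$decision[out$pair_id == "a"], FALSE)   # 0.5 is at rank 3
  expect_equal(out$n_models[out$pair_id == "a"], 3)
})
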