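test_that("Euclidean-norm scaling matches hand-computed values", {
  tab <- data.frame(label = c("wet", "dry"), a = c(3, 4))
  sc <- scale_features(tab, feature_cols = "a")
  expect_equal(sc$table$a, c(0.6, 0.8))
  expect_equal(sum(sc$table$a^2), 1)
  # all-equal column of length n scales to 1/sqrt(n)
  tab2 <- data.frame(label = rep("wet", 4), a = rep(7, 4))
  expect_equal(scale_features(tab2, feature_cols = "a")$table$a,
               rep(0.5, 4))
  # scaling an already unit-norm column is the identity
  sc2 <- scale_features(sc$table, feature_cols = "a")
  expect_equal(sc2$table$a, sc$table$a)
  expect_error(scale_features(data.frame(a = c(0, 0)), feature_cols = "a"),
               "zero-norm.*a")
})

test_that("dry up-sampling balances classes with the remainder rule", {
  t1 <- data.frame(label = c(rep("wet", 48), rep("dry", 16)))
  b1 <- upsample_dry(t1)
  expect_equal(as.vector(table(b1$label)[c("wet", "dry")]), c(48, 48))
  # balanced input unchanged
  t2 <- data.frame(label = c(rep("wet", 5), rep("dry", 5)), x = 1:10)
  expect_identical(upsample_dry(t2)$x, t2$x)
  # 10 wet + 3 dry: 3 whole replications + first dry once more
  t3 <- data.frame(label = c(rep("wet", 10), rep("dry", 3)), x = 1:13)
  b3 <- upsample_dry(t3)
  expect_equal(sum(b3$label == "dry"), 10)
  expect_equal(sum(b3$x == 11), 4)  # first dry row appears 3+1 times
  expect_equal(sum(b3$x == 12), 3)
  expect_error(upsample_dry(data.frame(label = rep("wet", 3))), "no dry")
})

test_that("all nine families separate well-separated Gaussian blobs", {
  set.seed(1)
  mk <- function(n, mu, lab) {
    data.frame(label = lab, f1 = rnorm(n, mu), f2 = rnorm(n, mu))
  }
  train <- rbind(mk(20, 0, "wet"), mk(20, 10, "dry"))
  test <- rbind(mk(6, 0, "wet"), mk(6, 10, "dry"))
  for (fam in names(all_classifiers())) {
    p <- fit_predict(classifier_spec(fam), train, test, c("f1", "f2"),
                     seed = 5)
    expect_equal(p, test$label, info = fam)
  }
  expect_error(fit_predict(classifier_spec("LDA"), mk(10, 0, "wet"),
                           test, c("f1", "f2")),
               "single class")
})

test_that("1-NN predicts the training label of a duplicated point", {
  train <- data.frame(label = c("wet", "dry", "wet"),
                      f1 = c(0, 5, 1), f2 = c(0, 5, 1))
  test <- data.frame(f1 = 5, f2 = 5)
  p <- fit_predict(classifier_spec("KNN"), train, test, c("f1", "f2"))
  expect_equal(p, "dry")
})

test_that("QDA matches the closed-form quadratic discriminant", {
  set.seed(8)
  mu_w <- c(0, 0); mu_d <- c(1.5, 1)
  S_w <- matrix(c(1, 0.3, 0.3, 1), 2)
  S_d <- matrix(c(2, -0.4, -0.4, 0.8), 2)
  draw <- function(n, mu, S) {
    z <- matrix(rnorm(2 * n), n) %*% chol(S)
    sweep(z, 2, mu, "+")
  }
  xw <- draw(2000, mu_w, S_w)
  xd <- draw(2000, mu_d, S_d)
  train <- rbind(
    data.frame(label = "wet", f1 = xw[, 1], f2 = xw[, 2]),
    data.frame(label = "dry", f1 = xd[, 1], f2 = xd[, 2]))
  grid <- expand.grid(f1 = seq(-3, 4, length.out = 40),
                      f2 = seq(-3, 4, length.out = 40))
  pred <- fit_predict(classifier_spec("QDA"), train, grid, c("f1", "f2"))
  # independent implementation of the same discriminant
  mq <- MASS::qda(train[, c("f1", "f2")],
                  grouping = factor(train$label, c("dry", "wet")))
  ref <- as.character(stats::predict(mq, grid)$class)
  expect_gte(mean(pred == ref), 0.99)
  # and the closed-form Bayes rule from the true generating parameters
  # agrees away from the decision boundary
  qd <- function(x, mu, S) {
    d <- x - mu
    -0.5 * log(det(S)) - 0.5 * sum(d * solve(S, d))
  }
  margin <- apply(grid, 1, function(x) qd(x, mu_d, S_d) - qd(x, mu_w, S_w))
  bayes <- ifelse(margin > 0, "dry", "wet")
  clear <- abs(margin) > 0.25
  expect_gte(mean(pred[clear] == bayes[clear]), 0.99)
})

test_that("metric identities hold and degenerate precision is flagged", {
  m <- compute_metrics(tp = 3, fn = 2, tn = 10, fp = 5)
  expect_equal(m$accuracy + m$error_rate, 1)
  expect_equal(m$specificity + m$fpr, 1)
  expect_equal(m$precision, 3 / 8)
  all_right <- compute_metrics(tp = 17, fn = 0, tn = 51, fp = 0)
  expect_equal(all_right$accuracy, 1)
  expect_equal(all_right$fpr, 0)
  none_dry <- compute_metrics(tp = 0, fn = 17, tn = 51, fp = 0)
  expect_true(none_dry$precision_undefined)
  expect_true(is.na(none_dry$precision))
})

test_that("subset enumeration covers all non-empty combinations", {
  expect_length(enumerate_subsets(index_names()), 511)
  expect_length(enumerate_subsets(c("SCL", "TVSymp")), 3)
})

test_that("data views have the documented shapes", {
  rest <- random_feature_table(seed = 40, n_subjects = 5)
  test <- random_feature_table(seed = 41, n_subjects = 5)
  attr(rest, "view") <- NULL; attr(test, "view") <- NULL
  v <- build_views(rest, test)
  expect_named(v, c("rest_only", "test_only", "increment", "rest_and_test"))
  expect_equal(ncol(v$increment), 3 + 9)
  expect_equal(ncol(v$rest_and_test), 3 + 18)
  expect_equal(v$increment$SCL, test$SCL - rest$SCL)
  expect_equal(view_feature_cols("rest_and_test", c("SCL", "TVSymp")),
               c("SCL_rest", "SCL_test", "TVSymp_rest", "TVSymp_test"))
  expect_equal(view_feature_cols("increment", "SCL"), "SCL")
})

test_that("an oracle feature drives LOSO accuracy to 1", {
  tab <- random_feature_table(seed = 50)
  tab$SCL <- ifelse(tab$label == "dry", 1, -1)  # leaked label
  r <- loso_evaluate(tab, "SCL", classifier_spec("KNN"), seed = 1)
  expect_equal(r$accuracy, 1)
  expect_equal(r$tp, 17)
  expect_equal(r$tn, 51)
})

test_that("LOSO folds scale on training rows only", {
  tab <- random_feature_table(seed = 60, shift = 3,
                              shifted_cols = c("SCL", "TVSymp"))
  # divisors fit on a row subset ignore excluded rows entirely
  sc <- scale_features(tab, fit_rows = 1:10, feature_cols = "SCL")
  tab2 <- tab; tab2$SCL[11:20] <- tab2$SCL[11:20] * 1000
  sc2 <- scale_features(tab2, fit_rows = 1:10, feature_cols = "SCL")
  expect_equal(sc$divisors, sc2$divisors)
  # and the full evaluation is reproducible bit-exactly given a seed
  r1 <- loso_evaluate(tab, c("SCL", "TVSymp"), classifier_spec("SE_KNN"),
                      seed = 4)
  r2 <- loso_evaluate(tab, c("SCL", "TVSymp"), classifier_spec("SE_KNN"),
                      seed = 4)
  expect_identical(r1, r2)
})

test_that("sweep results are ordered by accuracy with documented ties", {
  tab <- random_feature_table(seed = 70, shift = 2.5,
                              shifted_cols = c("SCL", "NS.SCRs"))
  res <- exhaustive_sweep(tab, families = list(classifier_spec("LDA")),
                          indices = c("SCL", "NS.SCRs", "PRVHF"))
  expect_equal(nrow(res), 7)
  expect_true(all(diff(res$accuracy) <= 0))
  expect_true(all(res$accuracy + res$error_rate == 1))
  expect_true(all(res$specificity + res$fpr == 1))
  # the informative pair should beat the noise index
  expect_true(res$subset[1] %in%
                c("SCL;NS.SCRs", "SCL", "NS.SCRs",
                  "SCL;NS.SCRs;PRVHF", "SCL;PRVHF", "NS.SCRs;PRVHF"))
  expect_gt(res$accuracy[1],
            res[res$subset == "PRVHF", "accuracy"])
})
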