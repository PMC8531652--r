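separable_data <- function(n = 200, seed = 20) {
  withr::with_seed(seed, {
    y <- factor(rep(c("neg", "pos"), each = n / 2), levels = c("neg", "pos"))
    x <- cbind(ifelse(y == "pos", 1, -1) * 3 + rnorm(n, 0, 0.2), rnorm(n))
    list(x = x, y = y)
  })
}

test_that("random forest fits linearly separable data perfectly", {
  d <- separable_data()
  m <- train_model(classifier_spec("rf", params = list(nodesize = 1)), d$x, d$y)
  expect_equal(mean(predict_classes(m, d$x) == d$y), 1)
})

test_that("naive Bayes approaches the Bayes error of a unit-variance mixture", {
  # classes N(-1, 1) vs N(+1, 1): optimal accuracy is pnorm(1) = 0.841
  withr::with_seed(21, {
    n <- 4000
    y <- factor(rep(c("neg", "pos"), each = n / 2), levels = c("neg", "pos"))
    x <- matrix(rnorm(n, ifelse(y == "pos", 1, -1), 1), ncol = 1)
    ytest <- factor(rep(c("neg", "pos"), each = n / 2), levels = c("neg", "pos"))
    xtest <- matrix(rnorm(n, ifelse(ytest == "pos", 1, -1), 1), ncol = 1)
  })
  m <- train_model(classifier_spec("nb"), x, y)
  acc <- mean(predict_classes(m, xtest) == ytest)
  expect_equal(acc, pnorm(1), tolerance = 0.025)
})

test_that("all four classifier kinds separate clear data and are deterministic", {
  d <- separable_data(n = 300, seed = 22)
  for (kind in c("nb", "da", "rf", "mlp")) {
    spec <- classifier_spec(kind, params = if (kind == "mlp") list(size = 8, maxit = 100) else list())
    m1 <- train_model(spec, d$x, d$y, seed = 5)
    m2 <- train_model(spec, d$x, d$y, seed = 5)
    p1 <- predict_classes(m1, d$x)
    expect_identical(p1, predict_classes(m2, d$x))
    expect_gt(mean(p1 == d$y), 0.97)
  }
})

test_that("degenerate class covariance falls back to a ridge discriminant", {
  withr::with_seed(23, {
    y <- factor(rep(c("neg", "pos"), each = 30), levels = c("neg", "pos"))
    x <- cbind(ifelse(y == "pos", 2, -2) + rnorm(60, 0, 0.1), 0)  # constant column
  })
  m <- train_model(classifier_spec("da"), x, y)
  expect_null(m$fit$qda)
  expect_gt(m$fit$ridge, 0)
  expect_gt(mean(predict_classes(m, x) == y), 0.97)
})

test_that("prediction is a pure per-voxel map", {
  d <- separable_data(n = 100, seed = 24)
  m <- train_model(classifier_spec("rf"), d$x, d$y)
  perm <- withr::with_seed(25, sample.int(100))
  expect_identical(predict_classes(m, d$x[perm, ]),
                   predict_classes(m, d$x)[perm])
})

test_that("predict_mask enforces the component contract and reshapes", {
  d <- separable_data(n = 100, seed = 26)
  m <- train_model(classifier_spec("rf"), d$x, d$y)
  expect_error(predict_classes(m, d$x[, 1, drop = FALSE]), "components")
  scores <- matrix(c(rep(3, 12), rep(-3, 12)), 24, 2)
  mask <- predict_mask(m, scores, c(2, 3, 4))
  expect_equal(dim(mask), c(2, 3, 4))
  expect_equal(sum(mask), 12)
})

test_that("a majority-only model yields a constant mask", {
  # features carry no signal and one class dominates: the forest predicts
  # the majority class everywhere
  withr::with_seed(27, {
    y <- factor(c(rep("neg", 180), rep("pos", 20)), levels = c("neg", "pos"))
    x <- matrix(rnorm(400), 200, 2)
  })
  m <- train_model(classifier_spec("rf"), x, y)
  mask <- predict_mask(m, matrix(rnorm(120), 60, 2), c(3, 4, 5))
  expect_equal(sum(mask), 0)
})

test_that("leave-one-stack-out bookkeeping is exact", {
  # three tiny synthetic 'stacks' of separable samples
  sets <- lapply(1:3, function(i) {
    d <- separable_data(n = 80, seed = 30 + i)
    noise <- withr::with_seed(130 + i, matrix(rnorm(160, sd = 0.1), 80, 2))
    list(features = cbind(d$x, noise),
         labels = d$y, stack_id = paste0("s", i), damage = "low")
  })
  rep <- evaluate_loo(sets, classifier_spec("rf", params = list(nodesize = 5)),
                      fixed_k = 4, seed = 1)
  expect_equal(nrow(rep), 3)
  expect_true(all(rep$tp + rep$tn + rep$fp + rep$fn == 80))
  expect_true(all(rep$accuracy > 0.95))
  expect_equal(attr(rep, "median_accuracy"), median(rep$accuracy))

  # a constant-negative predictor scores the negative base rate: emulate by
  # destroying the signal and flooding with negatives
  skewed <- lapply(1:3, function(i) {
    withr::with_seed(40 + i, {
      y <- factor(c(rep("neg", 90), rep("pos", 10)), levels = c("neg", "pos"))
      list(features = matrix(rnorm(400), 100, 4), labels = y,
           stack_id = paste0("k", i), damage = "low")
    })
  })
  rep2 <- evaluate_loo(skewed, classifier_spec("rf"), fixed_k = 2, seed = 2)
  expect_true(all(abs(rep2$accuracy - 0.9) <= 0.1))

  # merging reports pools counts additively
  merged <- merge_eval_reports(rep, rep2)
  expect_equal(sum(merged$tp), sum(rep$tp) + sum(rep2$tp))

  # stacks without labels are excluded with a warning
  sets_empty <- c(sets, list(list(features = matrix(0, 0, 4),
                                  labels = factor(character(0), levels = c("neg", "pos")),
                                  stack_id = "empty", damage = "low")))
  expect_warning(rep3 <- evaluate_loo(sets_empty, classifier_spec("rf"),
                                      fixed_k = 2, seed = 1),
                 "excluded")
  expect_equal(nrow(rep3), 3)
})
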