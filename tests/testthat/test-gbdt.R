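test_that("negative gradient of the deviance behaves at its anchor points", {
  expect_equal(negative_gradient(1, 0), 1)
  expect_equal(negative_gradient(-1, 0), -1)
  expect_lt(abs(negative_gradient(1, 50)), 1e-10)
  set.seed(21)
  y <- sample(c(-1, 1), 40, replace = TRUE)
  f <- rnorm(40)
  # numeric differentiation of L(y, f) = log(1 + exp(-2yf))
  eps <- 1e-6
  num <- -(log1p(exp(-2 * y * (f + eps))) - log1p(exp(-2 * y * (f - eps)))) /
    (2 * eps)
  expect_equal(negative_gradient(y, f), num, tolerance = 1e-6)
})

test_that("regression tree finds the obvious split and mean leaf values", {
  x <- matrix(c(1, 2, 3, 4), ncol = 1)
  tree <- fit_regression_tree(x, c(0, 0, 1, 1), max_depth = 1,
                              min_samples_leaf = 1)
  root <- 1L
  expect_equal(tree$feature[root], 0L)
  expect_gt(tree$threshold[root], 2)
  expect_lt(tree$threshold[root], 3)
  kids <- c(tree$left[root], tree$right[root]) + 1L
  expect_equal(sort(tree$value[kids]), c(0, 1))

  # constant targets give a single leaf carrying that value
  tree0 <- fit_regression_tree(x, rep(0.7, 4))
  expect_equal(tree0$feature, -1L)
  expect_equal(tree0$value, 0.7)
})

test_that("leaf values equal the mean residual in the leaf (closed-form optimum)", {
  # under squared error the per-leaf argmin is the mean of the targets;
  # the raw tree must return exactly that on random small instances
  set.seed(22)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    x <- matrix(rnorm(n * 3), ncol = 3)
    r <- rnorm(n)
    tree <- fit_regression_tree(x, r, max_depth = sample(1:3, 1),
                                min_samples_leaf = sample(1:4, 1))
    for (leaf in unique(tree$row_leaf)) {
      expect_equal(tree$value[leaf + 1L], mean(r[tree$row_leaf == leaf]),
                   tolerance = 1e-12)
    }
    # fitted tree never increases squared error over the single-leaf tree
    pred <- tree$value[tree$row_leaf + 1L]
    expect_lte(sum((r - pred)^2), sum((r - mean(r))^2) + 1e-12)
  }
})

test_that("tree respects depth, leaf-size and purity stopping rules", {
  set.seed(23)
  x <- matrix(rnorm(200), ncol = 2)
  r <- rnorm(100)
  tree <- fit_regression_tree(x, r, max_depth = 2, min_samples_leaf = 10)
  leaves <- which(tree$feature == -1L)
  expect_lte(length(leaves), 4L)
  expect_true(all(tree$n[leaves] >= 10L))
})

test_that("gbdt fits, classifies a separable toy set perfectly and is monotone in loss", {
  toy <- separable_toy()
  fit <- gbdt(toy$x, toy$y, n_trees = 50, max_depth = 2,
              min_samples_leaf = 1, shrinkage = 0.1)
  expect_s3_class(fit, "gbdt")
  expect_equal(mean(predict(fit, toy$x, type = "class") == 2 * toy$y - 1), 1)
  expect_true(all(diff(fit$deviance) <= 1e-12))
  expect_equal(fit$f0, 0)   # balanced labels
})

test_that("gbdt rejects degenerate inputs", {
  x <- matrix(rnorm(20), ncol = 2)
  expect_error(gbdt(x, rep(1, 10)), "single-class")
  expect_error(gbdt(x, c(rep(0, 9), 2)), "binary")
  expect_error(gbdt(x[1:9, ], rep(0:1, len = 10)), "disagree")
  expect_error(gbdt(x, rep(0:1, 5), shrinkage = 0), "shrinkage")
})

test_that("prediction equals f0 plus shrunk leaf values and is internally consistent", {
  set.seed(24)
  x <- matrix(rnorm(60 * 4), ncol = 4)
  y <- as.integer(x[, 1] - x[, 3] > 0)
  fit <- gbdt(x, y, n_trees = 25)
  # training scores logged during fitting match a fresh prediction pass
  expect_equal(predict(fit, x, type = "score"), fit$fitted_scores,
               tolerance = 1e-12)
  p <- predict(fit, x, type = "response")
  s <- predict(fit, x, type = "score")
  expect_equal(p, 1 / (1 + exp(-2 * s)), tolerance = 1e-12)
  expect_true(all(diff(p[order(s)]) >= 0))     # monotone link
  expect_error(predict(fit, x[, 1:3]), "features")
  expect_error(predict(fit, x, type = "class", threshold = 1.2), "threshold")
  # a model with no net tree contribution scores f0 everywhere
  empty <- fit
  empty$trees <- lapply(empty$trees, function(t) {
    t$value[] <- 0
    t
  })
  expect_equal(predict(empty, x, type = "score"), rep(fit$f0, nrow(x)))
})

test_that("same data and configuration reproduce the model exactly", {
  set.seed(25)
  x <- matrix(rnorm(50 * 5), ncol = 5)
  y <- rep(0:1, 25)
  f1 <- gbdt(x, y, n_trees = 20)
  f2 <- gbdt(x, y, n_trees = 20)
  expect_equal(f1$trees, f2$trees)
  expect_equal(predict(f1, x), predict(f2, x))
})

test_that("gbdt overfits any consistent labeling with enough capacity", {
  set.seed(26)
  x <- matrix(rnorm(80 * 3), ncol = 3)
  y <- sample(0:1, 80, replace = TRUE)
  fit <- gbdt(x, y, n_trees = 300, max_depth = 3, min_samples_leaf = 1,
              shrinkage = 0.1)
  expect_equal(mean(predict(fit, x, type = "class") == 2 * y - 1), 1)
})

test_that("model JSON serialization round-trips predictions", {
  set.seed(27)
  x <- matrix(rnorm(40 * 3), ncol = 3)
  y <- rep(0:1, 20)
  fit <- gbdt(x, y, n_trees = 15)
  path <- withr::local_tempfile(fileext = ".json")
  write_gbdt(fit, path)
  back <- read_gbdt(path)
  expect_equal(predict(back, x, type = "score"),
               predict(fit, x, type = "score"), tolerance = 1e-12)
  expect_equal(back$shrinkage, fit$shrinkage)
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "other"), bad, auto_unbox = TRUE)
  expect_error(read_gbdt(bad), "not a ppiboost")
})

test_that("accuracy is within a few points of an established boosting implementation", {
  set.seed(28)
  n <- 200
  x <- matrix(rnorm(n * 6), ncol = 6)
  y <- as.integer(x[, 1] + 0.5 * x[, 2] - x[, 4] + rnorm(n, sd = 0.5) > 0)
  train <- 1:140; test <- 141:200
  ours <- gbdt(x[train, ], y[train], n_trees = 100, max_depth = 3,
               min_samples_leaf = 5, shrinkage = 0.1)
  acc_ours <- mean(predict(ours, x[test, ], type = "class") == 2 * y[test] - 1)
  ref <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 3, eta = 0.1,
                  lambda = 0, min_child_weight = 0, nthread = 1),
    data = xgboost::xgb.DMatrix(x[train, ], label = y[train]),
    nrounds = 100, verbose = 0)
  p_ref <- predict(ref, xgboost::xgb.DMatrix(x[test, ]))
  acc_ref <- mean(as.integer(p_ref >= 0.5) == y[test])
  expect_lte(abs(acc_ours - acc_ref), 0.05)
})

test_that("summary, print, plot and residuals methods work", {
  set.seed(29)
  x <- matrix(rnorm(60), ncol = 2)
  y <- rep(0:1, 15)
  fit <- gbdt(x, y, n_trees = 10)
  expect_output(print(fit), "Gradient boosting")
  s <- summary(fit)
  expect_s3_class(s, "summary.gbdt")
  expect_output(print(s), "trees")
  expect_equal(residuals(fit),
               negative_gradient(fit$y, fit$fitted_scores))
  pdf(NULL)
  on.exit(dev.off(), add = TRUE)
  expect_silent(plot(fit))
})
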