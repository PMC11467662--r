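test_that("stratified split preserves sizes, proportions and membership determinism", {
  set.seed(1)
  x <- matrix(rnorm(100 * 5), 100, 5,
              dimnames = list(sprintf("s%03d", 1:100), paste0("f", 1:5)))
  y <- rep(c("a", "b"), c(60, 40))
  sp <- split_spec(test_fraction = 0.2, seed = 2)
  parts <- train_test_split(x, y, sp)
  expect_identical(nrow(parts$train$x), 80L)
  expect_identical(nrow(parts$test$x), 20L)
  expect_length(intersect(parts$train$idx, parts$test$idx), 0)
  # class ratio preserved within one sample per class
  expect_lte(abs(sum(parts$test$y == "a") - 12), 1)
  expect_lte(abs(sum(parts$test$y == "b") - 8), 1)
  parts2 <- train_test_split(x, y, sp)
  expect_identical(parts$test$idx, parts2$test$idx)
  expect_error(split_spec(test_fraction = 0),
               "strictly between")
  expect_error(train_test_split(x[1:5, ], c("a", "a", "a", "a", "b"),
                                split_spec(seed = 1)),
               "too small")
})

test_that("grid search evaluates the whole grid and picks the better setting", {
  fx <- separable_fixture(n = 200, p = 15, n_inform = 3, seed = 3)
  # single-cell grid returns that setting
  gs1 <- grid_spec("random_forest", grid = list(num_trees = 50,
                                                max_depth = 0),
                   cv_folds = 3)
  fit1 <- grid_search_fit(fx$x, fx$y, gs1, seed = 4)
  expect_identical(fit1$best_params$num_trees, 50)
  expect_identical(nrow(fit1$cv_table), 1L)
  # a crippled 1-tree depth-1 forest must not displace a real one
  gs2 <- grid_spec("random_forest",
                   grid = list(num_trees = c(200, 1), max_depth = c(0, 1)),
                   cv_folds = 3)
  fit2 <- grid_search_fit(fx$x, fx$y, gs2, seed = 4)
  expect_identical(nrow(fit2$cv_table), 4L)
  expect_identical(fit2$best_params$num_trees, 200)
})

test_that("evaluation reproduces hand-computed metrics from confusion counts", {
  m <- confusion_metrics(tp = 90, fp = 10, tn = 95, fn = 5)
  expect_equal(m$precision_ppv, 0.900)
  expect_equal(m$npv, 0.950)
  expect_equal(m$recall_sensitivity, 90 / 95, tolerance = 1e-12)
  expect_equal(m$specificity, 95 / 105, tolerance = 1e-12)
  expect_equal(m$accuracy, 0.925)
  expect_equal(m$f1, 2 * 0.9 * (90 / 95) / (0.9 + 90 / 95))
  # perfect predictions
  perfect <- confusion_metrics(50, 0, 50, 0)
  expect_equal(unlist(perfect[c("accuracy", "precision_ppv", "npv",
                                "recall_sensitivity", "specificity",
                                "f1")]),
               c(accuracy = 1, precision_ppv = 1, npv = 1,
                 recall_sensitivity = 1, specificity = 1, f1 = 1))
  expect_length(perfect$undefined, 0)
})

test_that("zero-denominator metrics surface as NaN with a flag, never 0", {
  m <- confusion_metrics(tp = 0, fp = 0, tn = 80, fn = 20)
  expect_true(is.nan(m$precision_ppv))
  expect_true("precision_ppv" %in% m$undefined)
  expect_false(identical(m$precision_ppv, 0))
})

test_that("metric identities hold over random confusion counts", {
  set.seed(5)
  for (i in 1:50) {
    counts <- rmultinom(1, size = sample(20:500, 1), prob = runif(4))[, 1]
    tp <- counts[1]; fp <- counts[2]; tn <- counts[3]; fn <- counts[4]
    m <- confusion_metrics(tp, fp, tn, fn)
    expect_equal(m$accuracy, (tp + tn) / sum(counts))
    p <- m$precision_ppv; r <- m$recall_sensitivity
    if (!is.nan(p) && !is.nan(r) && p + r > 0) {
      expect_equal(m$f1, 2 * p * r / (p + r))
    }
    # swapping the positive class swaps precision<->NPV, recall<->specificity
    sw <- confusion_metrics(tn, fn, tp, fp)
    expect_equal(sw$precision_ppv, m$npv)
    expect_equal(sw$recall_sensitivity, m$specificity)
    expect_equal(sw$npv, m$precision_ppv)
    expect_equal(sw$specificity, m$recall_sensitivity)
  }
})

test_that("both model families master a linearly separable task", {
  fx <- cluster_fixture(n = 400, p = 200, n_inform = 20, effect = 2,
                        seed = 6)
  parts <- train_test_split(fx$x, fx$y, split_spec(seed = 7))
  for (mdl in c("random_forest", "xgboost")) {
    gs <- grid_spec(mdl,
                    grid = if (mdl == "random_forest") {
                      list(num_trees = 200, max_depth = 0)
                    } else {
                      list(num_trees = 100, max_depth = 3, eta = 0.3)
                    },
                    cv_folds = 3)
    fit <- grid_search_fit(parts$train$x, parts$train$y, gs, seed = 7)
    ev <- evaluate_model(fit, parts$test$x, parts$test$y)
    expect_gte(ev$metrics$accuracy, 0.95)
  }
})

test_that("the positive class defaults to the lexicographically larger label", {
  fx <- separable_fixture(n = 120, p = 10, seed = 8)
  fit <- quick_xgb(fx$x, fx$y, seed = 8, nrounds = 20)
  expect_identical(fit$positive, "caseB")
  fit2 <- grid_search_fit(fx$x, fx$y,
                          grid_spec("xgboost",
                                    grid = list(num_trees = 20,
                                                max_depth = 3, eta = 0.3),
                                    cv_folds = 3),
                          seed = 8, positive = "caseA")
  expect_identical(fit2$positive, "caseA")
})
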