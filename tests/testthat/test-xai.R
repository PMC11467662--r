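# single-feature fixture: only feature "f01" carries the label
single_feature_fit <- function(seed = 1) {
  set.seed(seed)
  n <- 200
  x <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, sprintf("f%02d", 1:10)))
  y <- ifelse(x[, 1] > 0, "pos", "neg")
  list(fit = quick_xgb(x, y, seed = seed, nrounds = 30), x = x, y = y)
}

test_that("variable importance singles out the label-determining feature", {
  sf <- single_feature_fit(1)
  vi <- varimp_ranking(sf$fit)
  expect_identical(vi$scores$feature[1], "f01")
  expect_equal(sum(vi$scores$score), 1)
  # forests agree
  frf <- grid_search_fit(sf$x, sf$y,
                         grid_spec("random_forest",
                                   grid = list(num_trees = 100,
                                               max_depth = 0),
                                   cv_folds = 3),
                         seed = 1)
  vi_rf <- varimp_ranking(frf)
  expect_identical(vi_rf$scores$feature[1], "f01")
  expect_equal(sum(vi_rf$scores$score), 1)
})

test_that("pure-noise features sit at the bottom of a planted ranking", {
  fx <- separable_fixture(n = 300, p = 20, n_inform = 3, noise = 0.2,
                          seed = 2)
  fit <- quick_xgb(fx$x, fx$y, seed = 2)
  vi <- varimp_ranking(fit)
  expect_setequal(vi$scores$feature[1:3], fx$informative)
})

test_that("tree SHAP attributions satisfy local accuracy and find the signal", {
  sf <- single_feature_fit(3)
  shap <- shap_ranking(sf$fit, sf$x, sf$x[1:50, ])
  expect_identical(shap$scores$feature[1], "f01")
  # the driving feature holds nearly all attribution mass
  expect_gte(shap$scores$score[1] / sum(shap$scores$score), 0.9)
  # per-sample attributions + bias reproduce the margin prediction
  phi <- attr(shap, "attributions")
  bias <- attr(shap, "bias")
  marg <- predict(sf$fit$fit, xgboost::xgb.DMatrix(sf$x[1:50, ]),
                  outputmargin = TRUE)
  expect_lt(max(abs(rowSums(phi) + bias - marg)), 1e-5)
})

test_that("a constant feature receives zero SHAP attribution", {
  set.seed(4)
  x <- matrix(rnorm(150 * 6), 150, 6,
              dimnames = list(NULL, sprintf("f%02d", 1:6)))
  x[, 6] <- 1
  y <- ifelse(x[, 1] > 0, "pos", "neg")
  fit <- quick_xgb(x, y, seed = 4, nrounds = 20)
  shap <- shap_ranking(fit, x, x[1:30, ])
  expect_equal(shap$scores$score[shap$scores$feature == "f06"], 0)
  expect_error(shap_ranking(fit, x, x[0, , drop = FALSE]), "empty")
})

test_that("sampling SHAP for forests agrees on the dominant feature", {
  sf <- single_feature_fit(5)
  frf <- grid_search_fit(sf$x, sf$y,
                         grid_spec("random_forest",
                                   grid = list(num_trees = 80,
                                               max_depth = 0),
                                   cv_folds = 3),
                         seed = 5)
  shap <- shap_ranking(frf, sf$x, sf$x[1:15, ], n_mc = 25, seed = 6)
  expect_identical(shap$scores$feature[1], "f01")
  expect_gte(shap$scores$score[1] / sum(shap$scores$score), 0.5)
})

test_that("LIME finds the signal and is reproducible and stable", {
  sf <- single_feature_fit(7)
  lime1 <- lime_ranking(sf$fit, sf$x[1:20, ], n_perturb = 300, seed = 8)
  expect_identical(lime1$scores$feature[1], "f01")
  lime2 <- lime_ranking(sf$fit, sf$x[1:20, ], n_perturb = 300, seed = 8)
  expect_identical(lime1$scores, lime2$scores)
  expect_error(lime_ranking(sf$fit, sf$x[1:5, ], n_perturb = 5), "n_perturb")
  # perturbation-count stability: top-10 Jaccard stays high
  fx <- separable_fixture(n = 250, p = 30, n_inform = 10, noise = 0.2,
                          seed = 9)
  fit <- quick_xgb(fx$x, fx$y, seed = 9)
  t_small <- ranking_top_k(lime_ranking(fit, fx$x[1:15, ],
                                        n_perturb = 500, seed = 10), 10)
  t_big <- ranking_top_k(lime_ranking(fit, fx$x[1:15, ],
                                      n_perturb = 5000, seed = 10), 10)
  jaccard <- length(intersect(t_small, t_big)) /
    length(union(t_small, t_big))
  expect_gte(jaccard, 0.8)
})

test_that("consensus implements the >= min_methods rule with Venn counts", {
  r1 <- make_ranking("shap", c(A = 3, B = 2, C = 1))
  r2 <- make_ranking("lime", c(B = 5, C = 4, D = 1))
  r3 <- make_ranking("varimp", c(C = 2, E = 1.5, F = 1))
  cs <- consensus_features(list(r1, r2, r3), k = 3, min_methods = 2)
  expect_setequal(cs$features$feature, c("B", "C"))
  expect_identical(unname(cs$venn[["shap+lime+varimp"]]), 1L)   # C
  expect_identical(unname(cs$venn[["shap+lime"]]), 1L)          # B
  expect_identical(sum(cs$venn[c("shap", "lime", "varimp")]), 4L)
  expect_identical(sum(cs$venn), 6L)   # |union of the three top-k lists|

  # identical lists: consensus is the full list, all in the triple region
  same <- lapply(c("shap", "lime", "varimp"), function(m)
    make_ranking(m, c(a = 5, b = 4, c = 3, d = 2, e = 1)))
  cs_same <- consensus_features(same, k = 5, min_methods = 2)
  expect_setequal(cs_same$features$feature, c("a", "b", "c", "d", "e"))
  expect_identical(unname(cs_same$venn[["shap+lime+varimp"]]), 5L)

  # disjoint lists: empty consensus at min_methods = 2
  disj <- list(make_ranking("shap", c(a = 1)),
               make_ranking("lime", c(b = 1)),
               make_ranking("varimp", c(c = 1)))
  expect_identical(nrow(consensus_features(disj, k = 1,
                                           min_methods = 2)$features), 0L)
  expect_error(consensus_features(disj[1:2], k = 1, min_methods = 2),
               "three")
})

test_that("consensus is monotone in min_methods", {
  set.seed(11)
  feats <- sprintf("f%02d", 1:15)
  rk <- lapply(c("shap", "lime", "varimp"), function(m)
    make_ranking(m, setNames(runif(15), feats)))
  sets <- lapply(1:3, function(mm)
    consensus_features(rk, k = 6, min_methods = mm)$features$feature)
  expect_true(all(sets[[3]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[1]]))
})

test_that("the three-explainer consensus recovers planted informative features", {
  fx <- separable_fixture(n = 400, p = 200, n_inform = 10, noise = 0.3,
                          seed = 12)
  parts <- train_test_split(fx$x, fx$y, split_spec(seed = 13))
  fit <- quick_xgb(parts$train$x, parts$train$y, seed = 13, nrounds = 80)
  shap <- shap_ranking(fit, parts$train$x, parts$test$x)
  lime <- lime_ranking(fit, parts$test$x, n_perturb = 400, seed = 14)
  vi <- varimp_ranking(fit)
  cs <- consensus_features(list(shap, lime, vi), k = 10, min_methods = 2)
  expect_gte(length(intersect(cs$features$feature, fx$informative)), 7)
})
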