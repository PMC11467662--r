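# Feature-attribution rankings (model-native importance, SHAP, LIME) and
# their top-k consensus. Exact TreeSHAP is delegated to xgboost's
# prediction-contribution mode; forests use a Monte-Carlo sampling Shapley
# estimator. The LIME surrogate (Gaussian perturbations, distance kernel,
# weighted lasso) is implemented here on top of glmnet. Aggregation over
# samples is the mean absolute attribution; ties in rankings break by
# feature id so every ranking is deterministic.

#' Build an importance ranking from named scores
#'
#' Orders features by descending score, ties broken by feature id.
#'
#' @param method Method label (\code{"shap"}, \code{"lime"},
#'   \code{"varimp"}, ...).
#' @param scores Named numeric vector of non-negative finite scores.
#' @return Object of class \code{importance_ranking}.
#' @export
make_ranking <- function(method, scores) {
  stopifnot(!is.null(names(scores)), all(is.finite(scores)))
  ord <- order(-scores, names(scores))
  df <- data.frame(feature = names(scores)[ord],
                   score = unname(scores)[ord],
                   rank = seq_along(scores),
                   stringsAsFactors = FALSE)
  structure(list(method = method, scores = df), class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat(sprintf("importance_ranking (%s), %d features; top: %s\n",
              x$method, nrow(x$scores),
              paste(utils::head(x$scores$feature, 5), collapse = ", ")))
  invisible(x)
}

#' Top-k features of a ranking
#'
#' @param ranking An \code{importance_ranking}.
#' @param k Number of features.
#' @return Character vector of the k best features.
#' @export
ranking_top_k <- function(ranking, k) {
  stopifnot(inherits(ranking, "importance_ranking"))
  utils::head(ranking$scores$feature, k)
}

#' Model-native variable importance
#'
#' Impurity-decrease importance for random forests, split gain for
#' gradient boosting; normalized to sum to 1. Features a boosted model
#' never split on score 0.
#'
#' @param model A \code{\link{grid_search_fit}} result.
#' @return An \code{importance_ranking} with method \code{"varimp"}.
#' @export
varimp_ranking <- function(model) {
  stopifnot(inherits(model, "fitted_classifier"))
  if (model$model_name == "random_forest") {
    imp <- model$fit$variable.importance
    if (is.null(imp)) stop("model carries no variable importances")
  } else {
    tab <- xgboost::xgb.importance(model = model$fit)
    imp <- stats::setNames(rep(0, length(model$feature_names)),
                           model$feature_names)
    imp[tab$Feature] <- tab$Gain
  }
  imp <- pmax(imp, 0)
  total <- sum(imp)
  if (total > 0) imp <- imp / total
  make_ranking("varimp", imp)
}

# Monte-Carlo sampling Shapley attributions for an arbitrary probability
# model: repeatedly walk a random feature permutation from a random
# background row towards the explained row, crediting each feature with the
# prediction change it causes. Unbiased for the interventional Shapley
# value; variance shrinks as 1/sqrt(n_mc).
sampling_shap <- function(model, background, explain_set, n_mc, seed) {
  set.seed(seed)
  p <- ncol(explain_set)
  n_ex <- nrow(explain_set)
  phi <- matrix(0, n_ex, p, dimnames = list(NULL, colnames(explain_set)))
  for (it in seq_len(n_mc)) {
    perm <- sample.int(p)
    bg <- background[sample.int(nrow(background), n_ex, replace = TRUE), ,
                     drop = FALSE]
    # stack the p+1 interpolation steps into one batched prediction
    z <- bg
    steps <- vector("list", p + 1)
    steps[[1]] <- z
    for (k in seq_len(p)) {
      z[, perm[k]] <- explain_set[, perm[k]]
      steps[[k + 1]] <- z
    }
    preds <- predict(model, do.call(rbind, steps), type = "prob")
    pm <- matrix(preds, nrow = n_ex)
    for (k in seq_len(p)) {
      phi[, perm[k]] <- phi[, perm[k]] + (pm[, k + 1] - pm[, k])
    }
  }
  phi / n_mc
}

#' SHAP attribution ranking
#'
#' For gradient-boosted models the per-sample attributions are exact
#' tree-path-dependent SHAP values (xgboost prediction contributions, on
#' the margin scale, satisfying local accuracy). For forests a Monte-Carlo
#' sampling Shapley estimator over the background set is used. The score is
#' the mean absolute attribution over the explained samples.
#'
#' @param model A \code{\link{grid_search_fit}} result.
#' @param background Background samples (used by the sampling estimator).
#' @param explain_set Samples to attribute (non-empty).
#' @param n_mc Monte-Carlo permutations for the sampling estimator.
#' @param seed Seed for the sampling estimator.
#' @return An \code{importance_ranking} with method \code{"shap"};
#'   per-sample attributions are attached as attribute
#'   \code{"attributions"}.
#' @export
shap_ranking <- function(model, background, explain_set, n_mc = 50,
                         seed = 1L) {
  stopifnot(inherits(model, "fitted_classifier"))
  explain_set <- as.matrix(explain_set)
  if (nrow(explain_set) == 0) stop("explain set is empty")
  if (model$model_name == "xgboost") {
    contrib <- stats::predict(model$fit,
                              xgboost::xgb.DMatrix(data = explain_set),
                              predcontrib = TRUE)
    bias_col <- intersect(c("BIAS", "(Intercept)"), colnames(contrib))
    phi <- contrib[, setdiff(colnames(contrib), bias_col), drop = FALSE]
    bias <- contrib[, bias_col[1]]
  } else {
    background <- as.matrix(background)
    phi <- sampling_shap(model, background, explain_set, n_mc, seed)
    bias <- NULL
  }
  scores <- colMeans(abs(phi))
  names(scores) <- colnames(phi)
  out <- make_ranking("shap", scores)
  attr(out, "attributions") <- phi
  attr(out, "bias") <- bias
  out
}

#' LIME attribution ranking
#'
#' For each explained sample, draws \code{n_perturb} Gaussian perturbations
#' around it (per-feature scale from the explained set), weights them by an
#' exponential kernel on standardized euclidean distance, and fits a
#' weighted lasso surrogate to the model's positive-class probability. The
#' surrogate is read at the sparsest point of the regularization path with
#' at most \code{n_surrogate} active features. The score is the mean
#' absolute surrogate weight over the explained samples.
#'
#' @param model A \code{\link{grid_search_fit}} result.
#' @param explain_set Samples to explain.
#' @param n_perturb Perturbations per sample (at least 10).
#' @param seed Seed for perturbation draws.
#' @param n_surrogate Maximum active features per local surrogate.
#' @param kernel_width Kernel width; default \code{0.75 * sqrt(p)}.
#' @return An \code{importance_ranking} with method \code{"lime"}.
#' @export
lime_ranking <- function(model, explain_set, n_perturb = 500, seed = 1L,
                         n_surrogate = 10, kernel_width = NULL) {
  stopifnot(inherits(model, "fitted_classifier"))
  if (n_perturb < 10) stop("n_perturb must be at least 10")
  explain_set <- as.matrix(explain_set)
  if (nrow(explain_set) == 0) stop("explain set is empty")
  p <- ncol(explain_set)
  sds <- apply(explain_set, 2, stats::sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  if (is.null(kernel_width)) kernel_width <- 0.75 * sqrt(p)

  set.seed(seed)
  total <- stats::setNames(rep(0, p), colnames(explain_set))
  for (s in seq_len(nrow(explain_set))) {
    x0 <- explain_set[s, ]
    z <- matrix(stats::rnorm(n_perturb * p, mean = rep(x0, each = n_perturb),
                             sd = rep(sds, each = n_perturb)),
                n_perturb, p, dimnames = list(NULL, colnames(explain_set)))
    prob <- predict(model, z, type = "prob")
    d <- sqrt(rowSums(sweep(z, 2, x0, "-")^2 / rep(sds^2, each = n_perturb)))
    w <- exp(-d^2 / kernel_width^2)
    fit <- glmnet::glmnet(z, prob, weights = w, alpha = 1,
                          standardize = TRUE)
    df <- fit$df
    idx <- which(df <= n_surrogate)
    idx <- if (length(idx)) max(idx) else 1L
    beta <- abs(as.numeric(fit$beta[, idx]))
    total <- total + beta
  }
  make_ranking("lime", total / nrow(explain_set))
}

#' Consensus of attribution rankings
#'
#' Takes the top-\code{k} features of each ranking and keeps the features
#' that appear in at least \code{min_methods} of them. Also tabulates the
#' Venn regions of the three top-k lists.
#'
#' @param rankings List of exactly three \code{importance_ranking} objects
#'   with distinct methods.
#' @param k Size of each top list.
#' @param min_methods Minimum number of supporting methods (1 to 3).
#' @return Object of class \code{consensus_set}: \code{features} (data
#'   frame with \code{feature}, \code{n_methods}, \code{methods}),
#'   \code{venn} (the 7 region counts), and the parameters used.
#' @export
#' @examples
#' r1 <- make_ranking("shap", c(A = 3, B = 2, C = 1))
#' r2 <- make_ranking("lime", c(B = 5, C = 4, D = 1))
#' r3 <- make_ranking("varimp", c(C = 2, E = 1.5, F = 1))
#' consensus_features(list(r1, r2, r3), k = 3, min_methods = 2)
consensus_features <- function(rankings, k = 10, min_methods = 2) {
  if (length(rankings) != 3 ||
      !all(vapply(rankings, inherits, logical(1), "importance_ranking"))) {
    stop("need exactly three importance rankings")
  }
  methods <- vapply(rankings, function(r) r$method, character(1))
  if (anyDuplicated(methods)) stop("ranking methods must be distinct")
  if (k < 1) stop("k must be at least 1")
  if (!min_methods %in% 1:3) stop("min_methods must be 1, 2 or 3")

  tops <- lapply(rankings, ranking_top_k, k = k)
  names(tops) <- methods
  all_feats <- sort(unique(unlist(tops)))
  membership <- vapply(tops, function(t) all_feats %in% t,
                       logical(length(all_feats)))
  membership <- matrix(membership, nrow = length(all_feats),
                       dimnames = list(all_feats, methods))
  n_methods <- rowSums(membership)

  sel <- n_methods >= min_methods
  feats <- data.frame(
    feature = all_feats[sel],
    n_methods = n_methods[sel],
    methods = apply(membership[sel, , drop = FALSE], 1,
                    function(r) paste(methods[r], collapse = "+")),
    stringsAsFactors = FALSE, row.names = NULL)
  feats <- feats[order(-feats$n_methods, feats$feature), ]
  rownames(feats) <- NULL

  # the 7 Venn regions of three sets
  pattern <- apply(membership, 1, function(r) paste(methods[r],
                                                    collapse = "+"))
  region_names <- c(methods,
                    paste(methods[c(1, 1, 2)], methods[c(2, 3, 3)],
                          sep = "+"),
                    paste(methods, collapse = "+"))
  venn <- stats::setNames(integer(7), region_names)
  tab <- table(pattern)
  venn[names(tab)] <- as.integer(tab)

  structure(list(features = feats, venn = venn, k = k,
                 min_methods = min_methods, methods = methods),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("consensus_set: %d features in >= %d of 3 top-%d lists\n",
              nrow(x$features), x$min_methods, x$k))
  if (nrow(x$features)) {
    cat(" ", paste(x$features$feature, collapse = ", "), "\n")
  }
  invisible(x)
}
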