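# Shared fixtures, all generated in code at test time.

# tiny labelled count matrix
toy_counts <- function(values, n_genes, n_samples) {
  matrix(values, n_genes, n_samples,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

# brute-force median-of-ratios oracle: explicit loops, explicit even-count
# median convention (mean of the two central order statistics)
oracle_size_factors <- function(counts, mode) {
  n_genes <- nrow(counts)
  n <- ncol(counts)
  geo <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    prod_i <- 1
    for (j in seq_len(n)) prod_i <- prod_i * counts[i, j]
    geo[i] <- prod_i^(1 / n)
  }
  m <- numeric(n)
  for (j in seq_len(n)) {
    ratios <- c()
    for (i in seq_len(n_genes)) {
      if (geo[i] != 0) ratios <- c(ratios, counts[i, j] / geo[i])
    }
    r <- sort(ratios)
    k <- length(r)
    m[j] <- if (k %% 2 == 1) r[(k + 1) / 2] else (r[k / 2] + r[k / 2 + 1]) / 2
  }
  if (mode == "unit_sum") m / sum(m) else m
}

# data lying exactly in a low-dimensional linear subspace
linear_fixture <- function(n = 200, p = 30, rank = 5, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n * rank), n, rank)
  w <- matrix(rnorm(rank * p), rank, p)
  x <- z %*% w
  dimnames(x) <- list(sprintf("s%03d", seq_len(n)),
                      sprintf("f%02d", seq_len(p)))
  x
}

# two-class dataset separable through a few informative features
separable_fixture <- function(n = 300, p = 30, n_inform = 3, noise = 0.3,
                              seed = 7, imbalance = 0.5) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              sprintf("f%02d", seq_len(p))))
  score <- rowSums(x[, seq_len(n_inform), drop = FALSE]) +
    rnorm(n, 0, noise)
  thr <- stats::quantile(score, imbalance)
  y <- ifelse(score > thr, "caseB", "caseA")
  list(x = x, y = y, informative = colnames(x)[seq_len(n_inform)])
}

# two-class dataset with per-feature mean shifts: each informative feature
# individually separates the classes (two Gaussian clusters)
cluster_fixture <- function(n = 400, p = 200, n_inform = 20, effect = 2,
                            seed = 7, frac_b = 0.5) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              sprintf("f%03d", seq_len(p))))
  y <- ifelse(runif(n) < frac_b, "caseB", "caseA")
  x[y == "caseB", seq_len(n_inform)] <-
    x[y == "caseB", seq_len(n_inform)] + effect
  list(x = x, y = y, informative = colnames(x)[seq_len(n_inform)])
}

# quick xgboost fit used by explainer tests
quick_xgb <- function(x, y, seed = 5, nrounds = 50) {
  grid_search_fit(x, y,
                  grid_spec("xgboost",
                            grid = list(num_trees = nrounds, max_depth = 3,
                                        eta = 0.3),
                            cv_folds = 3),
                  seed = seed)
}
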