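test_that("filter_genes separates low-count, near-zero-variance and kept genes", {
  counts <- rbind(
    toy_counts(0L, 1, 6),                       # all-zero -> low count
    matrix(7L, 1, 6),                           # constant -> nzv
    matrix(c(10L, 20L, 30L, 40L, 50L, 60L), 1, 6),
    matrix(c(15L, 25L, 35L, 45L, 55L, 65L), 1, 6))
  dimnames(counts) <- list(paste0("g", 1:4), paste0("s", 1:6))
  res <- filter_genes(counts, min_total = 10)
  expect_identical(res$report$removed_low_count, "g1")
  expect_identical(res$report$removed_nzv, "g2")
  expect_setequal(res$report$kept, c("g3", "g4"))
  # partition invariant
  expect_setequal(c(res$report$removed_low_count, res$report$removed_nzv,
                    res$report$kept), rownames(counts))
})

test_that("count filter removes exactly the rows below min_total", {
  counts <- toy_counts(c(1L, 30L, 60L, 1L, 30L, 60L, 1L, 20L, 40L,
                         2L, 20L, 40L), 3, 4)
  # row sums: 5, 100, 200
  expect_identical(unname(rowSums(counts)), c(5, 100, 200))
  res <- filter_genes(counts, min_total = 10)
  expect_identical(length(res$report$removed_low_count), 1L)
  expect_identical(res$report$removed_low_count, "g01")
})

test_that("removing every gene raises an error carrying the report", {
  counts <- toy_counts(0L, 3, 4)
  err <- tryCatch(filter_genes(counts, min_total = 10),
                  error = function(e) e)
  expect_s3_class(err, "error")
  expect_s3_class(err$report, "filter_report")
})

test_that("size factors match the closed forms on identical and scaled columns", {
  # identical positive columns: all ratios 1
  counts <- toy_counts(rep(c(2L, 5L, 9L), 3), 3, 3)
  sf <- compute_size_factors(counts, mode = "unit_sum")
  expect_equal(unname(sf$s), rep(1 / 3, 3))
  # column 2 = 2 x column 1: G_i = x_i * sqrt(2), m = (1/sqrt2, sqrt2)
  counts2 <- cbind(s1 = c(4L, 10L, 6L), s2 = c(8L, 20L, 12L))
  rownames(counts2) <- paste0("g", 1:3)
  sf_us <- compute_size_factors(counts2, mode = "unit_sum")
  expect_equal(unname(sf_us$s), c(1 / 3, 2 / 3))
  sf_deseq <- compute_size_factors(counts2, mode = "deseq")
  expect_equal(unname(sf_deseq$s), c(1 / sqrt(2), sqrt(2)))
})

test_that("genes containing a zero are excluded from the median", {
  counts <- cbind(s1 = c(4L, 10L, 6L), s2 = c(8L, 20L, 12L))
  rownames(counts) <- paste0("g", 1:3)
  base <- compute_size_factors(counts, mode = "deseq")$s
  with_zero <- rbind(counts, g4 = c(0L, 50L))
  expect_equal(compute_size_factors(with_zero, mode = "deseq")$s, base)
})

test_that("an all-zero-geometric-mean matrix cannot be normalized", {
  counts <- toy_counts(c(0L, 1L, 1L, 0L), 2, 2)
  expect_error(compute_size_factors(counts), "geometric mean")
})

test_that("size factors agree with the brute-force oracle on random matrices", {
  set.seed(42)
  for (rep_i in 1:10) {
    vals <- rpois(20 * 6, lambda = 30)
    vals[rbinom(20 * 6, 1, 0.1) == 1] <- 0L   # sprinkle zeros
    counts <- toy_counts(vals, 20, 6)
    for (mode in c("unit_sum", "deseq")) {
      got <- compute_size_factors(counts, mode = mode)$s
      want <- oracle_size_factors(counts, mode)
      expect_equal(unname(got), want, tolerance = 1e-12)
    }
  }
})

test_that("deseq-mode factors match the DESeq2 reference implementation", {
  set.seed(11)
  # odd gene count and no zeros so both median conventions coincide
  # (with an even count DESeq2 interpolates in log space, this package in
  # ratio space)
  counts <- toy_counts(rnbinom(51 * 8, mu = 100, size = 5) + 1L, 51, 8)
  got <- compute_size_factors(counts, mode = "deseq")$s
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(got), unname(ref), tolerance = 1e-10)
})

test_that("unit-sum factors are deseq factors divided by their sum, and sum to 1", {
  set.seed(3)
  counts <- toy_counts(rpois(30 * 5, 50), 30, 5)
  sp <- compute_size_factors(counts, mode = "unit_sum")$s
  sd_ <- compute_size_factors(counts, mode = "deseq")$s
  expect_equal(sp, sd_ / sum(sd_))
  expect_equal(sum(sp), 1)
})

test_that("deseq-mode factors recover the true library-size factors", {
  study <- simulate_study(sim_config(n_genes = 1000,
                                     n_samples_per_class = c(12, 12),
                                     n_deg = 0, libsize_sigma = 0.4,
                                     seed = 9))
  sf <- compute_size_factors(study$counts, mode = "deseq")
  expect_gt(cor(sf$s, study$libsize_factors), 0.99)
})

test_that("normalization divides columns by their factors", {
  counts <- cbind(s1 = c(4L, 10L, 6L), s2 = c(8L, 20L, 12L))
  rownames(counts) <- paste0("g", 1:3)
  sf <- compute_size_factors(counts, mode = "deseq")
  q <- normalize_counts(counts, sf)
  expect_equal(q[, 1], q[, 2])               # scaled columns become equal
  expect_equal(q["g1", "s1"], 4 / (1 / sqrt(2)))
  counts0 <- rbind(counts, g4 = c(0L, 0L))
  sf0 <- compute_size_factors(counts0, mode = "deseq")
  expect_equal(unname(normalize_counts(counts0, sf0)["g4", ]), c(0, 0))
  # mismatched samples
  bad <- counts
  colnames(bad) <- c("other1", "other2")
  expect_error(normalize_counts(bad, sf), "different samples")
})

test_that("fit_vst recovers a constant dispersion and falls back on Poisson data", {
  study <- simulate_study(sim_config(n_genes = 2000,
                                     n_samples_per_class = c(100, 100),
                                     n_deg = 0, dispersion = 0.2,
                                     libsize_sigma = 0,
                                     base_mean_range = c(20, 500),
                                     seed = 4))
  params <- fit_vst(study$counts + 0)
  expect_false(params$fallback_used)
  expect_equal(params$a0, 0.2, tolerance = 0.05)
  expect_lt(params$a1, 2)

  # permutation invariance of the trend fit
  perm <- sample(nrow(study$counts))
  params_p <- fit_vst((study$counts + 0)[perm, ])
  expect_equal(params_p$a0, params$a0)

  pois <- simulate_study(sim_config(n_genes = 1500,
                                    n_samples_per_class = c(100, 100),
                                    n_deg = 0, dispersion = 0,
                                    libsize_sigma = 0, seed = 8))
  pp <- fit_vst(pois$counts + 0)
  expect_true(pp$fallback_used || pp$a0 < 0.02)
})

test_that("vst_transform matches its closed form and is strictly increasing", {
  params <- structure(list(a0 = 0.1, a1 = 1, fallback_used = FALSE),
                      class = "vst_params")
  q <- matrix(10, 1, 1)
  expect_equal(as.numeric(vst_transform(q, params)),
               log2((4 + 2 * sqrt(3)) / 0.4), tolerance = 1e-12)
  expect_equal(as.numeric(vst_transform(q, params)), 4.2219,
               tolerance = 1e-4)
  grid <- matrix(seq(0.01, 1000, length.out = 500), ncol = 1)
  for (p in list(params,
                 structure(list(a0 = 0.5, a1 = 0, fallback_used = FALSE),
                           class = "vst_params"))) {
    v <- vst_transform(grid, p)
    expect_true(all(diff(v[, 1]) > 0))
  }
  # large-q behaviour: v(q) - log2(q) approaches a constant
  big <- matrix(c(1e5, 1e6), ncol = 1)
  dev <- vst_transform(big, params)[, 1] - log2(big[, 1])
  expect_equal(dev[1], dev[2], tolerance = 1e-3)
  # fallback transform
  fb <- structure(list(a0 = NA_real_, a1 = NA_real_, fallback_used = TRUE),
                  class = "vst_params")
  expect_equal(as.numeric(vst_transform(matrix(7), fb)), log2(8))
})

test_that("VST removes the mean-variance dependence of NB counts", {
  study <- simulate_study(sim_config(n_genes = 2000,
                                     n_samples_per_class = c(60, 60),
                                     n_deg = 0, dispersion = 0.2,
                                     libsize_sigma = 0.2,
                                     base_mean_range = c(5, 500),
                                     seed = 17))
  sf <- compute_size_factors(study$counts, mode = "deseq")
  q <- normalize_counts(study$counts, sf)
  params <- fit_vst(q)
  v <- vst_transform(q, params)
  slope_pre <- coef(lm(apply(q, 1, sd) ~ rowMeans(q)))[2]
  slope_post <- coef(lm(apply(v, 1, sd) ~ rowMeans(v)))[2]
  expect_gt(abs(slope_pre), 10 * abs(slope_post))
})
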