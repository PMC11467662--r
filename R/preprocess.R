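# Preprocessing: gene filtering, median-of-ratios size factors, count
# normalization and a closed-form variance-stabilizing transformation.

#' Filter low-count and near-zero-variance genes
#'
#' Two passes. First, genes whose total count across samples is below
#' \code{min_total} are dropped. Second, among the survivors, genes with zero
#' variance are dropped, as are genes whose most-common to second-most-common
#' value frequency ratio exceeds \code{nzv_freq_ratio} while the percentage
#' of distinct values is below \code{nzv_unique_pct} (the near-zero-variance
#' rule).
#'
#' @param counts Genes x samples count matrix.
#' @param min_total Minimum row sum to keep a gene.
#' @param nzv_freq_ratio Frequency-ratio cutoff of the near-zero-variance
#'   rule.
#' @param nzv_unique_pct Percent-distinct cutoff of the near-zero-variance
#'   rule.
#' @return A list with \code{counts} (the filtered matrix) and \code{report},
#'   an object of class \code{filter_report} partitioning the input genes
#'   into \code{removed_low_count}, \code{removed_nzv} and \code{kept}.
#' @export
filter_genes <- function(counts, min_total = 10, nzv_freq_ratio = 19,
                         nzv_unique_pct = 10) {
  validate_counts(counts)
  stopifnot(min_total > 0, nzv_freq_ratio > 0, nzv_unique_pct > 0)
  gene_ids <- rownames(counts)
  low <- rowSums(counts) < min_total
  removed_low <- gene_ids[low]
  rest <- counts[!low, , drop = FALSE]

  nzv <- logical(nrow(rest))
  n <- ncol(rest)
  for (i in seq_len(nrow(rest))) {
    x <- rest[i, ]
    tab <- sort(table(x), decreasing = TRUE)
    if (length(tab) == 1L) { # constant gene: zero variance
      nzv[i] <- TRUE
      next
    }
    freq_ratio <- tab[1] / tab[2]
    unique_pct <- 100 * length(tab) / n
    nzv[i] <- freq_ratio > nzv_freq_ratio && unique_pct < nzv_unique_pct
  }
  removed_nzv <- rownames(rest)[nzv]
  kept <- rownames(rest)[!nzv]

  report <- structure(
    list(removed_low_count = removed_low, removed_nzv = removed_nzv,
         kept = kept,
         thresholds = list(min_total = min_total,
                           nzv_freq_ratio = nzv_freq_ratio,
                           nzv_unique_pct = nzv_unique_pct)),
    class = "filter_report")
  if (length(kept) == 0L) {
    cond <- simpleError("all genes removed by filtering")
    cond$report <- report
    stop(cond)
  }
  list(counts = rest[!nzv, , drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: kept %d genes (removed %d low-count, %d near-zero-variance)\n",
              length(x$kept), length(x$removed_low_count),
              length(x$removed_nzv)))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' For gene i with counts \eqn{x_{ij}}, the geometric mean across samples is
#' \eqn{G_i = (\prod_j x_{ij})^{1/n}} (zero whenever any count is zero). The
#' per-sample median ratio is
#' \eqn{m_j = \mathrm{median}_{i: G_i \ne 0}\; x_{ij} / G_i}.
#' \code{mode = "deseq"} returns the standard median-of-ratios factors
#' \eqn{s_j = m_j}; \code{mode = "unit_sum"} additionally divides each median by
#' their sum, \eqn{s_j = m_j / \sum_j m_j}, so the factors sum to one. The
#' two modes differ by a constant multiple only, which rank- and
#' relative-scale computations downstream tolerate; \code{"unit_sum"} is the
#' default.
#'
#' Medians of an even number of ratios are the arithmetic mean of the two
#' central order statistics.
#'
#' @param counts Genes x samples count matrix.
#' @param mode \code{"unit_sum"} (factors renormalized to sum 1) or
#'   \code{"deseq"} (raw median of ratios).
#' @return An object of class \code{size_factors} with fields \code{s}
#'   (per-sample factors), \code{m} (per-sample medians), \code{geo_means}
#'   (per-gene geometric means) and \code{mode}.
#' @export
#' @examples
#' m <- matrix(c(1, 2, 4, 2, 4, 8), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' compute_size_factors(m, mode = "deseq")$s
compute_size_factors <- function(counts, mode = c("unit_sum", "deseq")) {
  validate_counts(counts)
  mode <- match.arg(mode)
  # geometric mean via logs: any zero count drives G_i to 0
  log_g <- rowMeans(log(counts))
  geo_means <- exp(log_g)
  geo_means[!is.finite(log_g)] <- 0
  usable <- geo_means > 0
  if (!any(usable)) {
    stop("no gene has a non-zero geometric mean; cannot normalize")
  }
  ratios <- counts[usable, , drop = FALSE] / geo_means[usable]
  m <- apply(ratios, 2, stats::median)
  s <- switch(mode, unit_sum = m / sum(m), deseq = m)
  structure(
    list(s = s, m = m, geo_means = stats::setNames(geo_means,
                                                   rownames(counts)),
         mode = mode),
    class = "size_factors")
}

#' @export
print.size_factors <- function(x, ...) {
  cat(sprintf("size_factors (mode=%s) for %d samples; range [%.4g, %.4g]\n",
              x$mode, length(x$s), min(x$s), max(x$s)))
  invisible(x)
}

#' Normalize counts by size factors
#'
#' Divides each column by its size factor: \eqn{q_{ij} = x_{ij} / s_j}.
#'
#' @param counts Genes x samples count matrix.
#' @param sf A \code{\link{compute_size_factors}} result for the same
#'   samples.
#' @return Numeric matrix of normalized counts, same dimensions and
#'   dimnames.
#' @export
normalize_counts <- function(counts, sf) {
  validate_counts(counts)
  stopifnot(inherits(sf, "size_factors"))
  if (!identical(colnames(counts), names(sf$s))) {
    stop("size factors were computed on different samples")
  }
  sweep(counts, 2, sf$s, "/")
}

#' Fit the dispersion trend behind the variance-stabilizing transform
#'
#' Estimates a two-parameter mean-dispersion trend
#' \eqn{\phi(\mu) \approx a_0 + a_1 / \mu} by ordinary least squares on
#' per-gene method-of-moments dispersions
#' \eqn{\phi_i = \max(0, (\mathrm{var}_i - \mathrm{mean}_i)/\mathrm{mean}_i^2)},
#' using only genes with mean above 1 (moment dispersions are unstable at
#' tiny means). \code{a0} is the asymptotic dispersion at large means,
#' \code{a1} the extra-Poisson low-mean term. If the fitted \code{a0} is not
#' positive the data carry no usable overdispersion signal and
#' \code{fallback_used} is set, in which case \code{\link{vst_transform}}
#' applies \code{log2(q + 1)}. A fitted negative \code{a1} is clamped to 0.
#'
#' @param normalized Normalized count matrix (genes x samples).
#' @return Object of class \code{vst_params} with \code{a0}, \code{a1},
#'   \code{fallback_used}.
#' @export
fit_vst <- function(normalized) {
  if (!is.matrix(normalized) || !all(is.finite(normalized))) {
    stop("normalized matrix must be finite")
  }
  if (nrow(normalized) < 50) {
    warning("fewer than 50 genes; dispersion trend may be unreliable")
  }
  mu <- rowMeans(normalized)
  v <- apply(normalized, 1, stats::var)
  use <- mu > 1
  if (sum(use) < 2) stop("fewer than 2 genes with mean > 1; cannot fit trend")
  phi <- pmax(0, (v[use] - mu[use]) / mu[use]^2)
  fit <- stats::lm(phi ~ I(1 / mu[use]))
  a0 <- unname(stats::coef(fit)[1])
  a1 <- max(0, unname(stats::coef(fit)[2]))
  fallback <- !is.finite(a0) || a0 <= 0
  structure(list(a0 = if (fallback) NA_real_ else a0,
                 a1 = if (fallback) NA_real_ else a1,
                 fallback_used = fallback),
            class = "vst_params")
}

#' @export
print.vst_params <- function(x, ...) {
  if (x$fallback_used) {
    cat("vst_params: fallback log2(q + 1) (no overdispersion detected)\n")
  } else {
    cat(sprintf("vst_params: a0 = %.4g, a1 = %.4g\n", x$a0, x$a1))
  }
  invisible(x)
}

#' Variance-stabilizing transformation
#'
#' Applies the closed-form transform implied by the fitted dispersion trend
#' \eqn{\phi(\mu) = a_0 + a_1/\mu}:
#' \deqn{v(q) = \log_2\!\frac{1 + a_1 + 2 a_0 q +
#'   2\sqrt{a_0 q (1 + a_1 + a_0 q)}}{4 a_0}}
#' which is strictly increasing in \eqn{q} and behaves like
#' \eqn{\log_2 q + const} for large \eqn{q}. When the trend fit fell back
#' (no overdispersion) the transform is \eqn{\log_2(q + 1)}.
#'
#' @param normalized Normalized count matrix.
#' @param params A \code{\link{fit_vst}} result.
#' @return Transformed matrix of the same shape.
#' @export
vst_transform <- function(normalized, params) {
  stopifnot(inherits(params, "vst_params"))
  if (!all(is.finite(normalized))) stop("non-finite values in input")
  if (params$fallback_used) {
    return(log2(normalized + 1))
  }
  a0 <- params$a0
  a1 <- params$a1
  q <- normalized
  log2((1 + a1 + 2 * a0 * q +
          2 * sqrt(a0 * q * (1 + a1 + a0 * q))) / (4 * a0))
}

#' Run filtering, normalization and VST in one call
#'
#' Convenience wrapper chaining \code{\link{filter_genes}},
#' \code{\link{compute_size_factors}}, \code{\link{normalize_counts}},
#' \code{\link{fit_vst}} and \code{\link{vst_transform}}.
#'
#' @param counts Genes x samples count matrix.
#' @param sf_mode Size-factor mode, see \code{\link{compute_size_factors}}.
#' @param min_total,nzv_freq_ratio,nzv_unique_pct Filter thresholds, see
#'   \code{\link{filter_genes}}.
#' @return List with \code{vst} (transformed matrix), \code{normalized},
#'   \code{size_factors}, \code{filter_report}, \code{vst_params}.
#' @export
preprocess_counts <- function(counts, sf_mode = "unit_sum", min_total = 10,
                              nzv_freq_ratio = 19, nzv_unique_pct = 10) {
  flt <- filter_genes(counts, min_total = min_total,
                      nzv_freq_ratio = nzv_freq_ratio,
                      nzv_unique_pct = nzv_unique_pct)
  sf <- compute_size_factors(flt$counts, mode = sf_mode)
  q <- normalize_counts(flt$counts, sf)
  params <- fit_vst(q)
  list(vst = vst_transform(q, params), normalized = q, size_factors = sf,
       filter_report = flt$report, vst_params = params)
}
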