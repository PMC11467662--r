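#' Configuration for a simulated two-class RNA-seq study
#'
#' Bundles the parameters of the negative-binomial count simulator. The
#' simulator emulates the shape of a bulk RNA-seq cohort: a genes x samples
#' integer count matrix, two sample classes of configurable (possibly
#' unbalanced) size, per-sample library-size variation, and a planted set of
#' differentially expressed genes with known log2 fold changes.
#'
#' @param n_genes Number of genes (rows) to simulate.
#' @param n_samples_per_class Integer vector of length 2: samples in class 0
#'   and class 1. Both must be at least 2.
#' @param n_deg Number of planted differentially expressed genes. Half are
#'   up-regulated in class 1 by \code{2^log2fc}, half down-regulated by
#'   \code{2^-log2fc} (the extra gene of an odd count goes to the up set).
#' @param log2fc Planted effect size in log2 units (positive).
#' @param base_mean_range Length-2 positive vector; per-gene baseline means
#'   are gamma-distributed and rescaled into this range, producing the
#'   mean-variance dependence the variance-stabilizing transform must remove.
#' @param dispersion Negative-binomial dispersion phi, so that
#'   \code{variance = mu + phi * mu^2}. \code{0} gives Poisson counts.
#' @param libsize_sigma Log-normal sigma of the per-sample library-size
#'   factor; \code{0} gives equal library sizes.
#' @param seed Integer seed; identical seeds give bitwise-identical studies.
#'
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 2000,
                       n_samples_per_class = c(60, 60),
                       n_deg = 100,
                       log2fc = 2,
                       base_mean_range = c(5, 500),
                       dispersion = 0.2,
                       libsize_sigma = 0.25,
                       seed = 1L) {
  stopifnot(length(n_samples_per_class) == 2, all(n_samples_per_class >= 2))
  if (n_genes < 1) stop("n_genes must be positive")
  if (n_deg < 0 || n_deg > n_genes) {
    stop("n_deg must lie in [0, n_genes]")
  }
  if (log2fc <= 0) stop("log2fc must be positive")
  stopifnot(length(base_mean_range) == 2, all(base_mean_range > 0),
            base_mean_range[1] <= base_mean_range[2])
  if (dispersion < 0) stop("dispersion must be non-negative")
  if (libsize_sigma < 0) stop("libsize_sigma must be non-negative")
  structure(
    list(n_genes = as.integer(n_genes),
         n_samples_per_class = as.integer(n_samples_per_class),
         n_deg = as.integer(n_deg),
         log2fc = log2fc,
         base_mean_range = base_mean_range,
         dispersion = dispersion,
         libsize_sigma = libsize_sigma,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate a two-class RNA-seq count study with planted DEGs
#'
#' Draws per-gene baseline means from a rescaled gamma distribution,
#' per-sample library-size factors from a log-normal, plants \code{n_deg}
#' differential genes (half up, half down in class 1), and samples counts
#' from a negative binomial with \code{variance = mu + phi * mu^2}. With
#' \code{dispersion = 0} counts are Poisson.
#'
#' @param config A \code{\link{sim_config}} object.
#'
#' @return An object of class \code{simulated_study} with elements:
#'   \describe{
#'     \item{counts}{integer matrix, genes x samples, with gene/sample ids}
#'     \item{labels}{named integer vector of classes in \{0, 1\}}
#'     \item{truth}{data frame (gene_id, planted_log2fc), one row per
#'       planted gene}
#'     \item{libsize_factors}{named numeric vector of true per-sample
#'       library-size factors}
#'     \item{config}{the configuration used}
#'   }
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_genes = 100,
#'                                    n_samples_per_class = c(10, 10),
#'                                    n_deg = 10, seed = 7))
#' dim(study$counts)
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_genes <- config$n_genes
  n0 <- config$n_samples_per_class[1]
  n1 <- config$n_samples_per_class[2]
  n <- n0 + n1

  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  sample_ids <- sprintf("S%04d", seq_len(n))
  labels <- c(rep(0L, n0), rep(1L, n1))
  names(labels) <- sample_ids

  # baseline means: gamma draws rescaled into base_mean_range
  lo <- config$base_mean_range[1]
  hi <- config$base_mean_range[2]
  g <- stats::rgamma(n_genes, shape = 2, rate = 1)
  mu <- lo + (hi - lo) * pmin(g / stats::qgamma(0.99, shape = 2), 1)

  # library-size factors, log-normal with median 1
  ell <- exp(stats::rnorm(n, 0, config$libsize_sigma))
  names(ell) <- sample_ids

  # planted effects: half up, half down (extra gene goes up)
  fc <- rep(1, n_genes)
  truth <- data.frame(gene_id = character(0), planted_log2fc = numeric(0),
                      stringsAsFactors = FALSE)
  if (config$n_deg > 0) {
    deg_idx <- sample.int(n_genes, config$n_deg)
    n_up <- ceiling(config$n_deg / 2)
    up_idx <- deg_idx[seq_len(n_up)]
    down_idx <- setdiff(deg_idx, up_idx)
    fc[up_idx] <- 2^config$log2fc
    fc[down_idx] <- 2^(-config$log2fc)
    truth <- data.frame(
      gene_id = gene_ids[deg_idx],
      planted_log2fc = ifelse(deg_idx %in% up_idx,
                              config$log2fc, -config$log2fc),
      stringsAsFactors = FALSE)
  }

  # per-cell means: class 0 columns mu_i * ell_j, class 1 mu_i * fc_i * ell_j
  mean_mat <- outer(mu, ell)
  mean_mat[, labels == 1L] <- mean_mat[, labels == 1L] * fc

  phi <- config$dispersion
  if (phi < 1e-12) {
    counts <- matrix(stats::rpois(n_genes * n, lambda = mean_mat),
                     n_genes, n)
  } else {
    counts <- matrix(stats::rnbinom(n_genes * n, mu = mean_mat,
                                    size = 1 / phi),
                     n_genes, n)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(gene_ids, sample_ids)

  structure(
    list(counts = counts, labels = labels, truth = truth,
         libsize_factors = ell, config = config),
    class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("simulated_study: %d genes x %d samples (%d / %d per class), %d planted DEGs\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$labels == 0L), sum(x$labels == 1L), nrow(x$truth)))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Counts go to \code{counts.tsv} (genes in rows, first column \code{gene_id},
#' remaining columns one per sample), labels to \code{labels.csv}
#' (\code{sample_id,class}) and the planted-gene table to \code{truth.csv}.
#'
#' @param study A \code{simulated_study}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counts_path <- file.path(dir, "counts.tsv")
  labels_path <- file.path(dir, "labels.csv")
  truth_path <- file.path(dir, "truth.csv")
  write_counts(study$counts, counts_path)
  utils::write.csv(data.frame(sample_id = names(study$labels),
                              class = unname(study$labels)),
                   labels_path, row.names = FALSE)
  utils::write.csv(study$truth, truth_path, row.names = FALSE)
  invisible(c(counts = counts_path, labels = labels_path,
              truth = truth_path))
}
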