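# Two-stage feature reduction: a PCA loading-energy screen of genes, then
# per-gene differential-expression testing and top-n selection.

#' PCA-based gene screening
#'
#' Reduces the gene set to the \code{n_pca} genes that carry the most
#' variance-weighted loading energy. Genes are standardized across samples
#' (zero-variance genes score 0 and are never preferred), principal
#' components are computed on the samples x genes orientation, and the
#' number of components \code{C} used for scoring is the smallest count
#' whose cumulative variance explained reaches \code{var_target}, capped at
#' \code{min(n_samples - 1, 50)}. Each gene's score is
#' \eqn{\sum_{c \le C} \lambda_c \, w_{gc}^2} where \eqn{w_{gc}} is the
#' gene's loading on component c and \eqn{\lambda_c} the component's
#' eigenvalue. Ties are broken by gene id so the screen is deterministic.
#'
#' The screen keeps gene-level features (rather than replacing them with
#' components) so that downstream importance analyses still name genes.
#'
#' @param vst_matrix Genes x samples matrix of variance-stabilized values.
#' @param n_pca Number of genes to retain (all genes if larger than the
#'   input).
#' @param var_target Cumulative variance-explained target selecting the
#'   number of scoring components.
#' @return Object of class \code{pca_screen} with \code{gene_scores},
#'   \code{n_components_used}, \code{variance_explained} and
#'   \code{kept_genes} (ordered, best first).
#' @export
pca_gene_screen <- function(vst_matrix, n_pca = 2000, var_target = 0.90) {
  if (n_pca <= 0) stop("n_pca must be positive")
  if (ncol(vst_matrix) < 3) stop("need at least 3 samples")
  if (!all(is.finite(vst_matrix))) stop("vst matrix must be finite")
  gene_ids <- rownames(vst_matrix)
  n <- ncol(vst_matrix)

  x <- t(vst_matrix)                       # samples x genes
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  ok <- sdv > 0
  z <- sweep(sweep(x, 2, mu, "-"), 2, ifelse(ok, sdv, 1), "/")
  z[, !ok] <- 0

  sv <- svd(z, nu = 0)
  eig <- sv$d^2 / (n - 1)
  pos <- eig > sum(eig) * 1e-12
  eig <- eig[pos]
  loadings <- sv$v[, pos, drop = FALSE]
  var_frac <- eig / sum(eig)
  cap <- min(n - 1, 50)
  c_used <- as.integer(min(which(cumsum(var_frac) >= var_target), cap))
  if (length(c_used) == 0 || !is.finite(c_used)) c_used <- as.integer(cap)

  idx <- seq_len(c_used)
  scores <- as.vector(loadings[, idx, drop = FALSE]^2 %*% eig[idx])
  names(scores) <- gene_ids
  ord <- order(-scores, gene_ids)
  kept <- gene_ids[ord][seq_len(min(n_pca, length(gene_ids)))]

  structure(
    list(gene_scores = scores, n_components_used = c_used,
         variance_explained = var_frac, kept_genes = kept),
    class = "pca_screen")
}

#' @export
print.pca_screen <- function(x, ...) {
  cat(sprintf("pca_screen: kept %d of %d genes using %d components (%.1f%% variance)\n",
              length(x$kept_genes), length(x$gene_scores),
              x$n_components_used,
              100 * sum(x$variance_explained[seq_len(x$n_components_used)])))
  invisible(x)
}

#' Per-gene differential-expression testing
#'
#' Welch's two-sample t test on the variance-stabilized values of each gene,
#' two-sided p from the t distribution with Welch-Satterthwaite degrees of
#' freedom. The log2 fold change is the mean VST difference
#' class 1 - class 0 (VST values live on a log2-like scale). P values are
#' Benjamini-Hochberg adjusted; genes are ranked by ascending p, ties by
#' descending |log2fc| and then gene id.
#'
#' Degenerate genes (zero within-group variance in both classes) get t = 0
#' and p = 1 when the means agree and p = 0 otherwise.
#'
#' @param vst_matrix Genes x samples matrix.
#' @param labels Two-class vector aligned with the matrix columns.
#' @return A \code{data.frame} of class \code{deg_table} with columns
#'   \code{gene_id}, \code{log2fc}, \code{t_stat}, \code{p_value},
#'   \code{p_adj}, \code{rank}, sorted by rank.
#' @export
de_test <- function(vst_matrix, labels) {
  if (length(labels) != ncol(vst_matrix)) {
    stop("labels must align with matrix columns")
  }
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2) stop("labels must have exactly two classes")
  g0 <- as.character(labels) == lev[1]
  g1 <- !g0
  if (sum(g0) < 2 || sum(g1) < 2) stop("each class needs at least 2 samples")

  n0 <- sum(g0); n1 <- sum(g1)
  m0 <- rowMeans(vst_matrix[, g0, drop = FALSE])
  m1 <- rowMeans(vst_matrix[, g1, drop = FALSE])
  v0 <- apply(vst_matrix[, g0, drop = FALSE], 1, stats::var)
  v1 <- apply(vst_matrix[, g1, drop = FALSE], 1, stats::var)

  se2 <- v0 / n0 + v1 / n1
  lfc <- m1 - m0
  t_stat <- ifelse(se2 > 0, lfc / sqrt(se2), ifelse(lfc == 0, 0, Inf * sign(lfc)))
  df <- ifelse(se2 > 0,
               se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1)),
               1)
  p <- ifelse(is.finite(t_stat), 2 * stats::pt(-abs(t_stat), df),
              0)
  p[t_stat == 0 & se2 == 0] <- 1
  p_adj <- stats::p.adjust(p, method = "BH")

  gene_ids <- rownames(vst_matrix)
  ord <- order(p, -abs(lfc), gene_ids)
  rank <- integer(length(p))
  rank[ord] <- seq_along(ord)

  out <- data.frame(gene_id = gene_ids, log2fc = lfc, t_stat = t_stat,
                    p_value = p, p_adj = p_adj, rank = rank,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Select the top differentially expressed genes
#'
#' @param table A \code{\link{de_test}} result.
#' @param n_deg Number of genes to select (must not exceed the table size).
#' @return Character vector of the first \code{n_deg} gene ids by rank.
#' @export
select_top_degs <- function(table, n_deg = 200) {
  stopifnot(inherits(table, "deg_table"))
  if (n_deg > nrow(table)) {
    stop(sprintf("n_deg (%d) exceeds table size (%d)", n_deg, nrow(table)))
  }
  table$gene_id[order(table$rank)][seq_len(n_deg)]
}
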