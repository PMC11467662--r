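# Volcano classification of genes and the consensus-vs-gray-zone check.

#' Classify genes for a volcano plot
#'
#' Each gene falls in exactly one category: \code{significant} when
#' \code{p < p_cut} and \code{|log2fc| >= fc_cut} (the boundary fold change
#' counts as significant), \code{non_significant} when \code{p < p_cut} but
#' the fold change is small, and \code{unregulated} (the gray zone) when
#' \code{p >= p_cut}.
#'
#' @param deg_table A \code{\link{de_test}} result.
#' @param fc_cut Absolute log2 fold-change threshold.
#' @param p_cut P-value threshold.
#' @param use_adjusted Threshold the BH-adjusted p instead of the raw p.
#' @param consensus Optional \code{consensus_set}; its features are flagged
#'   in the output.
#' @return Data frame of class \code{volcano_table} with columns
#'   \code{gene_id}, \code{log2fc}, \code{p_value}, \code{neg_log10_p}
#'   (p floored at 1e-300), \code{category}, \code{is_consensus}.
#' @export
volcano_classify <- function(deg_table, fc_cut = 1, p_cut = 0.05,
                             use_adjusted = FALSE, consensus = NULL) {
  stopifnot(inherits(deg_table, "deg_table"), fc_cut > 0, p_cut > 0)
  p <- if (use_adjusted) deg_table$p_adj else deg_table$p_value
  category <- ifelse(p >= p_cut, "unregulated",
                     ifelse(abs(deg_table$log2fc) >= fc_cut,
                            "significant", "non_significant"))
  consensus_feats <- character(0)
  if (!is.null(consensus)) {
    stopifnot(inherits(consensus, "consensus_set"))
    consensus_feats <- consensus$features$feature
  }
  out <- data.frame(
    gene_id = deg_table$gene_id,
    log2fc = deg_table$log2fc,
    p_value = p,
    neg_log10_p = -log10(pmax(p, 1e-300)),
    category = category,
    is_consensus = deg_table$gene_id %in% consensus_feats,
    stringsAsFactors = FALSE)
  class(out) <- c("volcano_table", "data.frame")
  out
}

#' Check that no consensus feature sits in the volcano gray zone
#'
#' Influential features ought to be differentially expressed; a consensus
#' feature classified \code{unregulated} signals a selection artifact.
#'
#' @param records A \code{\link{volcano_classify}} result.
#' @param consensus A \code{consensus_set}.
#' @return List with \code{violations} (consensus features in the gray
#'   zone, empty when the property holds) and \code{ok}.
#' @export
check_consensus_not_gray <- function(records, consensus) {
  stopifnot(inherits(records, "volcano_table"),
            inherits(consensus, "consensus_set"))
  feats <- consensus$features$feature
  unknown <- setdiff(feats, records$gene_id)
  if (length(unknown)) {
    stop(sprintf("consensus features not in volcano records: %s",
                 paste(unknown, collapse = ", ")))
  }
  gray <- records$gene_id[records$category == "unregulated"]
  violations <- intersect(feats, gray)
  list(violations = violations, ok = length(violations) == 0)
}
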