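# Plain-text readers/writers shared by the command-line interface and the
# pipeline. Counts travel as TSV with genes in rows; labels as two-column CSV.

#' Read a genes x samples count matrix from TSV
#'
#' The file must have a header row of sample ids and gene ids in the first
#' column. Values must be non-negative.
#'
#' @param path Path to a tab-separated file.
#' @return An integer matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- gene_ids
  validate_counts(m)
  m
}

#' Write a count or expression matrix as TSV
#'
#' @param m Matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param id_col Name of the leading id column.
#' @return Invisibly, \code{path}.
#' @export
write_counts <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample label table
#'
#' Expects a CSV with columns \code{sample_id} and \code{class}.
#'
#' @param path Path to the CSV file.
#' @return A named vector of classes, names are sample ids.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "class") %in% names(df))) {
    stop("label file must have columns 'sample_id' and 'class'")
  }
  stats::setNames(df$class, df$sample_id)
}

#' Restrict a cohort to selected classes
#'
#' Drops samples whose class is listed in \code{drop} (or keeps only those
#' in \code{keep}). Used to reduce a multi-subtype cohort to a two-class
#' contrast before classification, e.g. dropping a small third subtype.
#'
#' @param labels Named class vector (names are sample ids).
#' @param keep Classes to retain (default: all not dropped).
#' @param drop Classes to remove.
#' @return The filtered named label vector.
#' @export
subset_cohort <- function(labels, keep = NULL, drop = NULL) {
  cls <- as.character(labels)
  sel <- rep(TRUE, length(labels))
  if (!is.null(drop)) sel <- sel & !(cls %in% drop)
  if (!is.null(keep)) sel <- sel & cls %in% keep
  labels[sel]
}

# shared validation for count matrices
validate_counts <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("gene ids must be unique")
  if (anyDuplicated(colnames(counts))) stop("sample ids must be unique")
  if (ncol(counts) < 2) stop("need at least 2 samples")
  if (any(counts < 0)) stop("counts must be non-negative")
  invisible(counts)
}
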