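# MixUp augmentation for tabular features: synthetic samples are convex
# combinations x~ = lambda * x_i + (1 - lambda) * x_j of two real samples,
# lambda ~ Beta(alpha, alpha). Pairing is within class, so synthetic labels
# equal both parents' label exactly.

#' MixUp configuration
#'
#' @param alpha Positive Beta(alpha, alpha) concentration controlling the
#'   mixing intensity; small values push lambda towards 0 or 1 (synthetic
#'   rows close to one parent), alpha = 1 mixes uniformly.
#' @param mode \code{"full_double"} doubles the dataset with within-class
#'   synthetic rows drawn proportionally to class frequencies;
#'   \code{"minority_only"} synthesizes minority-class rows until the class
#'   counts are equal.
#' @param seed Integer seed; augmentation is deterministic under it.
#' @return Object of class \code{mixup_config}.
#' @export
mixup_config <- function(alpha = 0.2, mode = c("full_double", "minority_only"),
                         seed = 1L) {
  if (alpha <= 0) stop("alpha must be positive")
  mode <- match.arg(mode)
  structure(list(alpha = alpha, mode = mode, pairing = "within_class",
                 seed = as.integer(seed)),
            class = "mixup_config")
}

#' Draw MixUp mixing coefficients
#'
#' @param config A \code{\link{mixup_config}}.
#' @param n Number of draws.
#' @return \code{n} values of lambda ~ Beta(alpha, alpha), reproducible
#'   under the config seed.
#' @export
sample_lambda <- function(config, n = 1) {
  stopifnot(inherits(config, "mixup_config"))
  set.seed(config$seed)
  stats::rbeta(n, config$alpha, config$alpha)
}

#' Mix one pair of samples
#'
#' \eqn{\tilde x = \lambda x_i + (1-\lambda) x_j},
#' \eqn{\tilde y = \lambda y_i + (1-\lambda) y_j}. With within-class pairing
#' \eqn{y_i = y_j} and the mixed label equals both parents' label exactly.
#'
#' @param xi,xj Feature vectors of equal length.
#' @param yi,yj Numeric labels.
#' @param lam Mixing coefficient in [0, 1].
#' @return List with \code{x} (mixed features) and \code{y} (mixed label).
#' @export
mixup_pair <- function(xi, xj, yi, yj, lam) {
  if (length(xi) != length(xj)) stop("feature vectors differ in length")
  if (lam < 0 || lam > 1) stop("lam must lie in [0, 1]")
  list(x = lam * xi + (1 - lam) * xj, y = lam * yi + (1 - lam) * yj)
}

#' Augment a dataset with MixUp rows
#'
#' Original rows are kept unchanged and synthetic rows appended. In
#' \code{minority_only} mode pairs are sampled (with replacement, i != j)
#' from the minority class until the class counts are equal. In
#' \code{full_double} mode exactly \code{nrow(features)} synthetic rows are
#' generated, each from a class drawn with probability proportional to the
#' class frequencies, so the output has twice the input rows. Pairing is
#' always within class.
#'
#' @param features Samples x features numeric matrix.
#' @param labels Two-class vector aligned with rows.
#' @param config A \code{\link{mixup_config}}.
#' @return Object of class \code{augmented_dataset}: \code{features}
#'   (original rows then synthetic rows), \code{labels}, and
#'   \code{provenance}, a data frame with one row per synthetic sample
#'   (\code{row_id}, \code{src_i}, \code{src_j}, \code{lambda}).
#' @export
#' @examples
#' x <- matrix(rnorm(40), 10, 4,
#'             dimnames = list(paste0("s", 1:10), paste0("f", 1:4)))
#' y <- rep(c("a", "b"), each = 5)
#' aug <- mixup_augment(x, y, mixup_config(mode = "full_double", seed = 3))
#' nrow(aug$features)  # 20
mixup_augment <- function(features, labels, config) {
  stopifnot(inherits(config, "mixup_config"))
  features <- as.matrix(features)
  if (nrow(features) != length(labels)) {
    stop("labels must align with feature rows")
  }
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2) stop("need exactly two classes")
  counts <- table(factor(as.character(labels), levels = classes))
  if (any(counts < 2)) stop("each class needs at least 2 samples")
  n <- nrow(features)
  if (is.null(rownames(features))) {
    rownames(features) <- paste0("s", seq_len(n))
  }

  set.seed(config$seed)
  if (config$mode == "minority_only") {
    minority <- classes[which.min(counts)]
    n_new <- as.integer(max(counts) - min(counts))
    new_classes <- rep(minority, n_new)
  } else {
    n_new <- n
    new_classes <- sample(classes, n_new, replace = TRUE,
                          prob = as.numeric(counts) / n)
  }

  if (n_new == 0L) {
    prov <- data.frame(row_id = character(0), src_i = character(0),
                       src_j = character(0), lambda = numeric(0),
                       stringsAsFactors = FALSE)
    return(structure(list(features = features, labels = labels,
                          provenance = prov),
                     class = "augmented_dataset"))
  }

  lam <- stats::rbeta(n_new, config$alpha, config$alpha)
  synth <- matrix(NA_real_, n_new, ncol(features),
                  dimnames = list(paste0("mix_", seq_len(n_new)),
                                  colnames(features)))
  src_i <- character(n_new)
  src_j <- character(n_new)
  for (r in seq_len(n_new)) {
    pool <- which(as.character(labels) == new_classes[r])
    pair <- sample(pool, 2, replace = FALSE)
    mixed <- mixup_pair(features[pair[1], ], features[pair[2], ],
                        1, 1, lam[r])
    synth[r, ] <- mixed$x
    src_i[r] <- rownames(features)[pair[1]]
    src_j[r] <- rownames(features)[pair[2]]
  }

  out_labels <- c(as.character(labels), new_classes)
  if (is.numeric(labels)) out_labels <- as.numeric(out_labels)
  prov <- data.frame(row_id = rownames(synth), src_i = src_i, src_j = src_j,
                     lambda = lam, stringsAsFactors = FALSE)
  structure(
    list(features = rbind(features, synth), labels = out_labels,
         provenance = prov),
    class = "augmented_dataset")
}

#' @export
print.augmented_dataset <- function(x, ...) {
  cat(sprintf("augmented_dataset: %d rows (%d synthetic) x %d features\n",
              nrow(x$features), nrow(x$provenance), ncol(x$features)))
  invisible(x)
}
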