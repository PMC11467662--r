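# A small fully-connected autoencoder trained by minibatch Adam on the
# mean-squared reconstruction error. Hidden layers use the rectifier, the
# output layer is linear, and the decoder mirrors the encoder. Implemented
# with base matrix algebra; the layer widths involved (hundreds of units)
# need no specialised backend.

#' Autoencoder architecture and training specification
#'
#' The encoder maps \code{input_dim -> encoder_dims ... -> bottleneck_dim};
#' the decoder mirrors the encoder back to \code{input_dim}. Defaults follow
#' the 200 -> 128 -> 72 -> 128 -> 200 architecture used for compressing the
#' 200 selected genes to 72 latent features.
#'
#' @param input_dim Number of input features.
#' @param encoder_dims Integer vector of encoder hidden-layer widths.
#' @param bottleneck_dim Width of the latent layer (must be below
#'   \code{input_dim}).
#' @param activation Hidden activation; only \code{"relu"} is provided.
#' @param epochs,batch_size,learning_rate Training scalars for minibatch
#'   Adam.
#' @param seed Integer seed controlling weight initialization and batch
#'   shuffling.
#' @return Object of class \code{autoencoder_spec}.
#' @export
autoencoder_spec <- function(input_dim = 200, encoder_dims = 128,
                             bottleneck_dim = 72, activation = "relu",
                             epochs = 200, batch_size = 32,
                             learning_rate = 1e-3, seed = 1L) {
  stopifnot(input_dim >= 1, bottleneck_dim >= 1, all(encoder_dims >= 1))
  if (bottleneck_dim >= input_dim) {
    stop("bottleneck_dim must be smaller than input_dim")
  }
  if (activation != "relu") stop("only the rectifier activation is provided")
  structure(
    list(input_dim = as.integer(input_dim),
         encoder_dims = as.integer(encoder_dims),
         bottleneck_dim = as.integer(bottleneck_dim),
         activation = activation,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, seed = as.integer(seed)),
    class = "autoencoder_spec")
}

relu <- function(x) pmax(x, 0)

ae_layer_dims <- function(spec) {
  c(spec$input_dim, spec$encoder_dims, spec$bottleneck_dim,
    rev(spec$encoder_dims), spec$input_dim)
}

ae_init_weights <- function(spec) {
  dims <- ae_layer_dims(spec)
  w <- vector("list", length(dims) - 1)
  b <- vector("list", length(dims) - 1)
  for (l in seq_along(w)) {
    # He initialization for rectifier layers
    w[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1],
                                  sd = sqrt(2 / dims[l])),
                     dims[l], dims[l + 1])
    b[[l]] <- rep(0, dims[l + 1])
  }
  list(w = w, b = b)
}

# forward pass; returns activations per layer (a[[1]] is the input)
ae_forward <- function(params, x) {
  n_layers <- length(params$w)
  a <- vector("list", n_layers + 1)
  a[[1]] <- x
  for (l in seq_len(n_layers)) {
    pre <- a[[l]] %*% params$w[[l]] +
      matrix(params$b[[l]], nrow(x), length(params$b[[l]]), byrow = TRUE)
    a[[l + 1]] <- if (l < n_layers) relu(pre) else pre  # linear output
  }
  a
}

#' Fit an autoencoder on a training matrix
#'
#' Inputs are standardized per feature (mean/sd estimated from the training
#' data only; constant features get unit scale) and the network is trained
#' to minimize the mean-squared reconstruction error in standardized units
#' by minibatch Adam. Training is reproducible under \code{spec$seed}. With
#' \code{epochs = 0} the model keeps its random initial weights, which is
#' useful for before/after-training comparisons.
#'
#' @param train Samples x features numeric matrix; the feature count must
#'   equal \code{spec$input_dim}.
#' @param spec An \code{\link{autoencoder_spec}}.
#' @return Object of class \code{autoencoder} with the fitted weights, the
#'   training scaler, the spec and the per-epoch loss history.
#' @export
fit_autoencoder <- function(train, spec) {
  stopifnot(inherits(spec, "autoencoder_spec"))
  train <- as.matrix(train)
  if (ncol(train) != spec$input_dim) {
    stop(sprintf("training data has %d features, spec expects %d",
                 ncol(train), spec$input_dim))
  }
  set.seed(spec$seed)
  center <- colMeans(train)
  scale_ <- apply(train, 2, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  x <- sweep(sweep(train, 2, center, "-"), 2, scale_, "/")

  params <- ae_init_weights(spec)
  n_layers <- length(params$w)
  n <- nrow(x)
  lr <- spec$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  m_w <- lapply(params$w, function(w) w * 0)
  v_w <- m_w
  m_b <- lapply(params$b, function(b) b * 0)
  v_b <- m_b
  t_step <- 0
  loss_history <- numeric(spec$epochs)

  for (epoch in seq_len(spec$epochs)) {
    idx <- sample.int(n)
    batch_starts <- seq(1, n, by = spec$batch_size)
    epoch_loss <- 0
    for (s in batch_starts) {
      rows <- idx[s:min(s + spec$batch_size - 1, n)]
      xb <- x[rows, , drop = FALSE]
      nb <- nrow(xb)
      a <- ae_forward(params, xb)
      err <- a[[n_layers + 1]] - xb
      epoch_loss <- epoch_loss + sum(err^2)

      # backprop of mean-squared error
      delta <- 2 * err / (nb * ncol(xb))
      t_step <- t_step + 1
      for (l in rev(seq_len(n_layers))) {
        gw <- crossprod(a[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(params$w[[l]])) * (a[[l]] > 0)
        }
        m_w[[l]] <- beta1 * m_w[[l]] + (1 - beta1) * gw
        v_w[[l]] <- beta2 * v_w[[l]] + (1 - beta2) * gw^2
        m_b[[l]] <- beta1 * m_b[[l]] + (1 - beta1) * gb
        v_b[[l]] <- beta2 * v_b[[l]] + (1 - beta2) * gb^2
        mhat_w <- m_w[[l]] / (1 - beta1^t_step)
        vhat_w <- v_w[[l]] / (1 - beta2^t_step)
        mhat_b <- m_b[[l]] / (1 - beta1^t_step)
        vhat_b <- v_b[[l]] / (1 - beta2^t_step)
        params$w[[l]] <- params$w[[l]] - lr * mhat_w / (sqrt(vhat_w) + eps)
        params$b[[l]] <- params$b[[l]] - lr * mhat_b / (sqrt(vhat_b) + eps)
      }
    }
    loss_history[epoch] <- epoch_loss / (n * ncol(x))
  }

  structure(
    list(params = params, spec = spec,
         scaler = list(center = center, scale = scale_),
         loss_history = loss_history,
         feature_names = colnames(train)),
    class = "autoencoder")
}

#' @export
print.autoencoder <- function(x, ...) {
  dims <- ae_layer_dims(x$spec)
  cat(sprintf("autoencoder %s; final training MSE %s\n",
              paste(dims, collapse = " -> "),
              if (length(x$loss_history)) {
                sprintf("%.4g", utils::tail(x$loss_history, 1))
              } else "(untrained)"))
  invisible(x)
}

ae_standardize <- function(model, data) {
  data <- as.matrix(data)
  if (ncol(data) != model$spec$input_dim) {
    stop("data feature count does not match the fitted model")
  }
  sweep(sweep(data, 2, model$scaler$center, "-"), 2, model$scaler$scale, "/")
}

#' Encode samples into the latent space
#'
#' Applies the training scaler and the encoder half of a fitted autoencoder.
#'
#' @param model A fitted \code{\link{fit_autoencoder}} object.
#' @param data Samples x features matrix with the model's input width.
#' @return Samples x bottleneck_dim matrix of latent features, rownames
#'   preserved, columns named \code{Z1..}.
#' @export
encode <- function(model, data) {
  stopifnot(inherits(model, "autoencoder"))
  x <- ae_standardize(model, data)
  a <- ae_forward(model$params, x)
  z <- a[[length(model$spec$encoder_dims) + 2]]
  colnames(z) <- paste0("Z", seq_len(ncol(z)))
  rownames(z) <- rownames(data)
  z
}

#' Per-sample reconstruction errors
#'
#' Reconstruction error is the mean squared difference between the
#' standardized input and its reconstruction. Samples are ranked ascending,
#' so the best-represented samples come first.
#'
#' @param model A fitted autoencoder.
#' @param data Samples x features matrix.
#' @return Object of class \code{recon_report} with \code{errors} (named,
#'   per sample) and \code{ranking} (sample ids, ascending error).
#' @export
reconstruction_errors <- function(model, data) {
  stopifnot(inherits(model, "autoencoder"))
  x <- ae_standardize(model, data)
  a <- ae_forward(model$params, x)
  recon <- a[[length(a)]]
  errors <- rowMeans((recon - x)^2)
  ids <- rownames(data)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  names(errors) <- ids
  structure(list(errors = errors, ranking = ids[order(errors, ids)]),
            class = "recon_report")
}

#' Best-reconstructed samples
#'
#' @param report A \code{\link{reconstruction_errors}} result.
#' @param k Number of sample ids to return.
#' @return The \code{k} sample ids with the lowest reconstruction error.
#' @export
top_k <- function(report, k) {
  stopifnot(inherits(report, "recon_report"), k >= 1)
  utils::head(report$ranking, k)
}
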