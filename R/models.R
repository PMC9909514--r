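#' CNN architecture description
#'
#' Four convolution blocks (3x3 kernels; 16, 32, 64, 32 channels; ReLU; 2x2
#' max-pooling), a flatten, dense layers of 128 and 64 units with dropout
#' 0.5 between them, and a single sigmoid output unit. Two pooling-stride
#' interpretations are provided: `"both_halve"` (stride 2 on both axes, the
#' default) and `"literal_1x2"` (stride 1 on the mel axis, 2 on time).
#'
#' @param input_mels,input_frames input patch size
#' @param conv_channels channels of the four convolution blocks
#' @param kernel square kernel size
#' @param stride_mode pooling stride interpretation
#' @param dense hidden dense layer sizes
#' @param dropout dropout probability between dense layers
#' @return a `cnn_architecture` list
#' @export
cnn_architecture <- function(input_mels = 64, input_frames = 200,
                             conv_channels = c(16, 32, 64, 32), kernel = 3,
                             stride_mode = c("both_halve", "literal_1x2"),
                             dense = c(128, 64), dropout = 0.5) {
  stride_mode <- match.arg(stride_mode)
  stopifnot(dropout >= 0, dropout <= 1, length(conv_channels) >= 1)
  pool_stride <- if (stride_mode == "both_halve") c(2L, 2L) else c(1L, 2L)
  structure(list(input_mels = as.integer(input_mels),
                 input_frames = as.integer(input_frames),
                 conv_channels = as.integer(conv_channels),
                 kernel = as.integer(kernel),
                 stride_mode = stride_mode,
                 pool_stride = pool_stride,
                 dense = as.integer(dense), dropout = dropout),
            class = "cnn_architecture")
}

#' Training protocol configuration
#'
#' @param epochs maximum training epochs
#' @param batch_size minibatch size
#' @param learning_rate Adam learning rate
#' @param patience early-stopping patience on validation accuracy
#' @param seed integer seed (weights, shuffling, dropout)
#' @return a `train_config` list
#' @export
train_config <- function(epochs = 20, batch_size = 32, learning_rate = 1e-3,
                         patience = 5, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

# spatial size after pooling with window 2 and the given stride
pooled_dims <- function(arch) {
  h <- arch$input_mels; w <- arch$input_frames
  for (i in seq_along(arch$conv_channels)) {
    h <- (h - 2) %/% arch$pool_stride[1] + 1L
    w <- (w - 2) %/% arch$pool_stride[2] + 1L
    if (h < 1 || w < 1)
      stop("invalid architecture: pooled feature map collapses below 1x1")
  }
  c(h, w)
}

#' Build (initialize) the CNN
#'
#' @param arch a [cnn_architecture()]
#' @param seed integer seed for the He-normal weight initialization
#' @return a `cnn_model` handle with introspectable `weights`, `arch`,
#'   `n_params` and a `layers` summary table
#' @export
build_cnn <- function(arch = cnn_architecture(), seed = 1L) {
  pooled_dims(arch)  # validates
  weights <- cpp_cnn_init(unclass(arch), as.integer(seed))
  model <- structure(list(arch = arch, weights = weights, trained = FALSE),
                     class = "cnn_model")
  model
}

#' Number of trainable parameters of a CNN
#' @param model a `cnn_model`
#' @return integer parameter count
#' @export
n_params <- function(model) {
  sum(vapply(model$weights$W, length, numeric(1))) +
    sum(vapply(model$weights$b, length, numeric(1)))
}

#' @export
print.cnn_model <- function(x, ...) {
  d <- pooled_dims(x$arch)
  cat(sprintf("<cnn_model> %dx%d input, blocks [%s], pool stride (%d,%d), ",
              x$arch$input_mels, x$arch$input_frames,
              paste(x$arch$conv_channels, collapse = ","),
              x$arch$pool_stride[1], x$arch$pool_stride[2]))
  cat(sprintf("flatten %d, dense [%s], %s params, %s\n",
              d[1] * d[2] * tail(x$arch$conv_channels, 1),
              paste(x$arch$dense, collapse = ","),
              format(n_params(x), big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# stack a list of segments into the (H*W) x N column matrix the C++ side
# expects, applying per-segment z-scoring
segments_to_matrix <- function(segments, standardize = TRUE) {
  X <- vapply(segments, function(s) {
    v <- as.numeric(s)
    if (standardize) {
      mu <- mean(v); sdv <- sd(v)
      if (sdv > 0) v <- (v - mu) / sdv else v <- v - mu
    }
    v
  }, numeric(length(segments[[1]])))
  matrix(X, ncol = length(segments))
}

segment_labels <- function(segments) {
  vapply(segments, function(s) as.numeric(attr(s, "label")), numeric(1))
}

#' Train the CNN on labelled segments
#'
#' Binary cross-entropy loss, Adam, early stopping on validation accuracy
#' with best-weight restoration. Inputs are z-scored per segment (the same
#' standardization is applied at inference by [predict_segments()]).
#'
#' @param model a `cnn_model` from [build_cnn()]
#' @param train_segments,val_segments lists of `logmel_segment`s carrying a
#'   `label` attribute (1 = MDD, 0 = HC), or plain matrices with `labels`
#'   supplied
#' @param config a [train_config()]
#' @param train_labels,val_labels optional explicit 0/1 label vectors
#' @param verbose print per-epoch progress
#' @return the trained `cnn_model`; `$history` holds per-epoch train/val
#'   loss and accuracy
#' @export
train_cnn <- function(model, train_segments, val_segments,
                      config = train_config(), train_labels = NULL,
                      val_labels = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"))
  ytr <- train_labels %||% segment_labels(train_segments)
  yva <- val_labels %||% segment_labels(val_segments)
  if (length(unique(ytr)) < 2)
    stop("invalid input: training data must contain both classes")
  Xtr <- segments_to_matrix(train_segments)
  Xva <- segments_to_matrix(val_segments)
  fit <- cpp_cnn_train(model$weights, unclass(model$arch), Xtr, ytr, Xva, yva,
                       config$epochs, config$batch_size,
                       config$learning_rate, config$patience,
                       config$seed, verbose)
  model$weights <- fit$weights
  model$history <- as.data.frame(fit$history)
  model$best_epoch <- fit$best_epoch
  model$trained <- TRUE
  model
}

#' Predict segment-level probabilities
#'
#' Deterministic at inference (dropout inactive); order preserving.
#'
#' @param model a `cnn_model`
#' @param segments list of segments (same shape as the training input)
#' @return numeric vector of MDD probabilities, one per segment
#' @export
predict_segments <- function(model, segments) {
  stopifnot(inherits(model, "cnn_model"))
  if (length(segments) == 0) return(numeric(0))
  dims <- vapply(segments, dim, integer(2))
  if (any(dims[1, ] != model$arch$input_mels) ||
      any(dims[2, ] != model$arch$input_frames))
    stop("invalid input: segment shape does not match the model input")
  X <- segments_to_matrix(segments)
  as.numeric(cpp_cnn_predict(model$weights, unclass(model$arch), X))
}

#' @importFrom utils tail
NULL

#' Serialize a CNN to a run directory
#'
#' Writes the architecture as JSON, the weights as a JSON container, and
#' the training history (if any) as CSV — all plain text, so checkpoints
#' survive tooling that strips binary artifacts.
#'
#' @param model a `cnn_model`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
save_cnn <- function(model, dir) {
  stopifnot(inherits(model, "cnn_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(model$arch),
                       file.path(dir, "architecture.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(model$weights, file.path(dir, "weights.json"),
                       digits = NA)
  if (!is.null(model$history))
    write.csv(model$history, file.path(dir, "history.csv"),
              row.names = FALSE)
  invisible(dir)
}

#' Restore a CNN from a run directory written by [save_cnn()]
#'
#' @param dir checkpoint directory
#' @return a `cnn_model`
#' @export
load_cnn <- function(dir) {
  arch_raw <- jsonlite::read_json(file.path(dir, "architecture.json"),
                                  simplifyVector = TRUE)
  arch <- cnn_architecture(
    input_mels = arch_raw$input_mels, input_frames = arch_raw$input_frames,
    conv_channels = arch_raw$conv_channels, kernel = arch_raw$kernel,
    stride_mode = arch_raw$stride_mode, dense = arch_raw$dense,
    dropout = arch_raw$dropout)
  w <- jsonlite::read_json(file.path(dir, "weights.json"),
                           simplifyVector = TRUE)
  weights <- list(W = lapply(w$W, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  }), b = lapply(w$b, as.numeric))
  model <- structure(list(arch = arch, weights = weights, trained = TRUE),
                     class = "cnn_model")
  hist_path <- file.path(dir, "history.csv")
  if (file.exists(hist_path)) model$history <- read.csv(hist_path)
  model
}
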