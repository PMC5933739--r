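#' Network configuration
#'
#' Configuration of the two-convolution-layer recognition network. The
#' first convolution applies 20 kernels and the second 50; kernel sizes
#' scale with the input so the convolution ratio is fixed: 13x13 / 7x7 for
#' 72x72 inputs, 9x9 / 5x5 for 48x48 and 5x5 / 3x3 for 24x24. Convolutions
#' are unpadded, each followed by ReLU and max-pool downsampling (window 2,
#' stride 2 by default). The classifier head is a 500-node fully connected
#' layer with dropout and a softmax output over 2, 3 or 6 classes, trained
#' with cross-entropy and Adam for 50 passes over the training data.
#'
#' `pool_stride = 1` with `pool_same = TRUE` selects a size-preserving
#' stride-1 pooling variant; the default halving pooling is what the
#' derived layer sizes assume.
#'
#' @param image_size input side, one of 72, 48, 24.
#' @param n_classes 2, 3 or 6.
#' @param epochs optimization passes over the training data.
#' @param batch_size minibatch size.
#' @param dropout dropout rate on the hidden fully connected layer.
#' @param learning_rate,beta1,beta2,adam_epsilon Adam settings.
#' @param pool_window,pool_stride,pool_same pooling geometry.
#' @param seed seed for weight initialization, shuffling and dropout.
#' @return an object of class `cnn_config`.
#' @examples
#' cnn_config(image_size = 48, n_classes = 2)
#' @export
cnn_config <- function(image_size = 48, n_classes = 2, epochs = 50,
                       batch_size = 32, dropout = 0.5, learning_rate = 1e-3,
                       beta1 = 0.9, beta2 = 0.999, adam_epsilon = 1e-8,
                       pool_window = 2, pool_stride = 2, pool_same = FALSE,
                       seed = 1) {
  kernels <- list(`72` = c(13L, 7L), `48` = c(9L, 5L), `24` = c(5L, 3L))
  key <- as.character(image_size)
  if (!key %in% names(kernels)) abort("image_size must be one of 72, 48, 24")
  if (!n_classes %in% c(2, 3, 6)) abort("n_classes must be 2, 3 or 6")
  if (dropout < 0 || dropout >= 1) abort("dropout must be in [0, 1)")
  structure(
    list(image_size = as.integer(image_size),
         kernel1 = kernels[[key]][1], n_kernels1 = 20L,
         kernel2 = kernels[[key]][2], n_kernels2 = 50L,
         fc_width = 500L, n_classes = as.integer(n_classes),
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         dropout = dropout, learning_rate = learning_rate,
         beta1 = beta1, beta2 = beta2, adam_epsilon = adam_epsilon,
         pool_window = as.integer(pool_window),
         pool_stride = as.integer(pool_stride),
         pool_same = isTRUE(pool_same),
         seed = as.integer(seed)),
    class = "cnn_config"
  )
}

.check_config <- function(config) {
  if (!inherits(config, "cnn_config")) abort("config must be a cnn_config")
  invisible(config)
}

.pool_out <- function(o, config) {
  if (config$pool_same) o else (o - config$pool_window) %/% config$pool_stride + 1
}

#' Layer-by-layer output shapes
#'
#' Closed-form shape arithmetic of the network for a given configuration:
#' each unpadded convolution shrinks the map by `kernel - 1`, each pooling
#' stage applies its window/stride geometry, and the flattened map feeds
#' the 500-node hidden layer and the class output.
#'
#' @param config a [cnn_config()].
#' @return a tibble with columns `stage`, `height`, `width`, `channels`,
#'   `units` (total values per item at that stage).
#' @examples
#' layer_shapes(cnn_config(image_size = 48, n_classes = 6))
#' @export
layer_shapes <- function(config) {
  .check_config(config)
  H <- config$image_size
  o1 <- H - config$kernel1 + 1
  if (o1 < 1) abort("conv1 output would be empty")
  p1 <- .pool_out(o1, config)
  if (p1 < 1) abort("pool1 output would be empty")
  o2 <- p1 - config$kernel2 + 1
  if (o2 < 1) abort("conv2 output would be empty")
  p2 <- .pool_out(o2, config)
  if (p2 < 1) abort("pool2 output would be empty")
  flat <- p2 * p2 * config$n_kernels2
  tibble(
    stage = c("input", "conv1", "pool1", "conv2", "pool2", "flatten",
              "fc", "output"),
    height = c(H, o1, p1, o2, p2, NA, NA, NA),
    width = c(H, o1, p1, o2, p2, NA, NA, NA),
    channels = c(1L, config$n_kernels1, config$n_kernels1,
                 config$n_kernels2, config$n_kernels2, NA, NA, NA),
    units = c(H * H, o1 * o1 * config$n_kernels1,
              p1 * p1 * config$n_kernels1, o2 * o2 * config$n_kernels2,
              flat, flat, config$fc_width, config$n_classes)
  )
}

.as_image_array <- function(images) {
  if (inherits(images, "swim_dataset")) return(images$images)
  if (is.matrix(images)) images <- array(images, dim = c(dim(images), 1))
  if (!is.array(images) || length(dim(images)) != 3) {
    abort("images must be a size x size x n array or a swim_dataset")
  }
  images
}

#' Train the recognition network
#'
#' Runs the configured number of optimization passes over the training
#' images with minibatch Adam and backpropagated gradients; ReLU follows
#' each convolution and dropout is active only during training. Training is
#' bit-reproducible for a fixed config seed.
#'
#' @param data a `swim_dataset` (see [build_dataset()]), or an image array
#'   with `labels` supplied.
#' @param config a [cnn_config()].
#' @param labels optional 0-based integer labels when `data` is an array.
#' @return a `swim_cnn` model: parameters, the config and the per-epoch
#'   training loss.
#' @export
cnn_train <- function(data, config, labels = NULL) {
  .check_config(config)
  images <- .as_image_array(data)
  if (is.null(labels)) {
    if (!inherits(data, "swim_dataset")) {
      abort("labels are required when data is a plain array")
    }
    labels <- data$class_index
  }
  if (length(labels) == 0) abort("training set is empty")
  if (dim(images)[1] != config$image_size ||
      dim(images)[2] != config$image_size) {
    abort("image size mismatch with config")
  }
  if (any(labels < 0 | labels >= config$n_classes)) {
    abort("label out of range for the configured class count")
  }
  shapes <- layer_shapes(config)  # validates the geometry
  fit <- .cnn_train_cpp(images, as.integer(labels), unclass(config))
  structure(
    list(parameters = fit[c("W1", "b1", "W2", "b2", "Wf1", "bf1",
                            "Wf2", "bf2")],
         config = config,
         loss_history = as.numeric(fit$loss_history),
         n_train = length(labels),
         shapes = shapes),
    class = "swim_cnn"
  )
}

#' @export
print.swim_cnn <- function(x, ...) {
  cat(sprintf(
    "<swim_cnn> %dx%d input, %d classes, %d epochs; final loss %.4f\n",
    x$config$image_size, x$config$image_size, x$config$n_classes,
    x$config$epochs, x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Predict classes for trajectory images
#'
#' @param object a trained `swim_cnn`.
#' @param images a `swim_dataset` or image array matching the model's input
#'   size.
#' @param ... unused.
#' @return a list with `class` (0-based predicted indices) and `prob`
#'   (n x K matrix of class probabilities, rows summing to 1).
#' @export
predict.swim_cnn <- function(object, images, ...) {
  arr <- .as_image_array(images)
  if (dim(arr)[1] != object$config$image_size ||
      dim(arr)[2] != object$config$image_size) {
    abort("image size mismatch with the model's input size")
  }
  prob <- .cnn_predict_cpp(object$parameters, arr, unclass(object$config))
  list(class = max.col(prob, ties.method = "first") - 1L, prob = prob)
}

#' @export
tidy.swim_cnn <- function(x, ...) {
  tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' @export
glance.swim_cnn <- function(x, ...) {
  n_par <- sum(vapply(x$parameters, length, numeric(1)))
  tibble(image_size = x$config$image_size, n_classes = x$config$n_classes,
         epochs = x$config$epochs, n_parameters = n_par,
         n_train = x$n_train,
         final_loss = x$loss_history[length(x$loss_history)])
}
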