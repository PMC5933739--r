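#' Split a dataset into training and validation parts
#'
#' Random, disjoint, exhaustive 80/20 split (training size is the ceiling
#' of `train_fraction * n`), reproducible from `seed`.
#'
#' @param dataset a `swim_dataset`.
#' @param train_fraction fraction assigned to training, in (0, 1).
#' @param seed shuffle seed.
#' @return list with elements `train` and `validation`, both `swim_dataset`s.
#' @examples
#' co <- simulate_cohort(cohort_spec(n_control = 2, n_lesion = 2, seed = 3))
#' ds <- build_dataset(co, 24, classes = 2, seed = 1)
#' sp <- split_dataset(ds, seed = 1)
#' length(sp$train$class_index)
#' @export
split_dataset <- function(dataset, train_fraction = 0.8, seed = 1) {
  if (!inherits(dataset, "swim_dataset")) abort("dataset must be a swim_dataset")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must lie strictly between 0 and 1")
  }
  n <- length(dataset$class_index)
  if (n < 5) abort("dataset must contain at least 5 items")
  n_train <- ceiling(train_fraction * n)
  ord <- .with_seed(seed, sample.int(n))
  list(train = .dataset_subset(dataset, ord[seq_len(n_train)]),
       validation = .dataset_subset(dataset, ord[(n_train + 1):n]))
}

#' Accuracy, sensitivity and specificity for a binary task
#'
#' Sensitivity is the detection rate of the positive class (thigmotaxis in
#' the 2-class task) and specificity the true-negative rate. When a rate is
#' undefined (no positive, or no negative, examples in the truth) it is
#' returned as `NA` rather than fabricated.
#'
#' @param truth,predicted equal-length label vectors (any comparable type).
#' @param positive the value of `truth` counted as positive.
#' @return a one-row tibble with `accuracy`, `sensitivity`, `specificity`
#'   and the four confusion cells.
#' @examples
#' binary_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0), positive = 1)
#' @export
binary_metrics <- function(truth, predicted, positive) {
  if (length(truth) != length(predicted)) {
    abort("truth and predicted must have equal length")
  }
  pos <- truth == positive
  ppos <- predicted == positive
  tp <- sum(pos & ppos)
  fn <- sum(pos & !ppos)
  tn <- sum(!pos & !ppos)
  fp <- sum(!pos & ppos)
  tibble(
    accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    tp = tp, fn = fn, tn = tn, fp = fp
  )
}

#' Misclassification matrix normalized by total errors
#'
#' Off-diagonal cell (i, j) is the percentage of all misclassifications in
#' which true class i was predicted as class j; diagonal cells are not
#' applicable and returned as `NA`. With zero errors every cell is `NA`.
#'
#' @param truth,predicted 0-based integer class labels.
#' @param k number of classes.
#' @param class_names optional dimnames.
#' @return a `k x k` numeric matrix of percentages (off-diagonals summing
#'   to 100 when any error exists).
#' @export
misclassification_matrix <- function(truth, predicted, k,
                                     class_names = NULL) {
  if (any(truth < 0 | truth >= k) || any(predicted < 0 | predicted >= k)) {
    abort("labels must lie in [0, k)")
  }
  counts <- matrix(0, k, k)
  for (i in seq_along(truth)) {
    counts[truth[i] + 1, predicted[i] + 1] <- counts[truth[i] + 1, predicted[i] + 1] + 1
  }
  errors <- counts
  diag(errors) <- 0
  total <- sum(errors)
  out <- if (total == 0) {
    matrix(NA_real_, k, k)
  } else {
    100 * errors / total
  }
  diag(out) <- NA_real_
  if (!is.null(class_names)) dimnames(out) <- list(class_names, class_names)
  out
}

# ---- classifiers ---------------------------------------------------------

#' Classifiers usable inside the repeated-holdout harness
#'
#' `cnn_classifier()` wraps the convolutional network. `stub_classifier()`
#' provides the three analytic reference classifiers used to validate the
#' evaluation harness itself: `"perfect"` predicts the true labels,
#' `"majority"` always predicts the most frequent training class, and
#' `"uniform"` predicts uniformly at random.
#'
#' @param config a [cnn_config()] (its seed is replaced per repetition).
#' @return a `swim_classifier` with `fit(train, seed)` and
#'   `predict_index(model, data, truth, seed)` functions.
#' @export
cnn_classifier <- function(config) {
  .check_config(config)
  structure(
    list(
      name = "cnn",
      fit = function(train, seed) {
        cfg <- config
        cfg$seed <- as.integer(seed %% 2147483647)
        cnn_train(train, cfg)
      },
      predict_index = function(model, data, truth, seed) {
        predict(model, data)$class
      }
    ),
    class = "swim_classifier"
  )
}

#' @rdname cnn_classifier
#' @param type one of `"perfect"`, `"majority"`, `"uniform"`.
#' @export
stub_classifier <- function(type = c("perfect", "majority", "uniform")) {
  type <- match.arg(type)
  fit <- switch(type,
    perfect = function(train, seed) list(),
    majority = function(train, seed) {
      tab <- table(train$class_index)
      list(majority = as.integer(names(tab)[which.max(tab)]))
    },
    uniform = function(train, seed) {
      list(k = train$n_classes)
    }
  )
  predict_index <- switch(type,
    perfect = function(model, data, truth, seed) truth,
    majority = function(model, data, truth, seed) {
      rep(model$majority, length(truth))
    },
    uniform = function(model, data, truth, seed) {
      .with_seed(seed, sample.int(model$k, length(truth), replace = TRUE) - 1L)
    }
  )
  structure(list(name = type, fit = fit, predict_index = predict_index),
            class = "swim_classifier")
}

# ---- repeated holdout ----------------------------------------------------

#' Repeated-holdout evaluation
#'
#' The validation protocol of the recognition study: the dataset is
#' reshuffled and split 80/20 `repetitions` times; each repetition trains
#' the classifier from scratch on the training part and evaluates it on the
#' held-out part. Reported metrics are means with their standard errors
#' across repetitions; confusion counts are accumulated across repetitions
#' and the misclassification matrix normalizes their off-diagonal errors to
#' percentages of all errors. For the 2-class task, sensitivity and
#' specificity treat thigmotaxis as the positive class.
#'
#' @param dataset a `swim_dataset`.
#' @param config a [cnn_config()]; may be `NULL` when `classifier` is a
#'   stub.
#' @param repetitions number of holdout repetitions.
#' @param classifier a `swim_classifier`; defaults to the network.
#' @param train_fraction training fraction of each split.
#' @param seed master seed; per-repetition shuffle/training seeds derive
#'   from it.
#' @return a `swim_eval` object.
#' @export
repeated_holdout <- function(dataset, config = NULL, repetitions = 10,
                             classifier = NULL, train_fraction = 0.8,
                             seed = 1) {
  if (!inherits(dataset, "swim_dataset")) abort("dataset must be a swim_dataset")
  if (repetitions < 1) abort("repetitions must be at least 1")
  if (is.null(classifier)) {
    if (is.null(config)) abort("either config or classifier must be given")
    classifier <- cnn_classifier(config)
  }
  k <- dataset$n_classes
  pos_index <- 1L  # thigmotaxis in the 2-class map
  t0 <- proc.time()[["elapsed"]]
  reps <- vector("list", repetitions)
  confusion <- matrix(0L, k, k)
  for (r in seq_len(repetitions)) {
    split_seed <- .derive_seed(seed, r)
    sp <- split_dataset(dataset, train_fraction, seed = split_seed)
    if (k == 2 && sum(sp$train$class_index == pos_index) == 0) {
      abort(paste("a training split contains no positive examples;",
                  "use a larger dataset"))
    }
    model <- classifier$fit(sp$train, .derive_seed(seed + 7, r))
    truth <- sp$validation$class_index
    pred <- classifier$predict_index(model, sp$validation, truth,
                                     .derive_seed(seed + 13, r))
    for (i in seq_along(truth)) {
      confusion[truth[i] + 1, pred[i] + 1] <- confusion[truth[i] + 1, pred[i] + 1] + 1L
    }
    acc <- mean(pred == truth)
    if (k == 2) {
      bm <- binary_metrics(truth, pred, positive = pos_index)
      reps[[r]] <- tibble(repetition = r, n_validation = length(truth),
                          accuracy = acc, sensitivity = bm$sensitivity,
                          specificity = bm$specificity)
    } else {
      reps[[r]] <- tibble(repetition = r, n_validation = length(truth),
                          accuracy = acc, sensitivity = NA_real_,
                          specificity = NA_real_)
    }
  }
  reps <- dplyr::bind_rows(reps)
  class_names <- names(sort(dataset$class_map[!duplicated(dataset$class_map)]))
  if (k == 2) class_names <- c("Other", "Thigmotaxis")
  if (k == 3) class_names <- c("Other", "Thigmotaxis", "Direct swim")
  dimnames(confusion) <- list(true = class_names, predicted = class_names)
  acc <- .mean_sem(reps$accuracy)
  sens <- .mean_sem(reps$sensitivity)
  spec <- .mean_sem(reps$specificity)
  structure(
    list(
      n_classes = k,
      repetitions = repetitions,
      per_repetition = reps,
      accuracy_mean = 100 * acc$mean,
      accuracy_sem = 100 * (acc$sem %||% NA_real_),
      sensitivity_mean = sens$mean,
      sensitivity_sem = sens$sem,
      specificity_mean = spec$mean,
      specificity_sem = spec$sem,
      confusion_counts = confusion,
      misclassification_percent = {
        cm <- confusion
        err <- cm
        diag(err) <- 0
        out <- if (sum(err) == 0) matrix(NA_real_, k, k) else 100 * err / sum(err)
        diag(out) <- NA_real_
        dimnames(out) <- dimnames(cm)
        out
      },
      classifier = classifier$name,
      wall_time_s = proc.time()[["elapsed"]] - t0
    ),
    class = "swim_eval"
  )
}

#' @export
print.swim_eval <- function(x, ...) {
  cat(sprintf(
    "<swim_eval> %s, %d-class, %d repetitions: accuracy %.1f%% +/- %.1f%%",
    x$classifier, x$n_classes, x$repetitions, x$accuracy_mean,
    x$accuracy_sem))
  if (x$n_classes == 2 && is.finite(x$sensitivity_mean)) {
    cat(sprintf("; sensitivity %.2f, specificity %.2f",
                x$sensitivity_mean, x$specificity_mean))
  }
  cat(sprintf(" (%.1f s)\n", x$wall_time_s))
  invisible(x)
}

#' @export
tidy.swim_eval <- function(x, ...) {
  x$per_repetition
}

#' @export
glance.swim_eval <- function(x, ...) {
  tibble(classifier = x$classifier, n_classes = x$n_classes,
         repetitions = x$repetitions, accuracy_mean = x$accuracy_mean,
         accuracy_sem = x$accuracy_sem, sensitivity = x$sensitivity_mean,
         specificity = x$specificity_mean, wall_time_s = x$wall_time_s)
}
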