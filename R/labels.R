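#' Strategy classes and cognitive scores
#'
#' Swim paths are classified into six exploratory strategy classes, each
#' carrying a fixed cognitive score from 0 (thigmotaxis, wall hugging) to 5
#' (direct swim to the platform). The score order is also the canonical
#' class order used throughout the package.
#'
#' @return `strategy_levels()` returns the six class names in score order;
#'   `strategy_labels()` returns a tibble with one row per class and its
#'   cognitive score.
#' @examples
#' strategy_labels()
#' @export
strategy_levels <- function() {
  c("Thigmotaxis", "Scanning", "Circling", "Focal search", "Rotating",
    "Direct swim")
}

#' @rdname strategy_levels
#' @export
strategy_labels <- function() {
  tibble(label = strategy_levels(), cognitive_score = 0:5)
}

.check_labels <- function(label) {
  bad <- setdiff(unique(as.character(label)), strategy_levels())
  if (length(bad) > 0) {
    abort(paste0("unknown strategy label: ", paste(bad, collapse = ", ")))
  }
  invisible(label)
}

#' Cognitive score of a strategy class
#'
#' Pure lookup in the fixed score map: Thigmotaxis 0, Scanning 1, Circling 2,
#' Focal search 3, Rotating 4, Direct swim 5.
#'
#' @param label character vector (or factor) of strategy class names.
#' @return integer vector of scores.
#' @examples
#' cognitive_score(c("Thigmotaxis", "Direct swim"))
#' @export
cognitive_score <- function(label) {
  label <- as.character(label)
  .check_labels(label)
  match(label, strategy_levels()) - 1L
}

#' Mean cognitive score of one mouse-day
#'
#' A training day holds up to five trials; the day's score is the arithmetic
#' mean of the per-trial cognitive scores.
#'
#' @param labels character vector of 1 to 5 strategy class names.
#' @return a single numeric mean score.
#' @examples
#' daily_mean_score(c("Thigmotaxis", "Scanning", "Direct swim"))
#' @export
daily_mean_score <- function(labels) {
  if (length(labels) < 1) abort("a day must contain at least one trial")
  if (length(labels) > 5) abort("a day holds at most five trials")
  mean(cognitive_score(labels))
}

#' Class-index maps for the 2-, 3- and 6-class recognition tasks
#'
#' Two-class recognition distinguishes thigmotaxis (index 1) from all other
#' paths (index 0). Three-class recognition additionally separates direct
#' swim (index 2). Six-class recognition uses the score order 0..5.
#'
#' @param classes 2, 3 or 6.
#' @return a named integer vector mapping each of the six strategy labels to
#'   its 0-based class index.
#' @examples
#' class_index_map(2)
#' @export
class_index_map <- function(classes) {
  lv <- strategy_levels()
  if (classes == 2) {
    idx <- ifelse(lv == "Thigmotaxis", 1L, 0L)
  } else if (classes == 3) {
    idx <- ifelse(lv == "Thigmotaxis", 1L, ifelse(lv == "Direct swim", 2L, 0L))
  } else if (classes == 6) {
    idx <- 0:5
  } else {
    abort("classes must be 2, 3 or 6")
  }
  stats::setNames(as.integer(idx), lv)
}
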