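#' Class percentages as printed in frequency tables
#'
#' Formats per-class trial counts as percentages of the row total at
#' one-decimal rounding, the convention used by the stage frequency tables.
#'
#' @param counts integer vector of per-class trial counts.
#' @param total row total (defaults to `sum(counts)`).
#' @return numeric vector of percentages rounded to one decimal.
#' @examples
#' class_percentages(c(44, 85, 87, 145, 84, 55))
#' @export
class_percentages <- function(counts, total = sum(counts)) {
  if (total <= 0) abort("total must be positive")
  round(100 * counts / total, 1)
}

# per-mouse mean latency on one day, then mean +/- SEM across mice
.day_latency <- function(df, day) {
  d <- df[df$day == day, ]
  per_mouse <- tapply(d$latency_s, d$mouse_id, mean)
  .mean_sem(as.numeric(per_mouse))
}

#' Stage frequency table
#'
#' Summarizes one training stage (early = days 1-2, late = days 4-5) the
#' way the study tables do: per group (all mice, control, lesion) the trial
#' and mouse counts, per-class counts with one-decimal percentages, and the
#' mean escape latency with SEM on the stage's reference day (day 2 for the
#' early stage, day 5 for the late stage), computed from per-mouse day
#' means.
#'
#' @param cohort a `swim_cohort` or its manifest (needs `mouse_id`,
#'   `group`, `day`, `trial`, `label`, `latency_s`).
#' @param stage `"early"` or `"late"`.
#' @return a `swim_freq_table` tibble: one row per group with columns
#'   `n_trials`, `n_mice`, `<class>_n`, `<class>_pct`, `latency_mean_s`,
#'   `latency_sem_s`.
#' @export
stage_frequency_table <- function(cohort, stage) {
  days <- .stage_days(stage)
  latency_day <- if (stage == "early") 2L else 5L
  df <- as_tibble(cohort)
  df$path <- NULL
  sub <- df[df$day %in% days, ]
  lv <- strategy_levels()
  one_row <- function(d, group_label) {
    counts <- vapply(lv, function(l) sum(d$label == l), integer(1))
    lat <- .day_latency(d, latency_day)
    row <- tibble(group = group_label, n_trials = nrow(d),
                  n_mice = dplyr::n_distinct(d$mouse_id))
    for (l in lv) {
      row[[paste0(gsub(" ", "_", tolower(l)), "_n")]] <- counts[[l]]
      row[[paste0(gsub(" ", "_", tolower(l)), "_pct")]] <-
        class_percentages(counts[[l]], nrow(d))
    }
    row$latency_mean_s <- round(lat$mean, 1)
    row$latency_sem_s <- round(lat$sem, 1)
    row
  }
  out <- dplyr::bind_rows(
    one_row(sub, "All mice"),
    one_row(sub[sub$group == "control", ], "Control"),
    one_row(sub[sub$group == "lesion", ], "Lesion")
  )
  class(out) <- c("swim_freq_table", class(out))
  attr(out, "stage") <- stage
  out
}

#' Partition mice by presence of a strategy in a stage
#'
#' A mouse is "with" the strategy if at least one of its trials in the
#' stage bears that label (so one mouse can be "with" several strategies).
#'
#' @param cohort a `swim_cohort` or manifest.
#' @param label a strategy class name.
#' @param stage `"early"` or `"late"`.
#' @return a tibble with one row per mouse: `mouse_id`, `group`,
#'   `with_strategy`.
#' @export
presence_grouping <- function(cohort, label, stage = "early") {
  .check_labels(label)
  days <- .stage_days(stage)
  df <- as_tibble(cohort)
  df$path <- NULL
  df |>
    dplyr::group_by(.data$mouse_id, .data$group) |>
    dplyr::summarise(
      with_strategy = any(.data$label[.data$day %in% days] == !!label),
      .groups = "drop")
}

#' Two-group comparison with a variance gate
#'
#' The study's two-sample protocol: an F test of equal variances at
#' alpha = 0.05 selects between the pooled-variance t test and the
#' unequal-variance (Welch) t test. Two groups with zero variance are
#' reported as degenerate rather than producing an error.
#'
#' @param values_a,values_b numeric vectors (each of length >= 2).
#' @param alpha significance level of the variance gate.
#' @return a one-row tibble: `test` ("student", "welch" or "degenerate"),
#'   `statistic`, `df`, `p_value`, `f_statistic`, `f_p_value`, `mean_a`,
#'   `mean_b`.
#' @examples
#' compare_two_groups(c(1, 2, 3), c(2, 3, 4))
#' @export
compare_two_groups <- function(values_a, values_b, alpha = 0.05) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("each group needs at least 2 values")
  }
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    same <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    return(tibble(test = "degenerate", statistic = NA_real_, df = NA_real_,
                  p_value = if (same) 1 else NA_real_,
                  f_statistic = NA_real_, f_p_value = NA_real_,
                  mean_a = mean(values_a), mean_b = mean(values_b)))
  }
  ft <- stats::var.test(values_a, values_b)
  equal_var <- ft$p.value >= alpha
  tt <- stats::t.test(values_a, values_b, var.equal = equal_var)
  tibble(test = if (equal_var) "student" else "welch",
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, f_statistic = unname(ft$statistic),
         f_p_value = ft$p.value,
         mean_a = mean(values_a), mean_b = mean(values_b))
}

#' One-way analysis of variance
#'
#' Standard one-way decomposition across two or more groups (the multiple
#' comparison analysis of the study); for two groups its F statistic equals
#' the square of the pooled-variance t statistic.
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return a one-row tibble: `statistic` (F), `df_between`, `df_within`,
#'   `p_value`.
#' @examples
#' anova_oneway(list(rnorm(5), rnorm(5), rnorm(5)))
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2) abort("at least two groups are required")
  if (any(vapply(groups, length, integer(1)) < 2)) {
    abort("every group needs at least 2 values")
  }
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  ow <- stats::oneway.test(values ~ g, var.equal = TRUE)
  tibble(statistic = unname(ow$statistic),
         df_between = unname(ow$parameter[1]),
         df_within = unname(ow$parameter[2]),
         p_value = ow$p.value)
}

#' Cognitive-score transition across training days
#'
#' For each mouse and day the mean per-trial cognitive score
#' ([daily_mean_score()]); aggregated across the mice of each group into a
#' per-day mean with SEM. A single-mouse group yields `NA` SEM.
#'
#' @param cohort a `swim_cohort` or manifest with labels.
#' @return a tibble with columns `group`, `day`, `mean_score`, `sem_score`,
#'   `n_mice`.
#' @export
score_transition <- function(cohort) {
  df <- as_tibble(cohort)
  df$path <- NULL
  per_day <- df |>
    dplyr::group_by(.data$group, .data$mouse_id, .data$day) |>
    dplyr::summarise(day_score = daily_mean_score(.data$label),
                     .groups = "drop")
  per_day |>
    dplyr::group_by(.data$group, .data$day) |>
    dplyr::summarise(mean_score = mean(.data$day_score),
                     sem_score = if (dplyr::n() > 1) {
                       stats::sd(.data$day_score) / sqrt(dplyr::n())
                     } else {
                       NA_real_
                     },
                     n_mice = dplyr::n(), .groups = "drop")
}

#' Day-5 outcome by early presence of a strategy
#'
#' The presence-of-strategy analysis: mice are split by whether they showed
#' the strategy at least once in the stage; the groups' day-5 per-mouse
#' mean escape latencies and day-5 mean cognitive scores are compared with
#' the variance-gated two-sample test.
#'
#' @param cohort a `swim_cohort` or manifest.
#' @param label strategy class defining the grouping.
#' @param stage stage in which presence is assessed.
#' @return a tibble with one row per outcome (`latency_s`, `cognitive_score`)
#'   giving group sizes, means with SEM, the chosen test and its p-value.
#' @export
presence_outcome <- function(cohort, label, stage = "early") {
  grouping <- presence_grouping(cohort, label, stage)
  df <- as_tibble(cohort)
  df$path <- NULL
  day5 <- df[df$day == 5L, ] |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::summarise(latency_s = mean(.data$latency_s),
                     cognitive_score = daily_mean_score(.data$label),
                     .groups = "drop") |>
    dplyr::left_join(grouping, by = "mouse_id")
  one <- function(outcome) {
    with_v <- day5[[outcome]][day5$with_strategy]
    without_v <- day5[[outcome]][!day5$with_strategy]
    cmp <- if (length(with_v) >= 2 && length(without_v) >= 2) {
      compare_two_groups(with_v, without_v)
    } else {
      tibble(test = "insufficient", p_value = NA_real_)
    }
    w <- .mean_sem(with_v)
    wo <- .mean_sem(without_v)
    tibble(outcome = outcome, strategy = label, stage = stage,
           n_with = length(with_v), n_without = length(without_v),
           mean_with = w$mean, sem_with = w$sem,
           mean_without = wo$mean, sem_without = wo$sem,
           test = cmp$test, p_value = cmp$p_value)
  }
  dplyr::bind_rows(one("latency_s"), one("cognitive_score"))
}
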