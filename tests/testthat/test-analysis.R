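test_that("percentage formatting matches one-decimal table arithmetic", {
  expect_equal(class_percentages(44, 500), 8.8)
  expect_equal(class_percentages(153, 500), 30.6)
  expect_equal(class_percentages(40, 280), 14.3)
  expect_equal(class_percentages(15, 220), 6.8)
  expect_equal(class_percentages(c(10, 20, 30)), c(16.7, 33.3, 50))
})

test_that("stage tables conserve trial counts and recompute percentages", {
  co <- small_cohort(n_control = 3, n_lesion = 4, seed = 21)
  for (stage in c("early", "late")) {
    tab <- stage_frequency_table(co, stage)
    expect_equal(tab$group, c("All mice", "Control", "Lesion"))
    expect_equal(tab$n_trials, c(70, 30, 40))
    expect_equal(tab$n_mice, c(7, 3, 4))
    cols_n <- grep("_n$", names(tab), value = TRUE)
    for (i in 1:3) {
      counts <- as.numeric(tab[i, cols_n])
      expect_equal(sum(counts), tab$n_trials[i])
      # brute-force group-by over the manifest
      days <- if (stage == "early") 1:2 else 4:5
      sub <- cohort_manifest(co)
      sub <- sub[sub$day %in% days, ]
      if (i == 2) sub <- sub[sub$group == "control", ]
      if (i == 3) sub <- sub[sub$group == "lesion", ]
      manual <- vapply(strategy_levels(),
                       function(l) sum(sub$label == l), numeric(1))
      expect_equal(counts, unname(manual))
      pct <- as.numeric(tab[i, sub("_n$", "_pct", cols_n)])
      expect_equal(pct, round(100 * counts / sum(counts), 1))
    }
  }
  expect_error(stage_frequency_table(co, "middle"), "early.*late")
})

test_that("a degenerate all-thigmotaxis cohort gives a 100% column", {
  mix <- default_class_mixtures()
  mix$prob <- ifelse(mix$label == "Thigmotaxis", 1, 0)
  co <- simulate_cohort(cohort_spec(n_control = 1, n_lesion = 1,
                                    class_mixture = mix, seed = 3))
  tab <- stage_frequency_table(co, "early")
  expect_equal(tab$thigmotaxis_pct, c(100, 100, 100))
  expect_equal(tab$scanning_pct, c(0, 0, 0))
  # nobody escapes under pure wall hugging: latency is the 120 s cap
  expect_equal(tab$latency_mean_s, c(120, 120, 120))
})

test_that("presence grouping applies the at-least-once rule", {
  co <- small_cohort(n_control = 4, n_lesion = 4, seed = 33)
  man <- cohort_manifest(co)
  for (lab in c("Thigmotaxis", "Direct swim")) {
    pg <- presence_grouping(co, lab, "early")
    expect_equal(nrow(pg), 8)
    for (i in seq_len(nrow(pg))) {
      seen <- any(man$label[man$mouse_id == pg$mouse_id[i] &
                              man$day %in% 1:2] == lab)
      expect_identical(pg$with_strategy[i], seen)
    }
  }
  # a label absent from the cohort puts every mouse in the without group
  mix <- default_class_mixtures()
  mix$prob <- ifelse(mix$label == "Scanning", 1, 0)
  co2 <- simulate_cohort(cohort_spec(n_control = 1, n_lesion = 1,
                                     class_mixture = mix, seed = 2))
  pg2 <- presence_grouping(co2, "Rotating", "early")
  expect_false(any(pg2$with_strategy))
})

test_that("the variance gate picks the textbook two-sample test", {
  a <- c(1, 2, 3)
  b <- c(2, 3, 4)
  res <- compare_two_groups(a, b)
  # hand computation: pooled t on 3+3 values
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$test, "student")
  expect_equal(res$statistic, t_hand)
  expect_equal(res$df, 4)
  # identical symmetric groups: no difference
  same <- compare_two_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  # zero-variance degenerate case is reported, not crashed
  deg <- compare_two_groups(c(2, 2), c(2, 2))
  expect_equal(deg$test, "degenerate")
  expect_equal(deg$p_value, 1)
})

test_that("the gate selects the unequal-variance branch under heteroscedasticity", {
  set.seed(55)
  welch <- 0
  student <- 0
  for (i in 1:200) {
    res <- compare_two_groups(rnorm(20, 0, 1), rnorm(20, 0, sqrt(10)))
    if (res$test == "welch") welch <- welch + 1
    res2 <- compare_two_groups(rnorm(20, 0, 1), rnorm(20, 0, 1))
    if (res2$test == "student") student <- student + 1
  }
  expect_gte(welch / 200, 0.97)
  expect_gte(student / 200, 0.9)
})

test_that("one-way ANOVA matches hand sums of squares and the t-squared identity", {
  g1 <- c(3, 5, 4, 6)
  g2 <- c(8, 9, 7, 10)
  g3 <- c(5, 6, 5, 7)
  res <- anova_oneway(list(g1, g2, g3))
  all_v <- c(g1, g2, g3)
  gm <- mean(all_v)
  ssb <- 4 * ((mean(g1) - gm)^2 + (mean(g2) - gm)^2 + (mean(g3) - gm)^2)
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2) +
    sum((g3 - mean(g3))^2)
  f_hand <- (ssb / 2) / (ssw / 9)
  expect_equal(res$statistic, f_hand)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 9)
  # two-group F equals the square of the pooled t statistic
  tt <- compare_two_groups(g1, g2)
  f2 <- anova_oneway(list(g1, g2))
  expect_equal(f2$statistic, tt$statistic^2, tolerance = 1e-9)
  # identical groups give F ~ 0
  f0 <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(f0$statistic, 0)
  expect_error(anova_oneway(list(c(1, 2), c(3))), "at least 2 values")
})

test_that("cognitive scores rise across days when the mixture shifts", {
  co <- small_cohort(n_control = 6, n_lesion = 6, seed = 44)
  tr <- score_transition(co)
  for (g in c("control", "lesion")) {
    d1 <- tr$mean_score[tr$group == g & tr$day == 1]
    d5 <- tr$mean_score[tr$group == g & tr$day == 5]
    expect_gt(d5, d1)
  }
  # brute-force double loop over mice and days
  man <- cohort_manifest(co)
  for (i in sample(nrow(tr), 5)) {
    g <- tr$group[i]
    d <- tr$day[i]
    mice <- unique(man$mouse_id[man$group == g])
    per_mouse <- vapply(mice, function(m) {
      mean(cognitive_score(man$label[man$mouse_id == m & man$day == d]))
    }, numeric(1))
    expect_equal(tr$mean_score[i], mean(per_mouse))
    expect_equal(tr$sem_score[i], sd(per_mouse) / sqrt(length(per_mouse)))
  }
  # a single-mouse group has no dispersion estimate
  co1 <- simulate_cohort(cohort_spec(n_control = 1, n_lesion = 1, seed = 4))
  tr1 <- score_transition(co1)
  expect_true(all(is.na(tr1$sem_score)))
})

test_that("early wall hugging predicts worse day-5 latency in cohorts", {
  co <- simulate_cohort(cohort_spec(n_control = 22, n_lesion = 28, seed = 77))
  out <- presence_outcome(co, "Thigmotaxis", "early")
  lat <- out[out$outcome == "latency_s", ]
  expect_gt(lat$n_with, 1)
  expect_gt(lat$mean_with, lat$mean_without)
})
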