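test_that("trajectories satisfy the shared structural invariants", {
  g <- pool_geometry()
  pr <- sim_params()
  for (l in strategy_levels()) {
    tr <- simulate_trajectory(l, g, pr, seed = 17)
    expect_gte(nrow(tr), 2)
    expect_equal(tr$time_s[1], 0)
    expect_true(all(diff(tr$time_s) > 0))
    expect_true(all(sqrt(tr$x_m^2 + tr$y_m^2) <= g$pool_radius + 1e-9))
    last <- c(tr$x_m[nrow(tr)], tr$y_m[nrow(tr)])
    on_platform <- sum((last - g$platform_center)^2) <= g$platform_radius^2
    expect_identical(attr(tr, "escaped"), on_platform)
    if (attr(tr, "escaped")) {
      expect_equal(attr(tr, "latency_s"), tr$time_s[nrow(tr)])
    } else {
      expect_equal(attr(tr, "latency_s"), pr$max_duration)
    }
  }
  expect_error(simulate_trajectory("Drifting"), "unknown strategy label")
  expect_error(sim_params(dt = 200), "smaller than max_duration")
})

test_that("trajectories are bit-for-bit reproducible from their seed", {
  for (l in c("Scanning", "Rotating", "Direct swim")) {
    a <- simulate_trajectory(l, seed = 123)
    b <- simulate_trajectory(l, seed = 123)
    expect_identical(a$x_m, b$x_m)
    expect_identical(a$y_m, b$y_m)
    c <- simulate_trajectory(l, seed = 124)
    expect_false(identical(a$x_m, c$x_m))
  }
})

test_that("each class satisfies its defining geometric property", {
  g <- pool_geometry()
  pr <- sim_params()
  checks <- list(
    "Thigmotaxis" = function(fv) fv$wall_zone_fraction >= 0.8,
    "Direct swim" = function(fv) fv$path_efficiency >= 0.8 && fv$escaped,
    "Focal search" = function(fv) fv$quadrant_count <= 2,
    "Circling" = function(fv) fv$turn_sign_consistency >= 0.75,
    "Rotating" = function(fv) fv$spatial_extent_ratio <= 0.5 &&
      fv$mean_abs_turn > 0.4,
    "Scanning" = function(fv) fv$quadrant_count >= 3
  )
  for (l in names(checks)) {
    for (s in 1:15) {
      tr <- simulate_trajectory(l, g, pr, seed = 3000 + s,
                                start_point = g$start_points[[(s - 1) %% 4 + 1]])
      expect_true(checks[[l]](compute_features(tr)), label = paste(l, s))
    }
  }
})

test_that("a noiseless direct swim reaches the platform at the kinematic time", {
  g <- pool_geometry(platform_center = c(0.3, 0), platform_radius = 0.01)
  pr <- sim_params(speed_sd = 0,
                   per_class = list("Direct swim" = list(heading_sd = 0,
                                                         speed_mult = 1)))
  start <- c(-0.6, 0)  # diametrically opposite the platform
  tr <- simulate_trajectory("Direct swim", g, pr, seed = 1,
                            start_point = start)
  dist <- sqrt(sum((start - g$platform_center)^2)) - g$platform_radius
  expect_true(attr(tr, "escaped"))
  expect_lt(abs(attr(tr, "latency_s") - dist / pr$speed_mean), pr$dt + 1e-9)
})

test_that("a pure tangential wall-following variant never leaves the annulus", {
  pr <- sim_params(per_class = list(
    "Thigmotaxis" = list(radial_sd = 0, reverse_prob = 0)))
  tr <- simulate_trajectory("Thigmotaxis", params = pr, seed = 8)
  g <- attr(tr, "geometry")
  r <- sqrt(tr$x_m^2 + tr$y_m^2)
  expect_true(all(r >= 0.9 * g$pool_radius))
  expect_equal(compute_features(tr)$wall_zone_fraction, 1.0)
})

test_that("cohorts have the full trial structure and derived labels", {
  co <- small_cohort(n_control = 2, n_lesion = 3, seed = 4)
  expect_equal(nrow(co), 5 * 5 * 5)
  expect_equal(sum(co$day %in% 1:2), 5 * 10)
  expect_setequal(unique(co$group), c("control", "lesion"))
  expect_true(all(co$label %in% strategy_levels()))
  # reproducibility of the whole cohort
  co2 <- small_cohort(n_control = 2, n_lesion = 3, seed = 4)
  expect_identical(cohort_manifest(co), cohort_manifest(co2))
  expect_identical(co$path[[7]], co2$path[[7]])
  expect_error(cohort_spec(n_control = 0), "at least one mouse")
})

test_that("a degenerate single-class mixture yields only that class", {
  mix <- default_class_mixtures()
  mix$prob <- ifelse(mix$label == "Thigmotaxis", 1, 0)
  labs <- draw_cohort_labels(cohort_spec(n_control = 3, n_lesion = 3,
                                         class_mixture = mix, seed = 2))
  expect_true(all(labs$label == "Thigmotaxis"))
})

test_that("cohort label frequencies converge to the specified mixtures", {
  labs <- draw_cohort_labels(cohort_spec(n_control = 500, n_lesion = 500,
                                         seed = 11))
  mix <- default_class_mixtures()
  for (g in c("control", "lesion")) {
    for (s in c("early", "late")) {
      days <- if (s == "early") 1:2 else 4:5
      obs <- labs$label[labs$group == g & labs$day %in% days]
      expect_gte(length(obs), 5000)
      p0 <- mix$prob[mix$group == g & mix$stage == s]
      counts <- table(factor(obs, levels = strategy_levels()))
      pval <- suppressWarnings(stats::chisq.test(counts, p = p0)$p.value)
      expect_gt(pval, 0.001)
    }
  }
})
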