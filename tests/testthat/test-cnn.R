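test_that("layer shapes follow the closed-form arithmetic for all sizes", {
  expected <- list(
    `48` = c(input = 48, conv1 = 40, pool1 = 20, conv2 = 16, pool2 = 8),
    `72` = c(input = 72, conv1 = 60, pool1 = 30, conv2 = 24, pool2 = 12),
    `24` = c(input = 24, conv1 = 20, pool1 = 10, conv2 = 8, pool2 = 4)
  )
  flat <- c(`48` = 3200, `72` = 7200, `24` = 800)
  for (size in c(48, 72, 24)) {
    for (k in c(2, 3, 6)) {
      sh <- layer_shapes(cnn_config(image_size = size, n_classes = k))
      key <- as.character(size)
      expect_equal(sh$height[1:5], unname(expected[[key]]))
      expect_equal(sh$width[1:5], unname(expected[[key]]))
      expect_equal(sh$channels[2:5], c(20, 20, 50, 50))
      expect_equal(sh$units[sh$stage == "flatten"], unname(flat[key]))
      expect_equal(sh$units[sh$stage == "fc"], 500)
      expect_equal(sh$units[sh$stage == "output"], k)
    }
  }
})

test_that("the stride-1 same-padding pooling variant preserves map sizes", {
  cfg <- cnn_config(image_size = 24, pool_stride = 1, pool_same = TRUE)
  sh <- layer_shapes(cfg)
  expect_equal(sh$height[1:5], c(24, 20, 20, 18, 18))
})

test_that("invalid geometry is rejected naming the stage", {
  cfg <- cnn_config(image_size = 24)
  cfg$kernel1 <- 25L
  expect_error(layer_shapes(cfg), "conv1")
})

test_that("a tiny training set is memorized within the standard pass count", {
  co <- small_cohort(seed = 9)
  ds <- build_dataset(co, 24, classes = 6, seed = 2, stage = "early")
  idx <- 1:20
  imgs <- ds$images[, , idx, drop = FALSE]
  labs <- ds$class_index[idx]
  cfg <- cnn_config(image_size = 24, n_classes = 6, epochs = 50,
                    batch_size = 4, seed = 3)
  m <- cnn_train(imgs, cfg, labels = labs)
  pred <- predict(m, imgs)
  expect_equal(mean(pred$class == labs), 1.0)
  # the same memorization continues at prediction time
  expect_identical(pred$class, labs)
  # loss history descends on any non-degenerate set
  expect_length(m$loss_history, 50)
  expect_lt(mean(tail(m$loss_history, 5)), mean(head(m$loss_history, 5)))
})

test_that("training is deterministic and prediction is a distribution", {
  co <- small_cohort(seed = 10)
  ds <- build_dataset(co, 24, classes = 2, seed = 2, stage = "early")
  cfg <- cnn_config(image_size = 24, n_classes = 2, epochs = 3, seed = 11)
  m1 <- cnn_train(ds, cfg)
  m2 <- cnn_train(ds, cfg)
  expect_identical(m1$parameters, m2$parameters)
  expect_identical(m1$loss_history, m2$loss_history)
  pr <- predict(m1, ds)
  expect_true(all(abs(rowSums(pr$prob) - 1) < 1e-6))
  expect_true(all(pr$prob >= 0))
  expect_identical(pr$class,
                   as.integer(apply(pr$prob, 1, which.max) - 1L))
})

test_that("a zeroed output layer predicts the uniform distribution", {
  co <- small_cohort(seed = 10)
  ds <- build_dataset(co, 24, classes = 6, seed = 2, stage = "early")
  cfg <- cnn_config(image_size = 24, n_classes = 6, epochs = 1, seed = 1)
  m <- cnn_train(.dataset_head(ds, 12), cfg)
  m$parameters$Wf2[] <- 0
  m$parameters$bf2[] <- 0
  pr <- predict(m, .dataset_head(ds, 5))
  expect_true(all(abs(pr$prob - 1 / 6) < 1e-6))
})

test_that("parameter shapes and counts are seed-invariant", {
  co <- small_cohort(seed = 10)
  ds <- build_dataset(co, 24, classes = 2, seed = 2, stage = "early")
  cfg1 <- cnn_config(image_size = 24, n_classes = 2, epochs = 1, seed = 1)
  cfg2 <- cnn_config(image_size = 24, n_classes = 2, epochs = 1, seed = 999)
  m1 <- cnn_train(ds, cfg1)
  m2 <- cnn_train(ds, cfg2)
  expect_identical(lapply(m1$parameters, dim), lapply(m2$parameters, dim))
  expect_identical(vapply(m1$parameters, length, numeric(1)),
                   vapply(m2$parameters, length, numeric(1)))
  expect_equal(glance(m1)$n_parameters, glance(m2)$n_parameters)
  # mismatched labels and image sizes are rejected
  expect_error(cnn_train(ds$images, cfg1, labels = rep(5L, 10)),
               "label out of range")
  expect_error(cnn_train(ds, cnn_config(image_size = 48, n_classes = 2)),
               "size mismatch")
})
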