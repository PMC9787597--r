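test_that("cyclic duplication reaches the target count exactly", {
  s3 <- tiny_set(n = 3, length = 32)
  d9 <- buildDuplicatedDataset(s3, 9)
  expect_equal(nSpectra(d9), 9L)
  x <- intensities(s3)
  expect_equal(intensities(d9), x[, rep(1:3, 3)], ignore_attr = TRUE)

  expect_identical(intensities(buildDuplicatedDataset(s3, 3)),
                   intensities(s3))

  s2 <- tiny_set(n = 2, length = 32)
  d5 <- buildDuplicatedDataset(s2, 5)
  expect_equal(as.numeric(table(apply(intensities(d5), 2, function(c)
    which.min(colSums(abs(intensities(s2) - c)))))), c(3, 2))
  expect_error(buildDuplicatedDataset(s2, 1), ">=")
})

test_that("the small convolutional classifier separates synthetic classes", {
  lib <- makeClassLibrary(2, length = 64, rng_seed = 3)
  a <- makeDataset(lib[[1]], n = 25, length = 64, noise_sigma = 0.02,
                   label = "class_1", rng_seed = 1)
  b <- makeDataset(lib[[2]], n = 25, length = 64, noise_sigma = 0.02,
                   label = "class_2", rng_seed = 2)
  x <- cbind(intensities(a), intensities(b))
  labs <- c(spectrumLabels(a), spectrumLabels(b))
  cfg <- classifierConfig(2, 64, epochs = 25, rng_seed = 4)
  cls <- trainClassifier(x, labs, cfg)
  expect_length(cls$history, 25L)
  expect_true(all(is.finite(cls$history)))
  # cost decreases over training
  expect_lt(mean(tail(cls$history, 5)), mean(head(cls$history, 5)))
  # held-out replicates of the same classes are classified correctly
  ta <- makeDataset(lib[[1]], n = 10, length = 64, noise_sigma = 0.02,
                    label = "class_1", rng_seed = 11)
  tb <- makeDataset(lib[[2]], n = 10, length = 64, noise_sigma = 0.02,
                    label = "class_2", rng_seed = 12)
  pred <- predictClassifier(cls, cbind(intensities(ta), intensities(tb)))
  truth <- c(spectrumLabels(ta), spectrumLabels(tb))
  expect_gt(mean(pred == truth), 0.9)
})

test_that("the two comparison arms are matched in size and test set", {
  lib <- makeClassLibrary(2, length = 64, rng_seed = 6)
  seed_sets <- list(
    class_1 = makeDataset(lib[[1]], n = 1, length = 64, label = "class_1",
                          rng_seed = 1),
    class_2 = makeDataset(lib[[2]], n = 1, length = 64, label = "class_2",
                          rng_seed = 2))
  test_sets <- list(
    class_1 = makeDataset(lib[[1]], n = 6, length = 64, label = "class_1",
                          rng_seed = 31),
    class_2 = makeDataset(lib[[2]], n = 6, length = 64, label = "class_2",
                          rng_seed = 32))
  pcfg <- function(seed) pipelineConfig("DA-GAN", length = 64,
    aug = augmentationConfig(n_out = 10, shift_scale = 2),
    gan_epochs = 2, base_channels = 4, noise_size = 5, rng_seed = seed)
  models <- list(runTraining(seed_sets[[1]], pcfg(1)),
                 runTraining(seed_sets[[2]], pcfg(2)))
  rep <- runComparison(seed_sets, models, test_sets,
                       classifierConfig(2, 64, epochs = 4, rng_seed = 9),
                       n_per_class = 8)
  expect_named(rep$accuracy, c("duplicated", "generated"))
  expect_length(rep$cost$duplicated, 4L)
  expect_length(rep$cost$generated, 4L)
  expect_true(all(rep$accuracy >= 0 & rep$accuracy <= 1))
  # the diversity-deficit mechanism: one duplicated seed per class has zero
  # within-class variance; generated spectra have strictly positive variance
  expect_equal(rep$within_class_variance[["duplicated"]], 0)
  expect_gt(rep$within_class_variance[["generated"]], 0)
})
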