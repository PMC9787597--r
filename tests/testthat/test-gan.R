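test_that("critic layer parameter counts match the canonical architecture", {
  cfg <- ganConfig(2688, noise_size = 100, epochs = 1)
  D <- buildCritic(cfg)
  counts <- layerParameters(D)
  convs <- counts$parameters[counts$type == "conv1d"]
  expect_equal(convs, c(256, 32768, 131072, 524288, 86016))
  bns <- counts$parameters[counts$type == "batchnorm1d"]
  expect_equal(bns, c(256, 512, 1024))
  expect_equal(countParameters(D), 256 + 32768 + 131072 + 524288 + 86016 +
                 256 + 512 + 1024)
  # layer 5 kernel width follows datasize/16: 512 * (2688/16) = 86,016
  expect_equal(512 * (2688 / 16), 86016)
})

test_that("generator layer parameter counts match the canonical architecture", {
  cfg <- ganConfig(2688, noise_size = 100, epochs = 1)
  G <- buildGenerator(cfg)
  counts <- layerParameters(G)
  tconvs <- counts$parameters[counts$type == "tconv1d"]
  expect_equal(tconvs, c(8601600, 524288, 131072, 32768, 256))
  bns <- counts$parameters[counts$type == "batchnorm1d"]
  expect_equal(bns, c(1024, 512, 256, 128))
  # layer 1 count is noise_size * 512 * (datasize/16) = 100 * 512 * 168
  expect_equal(100 * 512 * 168, 8601600)
})

test_that("datasize must allow four stride-2 halvings", {
  expect_error(ganConfig(2689, epochs = 1), "divisible by 16")
  expect_error(ganConfig(100, epochs = 1), "divisible by 16")
})

test_that("critic maps any padded length to one score, generator inverts", {
  ns <- asNamespace("RamanForge")
  for (ds in c(32L, 96L, 256L)) {
    cfg <- ganConfig(ds, noise_size = 5, base_channels = 4, epochs = 1)
    D <- buildCritic(cfg); G <- buildGenerator(cfg)
    y <- ns$nn_model_fwd(D, array(rnorm(ds * 3), c(1, ds, 3)), TRUE)$y
    expect_equal(dim(y), c(1L, 1L, 3L))
    g <- ns$nn_model_fwd(G, array(rnorm(5 * 3), c(5, 1, 3)), TRUE)$y
    expect_equal(dim(g), c(1L, ds, 3L))
    expect_true(all(abs(g) <= 1))   # tanh-bounded output
  }
})

test_that("Wasserstein losses are the stated score-gap forms", {
  expect_equal(criticLoss(c(1, 1), c(0, 0)), -1)
  expect_equal(generatorLoss(c(0, 0)), 0)
  expect_equal(criticLoss(2, -1), -3)
  expect_equal(generatorLoss(-1), 1)
  expect_error(criticLoss(numeric(0), 1), "non-empty")
})

test_that("training clips every critic parameter and counts critic batches", {
  ns <- asNamespace("RamanForge")
  x <- intensities(tiny_set(n = 12, length = 32))
  cfg <- tiny_gan_cfg(epochs = 2, seed = 3)
  st <- trainGAN(x, cfg)
  expect_lte(max(abs(unlist(ns$nn_trainable(st$D)))), cfg$clip_c)
  # ceiling(12/8) = 2 outer steps per epoch, 5 critic updates each
  expect_equal(st$critic_batches, 2L * 2L * 5L)
  expect_equal(st$step, 4L)
  h <- do.call(rbind, st$history)
  expect_true(all(is.finite(h)))

  # 10 generator updates -> exactly 50 critic batches
  st2 <- trainGAN(x[, 1:8], tiny_gan_cfg(epochs = 10, seed = 3))
  expect_equal(st2$critic_batches, 50L)
})

test_that("training and sampling are deterministic under a fixed seed", {
  x <- intensities(tiny_set(n = 8, length = 32))
  a <- trainGAN(x, tiny_gan_cfg(epochs = 2, seed = 9))
  b <- trainGAN(x, tiny_gan_cfg(epochs = 2, seed = 9))
  sa <- sampleGenerator(a, 4, rng_seed = 1)
  sb <- sampleGenerator(b, 4, rng_seed = 1)
  expect_identical(intensities(sa), intensities(sb))
  expect_equal(nChannels(sa), 32L)
  # distinct samples from distinct noise codes
  s100 <- intensities(sampleGenerator(a, 20, rng_seed = 2))
  expect_gt(min(dist(t(s100))), 0)
  # resuming advances rather than restarting
  # 8 spectra -> ceiling(8/8) = 1 outer step per epoch
  c2 <- trainGAN(x, tiny_gan_cfg(epochs = 2, seed = 9), state = a)
  expect_equal(c2$step, 4L)
  expect_false(identical(intensities(sampleGenerator(c2, 4, rng_seed = 1)),
                         intensities(sa)))
})
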