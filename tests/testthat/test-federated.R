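test_that("the plain gradient step follows theta - eta * g", {
  # quadratic (theta - 2)^2 at theta = 0: gradient -4, step 0.1 -> 0.4
  theta <- 0
  g <- 2 * (theta - 2)
  expect_equal(sgdStep(theta, g, 0.1), 0.4)
  expect_equal(sgdStep(list(a = 1, b = matrix(2, 2, 2)),
                       list(a = 1, b = matrix(1, 2, 2)), 0.5)$a, 0.5)
})

test_that("federated averaging is the sample-count-weighted mean", {
  # two troops, scalar params 0 and 4, counts (1, 3) -> 3
  expect_equal(federatedAverage(list(list(w = 0), list(w = 4)),
                                c(1, 3))$w, 3)
  # three troops, params (1, 2, 6), counts (2, 3, 5) -> 3.8
  expect_equal(federatedAverage(list(list(w = 1), list(w = 2), list(w = 6)),
                                c(2, 3, 5))$w, 3.8)
  # identical parameters are an exact fixed point
  p <- list(W = matrix(runif(6), 2, 3), b = runif(2))
  agg <- federatedAverage(list(p, p, p, p, p), rep(7, 5))
  expect_identical(agg, p)
  # weights implicitly sum to one: averaging constants returns the constant
  expect_equal(federatedAverage(list(list(w = 5), list(w = 5)), c(2, 9))$w, 5)
  expect_error(federatedAverage(list(), 1), "non-empty")
  expect_error(federatedAverage(list(list(w = 1), list(w = 1:2)), c(1, 1)),
               "shape-identical")
  expect_error(federatedAverage(list(list(w = 1)), 0), "positive")
})

test_that("a zero-epoch local update returns the broadcast parameters", {
  ns <- asNamespace("RamanForge")
  x <- intensities(tiny_set(n = 6, length = 32))
  cfg <- tiny_gan_cfg(epochs = 1, seed = 2)
  global <- ns$gan_init(cfg)
  agg <- ns$.fed_get(global, "gan")
  troop <- list(troop_id = 1, state = ns$gan_init(tiny_gan_cfg(seed = 99)),
                data = 2 * x - 1, s = ncol(x))
  up <- localUpdate(troop, agg, local_epochs = 0, model_kind = "gan")
  expect_identical(ns$nn_trainable(up$state$G), agg$trainable$G)
  expect_identical(ns$nn_trainable(up$state$D), agg$trainable$D)
})

test_that("single-troop federation reproduces centralized training bitwise", {
  ns <- asNamespace("RamanForge")
  x <- intensities(tiny_set(n = 10, length = 32))
  cfg <- tiny_gan_cfg(epochs = 1, seed = 5)
  fed <- runFederatedTraining(list(x), "gan",
                              federatedConfig(1, rounds = 3), cfg)
  central <- trainGAN(x, cfg, epochs = 3)
  expect_identical(ns$nn_trainable(fed$global$G), ns$nn_trainable(central$G))
  expect_identical(ns$nn_trainable(fed$global$D), ns$nn_trainable(central$D))
  expect_identical(ns$nn_buffers(fed$global$G), ns$nn_buffers(central$G))
  # and the two produce identical spectra
  expect_identical(intensities(sampleGenerator(fed$global, 3, rng_seed = 1)),
                   intensities(sampleGenerator(central, 3, rng_seed = 1)))
})

test_that("multi-troop federation trains, aggregates with equal weights and
           keeps raw data out of the aggregator", {
  x <- lapply(1:3, function(i)
    intensities(tiny_set(n = 5, length = 32, seed = i)))
  cfg <- tiny_gan_cfg(epochs = 1, seed = 4)
  res <- runFederatedTraining(x, "gan", federatedConfig(3, rounds = 2), cfg)
  expect_equal(res$rounds_run, 2L)
  expect_equal(unique(res$history$weight), 1 / 3)
  expect_true(all(is.finite(res$history$local_loss)))
  # the aggregation interface accepts only parameter lists and counts:
  # a SpectrumSet (or any non-conforming container) is rejected
  expect_error(federatedAverage(list(tiny_set(2, 32), tiny_set(2, 32)),
                                c(1, 1)))
})

test_that("federated DAE training runs and matches its centralized twin", {
  ns <- asNamespace("RamanForge")
  x <- intensities(tiny_set(n = 12, length = 32, noise = 0))
  cfg <- tiny_dae_cfg(len = 32, epochs = 1, seed = 6)
  fed <- runFederatedTraining(list(x), "dae",
                              federatedConfig(1, rounds = 2), cfg)
  central <- trainDAE(x, cfg, epochs = 2)
  expect_identical(ns$nn_trainable(fed$global$model),
                   ns$nn_trainable(central$model))
})
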