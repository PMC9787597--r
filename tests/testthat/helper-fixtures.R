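# Shared fixtures: tiny synthetic spectrum sets and miniature model configs
# so unit tests stay fast; realistic scales live in test-acceptance.R.

tiny_library <- function(n_classes = 1, length = 64, seed = 1)
  makeClassLibrary(n_classes, length = length, rng_seed = seed)

tiny_set <- function(n = 8, length = 64, noise = 0.01, seed = 1,
                     label = "class_1") {
  lib <- tiny_library(length = length, seed = seed)
  makeDataset(lib[[1]], n = n, length = length, noise_sigma = noise,
              label = label, rng_seed = seed)
}

# smallest legal GAN: datasize 32 (divisible by 16), 4-channel base width
tiny_gan_cfg <- function(epochs = 2, seed = 1, datasize = 32L)
  ganConfig(datasize, noise_size = 5L, base_channels = 4L,
            epochs = epochs, rng_seed = seed)

tiny_dae_cfg <- function(len = 32L, epochs = 5, seed = 1, sigma = 0.05)
  daeConfig(len, corruption_sigma = sigma, epochs = epochs, rng_seed = seed)

expect_same_numeric <- function(a, b, tol = 1e-12)
  expect_true(max(abs(a - b)) <= tol)
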