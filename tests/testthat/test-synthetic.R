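test_that("makeSpectrum builds peaks with the stated analytic shapes", {
  # no signal sources at all: an all-zero vector
  expect_equal(makeSpectrum(list(), length = 16), rep(0, 16))

  # Lorentzian HWHM: intensity at center + width is half the peak height
  # (on the raw kernel, a/(1 + ((x - c)/w)^2) evaluated analytically)
  s <- makeSpectrum(list(peakModel(100, 1, 5)), length = 256,
                    normalize = FALSE)
  expect_equal(s[106], s[101] / 2, tolerance = 1e-9)   # 0-based 105 vs 100
  expect_equal(s[101], 1)

  # Gaussian kernel: maximum at the center, symmetric about it
  g <- makeSpectrum(list(peakModel(8, 1, 2, shape = "gaussian")),
                    length = 16, normalize = FALSE)
  expect_equal(which.max(g), 9L)
  expect_equal(g[9 - 3], g[9 + 3], tolerance = 1e-12)
  expect_equal(g[9 + 2], g[9] / 2, tolerance = 1e-12)  # HWHM for Gaussian too

  expect_error(makeSpectrum(list(peakModel(20, 1, 2)), length = 16),
               "out of range")
})

test_that("min-max normalization hits 0 and 1 exactly on non-constant signal", {
  s <- makeSpectrum(list(peakModel(30, 1, 4)), length = 64,
                    baseline_amp = 0.2, noise_sigma = 0.05, rng_seed = 3)
  expect_equal(min(s), 0)
  expect_equal(max(s), 1)
})

test_that("spectrum generation is deterministic and seed-sensitive", {
  a <- makeSpectrum(list(peakModel(10, 1, 2)), 64, 0.1, 0.02, rng_seed = 5)
  b <- makeSpectrum(list(peakModel(10, 1, 2)), 64, 0.1, 0.02, rng_seed = 5)
  c <- makeSpectrum(list(peakModel(10, 1, 2)), 64, 0.1, 0.02, rng_seed = 6)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("class libraries are reproducible with distinct peak positions", {
  lib1 <- makeClassLibrary(4, length = 2688, rng_seed = 0)
  lib2 <- makeClassLibrary(4, length = 2688, rng_seed = 0)
  expect_identical(lib1, lib2)
  expect_length(lib1, 4L)

  centers <- lapply(lib1, function(cl)
    vapply(cl, `[[`, numeric(1), "center"))
  for (i in 1:3) for (j in (i + 1):4) {
    hits <- vapply(centers[[i]], function(c0)
      any(abs(centers[[j]] - c0) <= 2), logical(1))
    expect_lte(mean(hits), 0.5)
  }

  lib3 <- makeClassLibrary(2, length = 256, peaks_per_class = c(5, 5),
                           rng_seed = 2)
  expect_true(all(lengths(lib3) == 5L))
})

test_that("datasets are template plus iid noise of the requested level", {
  lib <- tiny_library(length = 128, seed = 2)
  # noiseless replicates are identical
  d0 <- makeDataset(lib[[1]], n = 3, length = 128, noise_sigma = 0,
                    rng_seed = 4)
  x0 <- intensities(d0)
  expect_identical(x0[, 1], x0[, 2])
  expect_identical(x0[, 1], x0[, 3])

  # noisy replicates: residual sd around the template within 20%
  dn <- makeDataset(lib[[1]], n = 50, length = 128, noise_sigma = 0.02,
                    rng_seed = 4)
  resid <- intensities(dn) - x0[, 1]
  expect_lt(abs(sd(resid) - 0.02) / 0.02, 0.2)
  expect_equal(unique(spectrumLabels(dn)), "class_1")

  # reproducible at the operating-point count
  d100a <- makeDataset(lib[[1]], n = 100, length = 128, rng_seed = 9)
  d100b <- makeDataset(lib[[1]], n = 100, length = 128, rng_seed = 9)
  expect_identical(intensities(d100a), intensities(d100b))
  expect_equal(nSpectra(d100a), 100L)
})
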