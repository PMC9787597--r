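test_that("Gaussian moments use the n-1 divisor plus the ridge", {
  m <- estimateMoments(matrix(c(0, 2), 1, 2), epsilon = 1e-6)
  expect_equal(as.numeric(m$m), 1)
  expect_equal(as.numeric(m$C), 2 + 1e-6)
  ident <- estimateMoments(matrix(1, 4, 3), epsilon = 1e-6)
  expect_equal(ident$C, diag(1e-6, 4), ignore_attr = TRUE)
  expect_error(estimateMoments(matrix(1, 4, 1)), "at least 2")
})

test_that("moments of simulated Gaussian data are recovered", {
  set.seed(10)
  S <- matrix(c(2, 1, 0, 1, 2, 0.5, 0, 0.5, 1), 3, 3)
  R <- chol(S)
  x <- t(crossprod(R, matrix(rnorm(3 * 500), 3, 500)) + c(1, -2, 0))
  mom <- estimateMoments(t(x))
  expect_lt(max(abs(mom$m - c(1, -2, 0))), 0.15)
  expect_lt(max(abs(mom$C - S)), 0.3)
})

test_that("Frechet distance closed forms, symmetry and non-negativity", {
  gm <- function(m, C) structure(list(m = m, C = as.matrix(C)),
                                 class = "GaussianMoments")
  a <- gm(0, 1); b <- gm(1, 4)
  expect_lt(abs(frechetDistance(a, a)), 1e-8)
  # 1-channel closed form: (0-1)^2 + 1 + 4 - 2*sqrt(4) = 2
  expect_equal(frechetDistance(a, b), 2, tolerance = 1e-10)
  expect_equal(frechetDistance(a, b), frechetDistance(b, a),
               tolerance = 1e-10)
  # random scalar cases against the closed form
  set.seed(4)
  for (i in 1:20) {
    m1 <- rnorm(1); m2 <- rnorm(1); c1 <- runif(1, .1, 3); c2 <- runif(1, .1, 3)
    expect_equal(frechetDistance(gm(m1, c1), gm(m2, c2)),
                 (m1 - m2)^2 + c1 + c2 - 2 * sqrt(c1 * c2),
                 tolerance = 1e-8)
  }
  expect_error(frechetDistance(a, gm(c(0, 0), diag(2))), "dimension")
})

test_that("multivariate Frechet distance agrees with an independent
           matrix-square-root implementation", {
  gm <- function(m, C) structure(list(m = m, C = C),
                                 class = "GaussianMoments")
  set.seed(11)
  for (i in 1:10) {
    A <- matrix(rnorm(9), 3, 3); C1 <- crossprod(A) + diag(0.1, 3)
    B <- matrix(rnorm(9), 3, 3); C2 <- crossprod(B) + diag(0.1, 3)
    m1 <- rnorm(3); m2 <- rnorm(3)
    ref <- sum((m1 - m2)^2) +
      sum(diag(C1 + C2 - 2 * pracma::sqrtm(C1 %*% C2)$B))
    expect_equal(frechetDistance(gm(m1, C1), gm(m2, C2)), Re(ref),
                 tolerance = 1e-6)
  }
})

test_that("Pearson correlation formula cases and invariances", {
  expect_equal(pearsonCC(1:5, 1:5), 1)
  expect_equal(pearsonCC(1:3, 3:1), -1)
  expect_equal(pearsonCC(c(1, 2, 3), c(1, 2, 4)), 9 / sqrt(84),
               tolerance = 1e-12)
  expect_error(pearsonCC(c(1, 1, 1), 1:3), "constant")
  set.seed(2)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(pearsonCC(2.5 * x + 7, y), pearsonCC(x, y), tolerance = 1e-12)
  expect_equal(pearsonCC(-x, y), -pearsonCC(x, y), tolerance = 1e-12)
})

test_that("Euclidean distance cases and the triangle inequality", {
  expect_equal(euclideanDist(c(0, 0), c(3, 4)), 5)
  expect_equal(euclideanDist(1:4, 1:4), 0)
  expect_equal(euclideanDist(c(1, 1, 1), c(2, 3, 5)), sqrt(21))
  expect_error(euclideanDist(1:3, 1:4), "length")
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(6); c <- rnorm(6)
    expect_lte(euclideanDist(a, c),
               euclideanDist(a, b) + euclideanDist(b, c) + 1e-12)
  }
})

test_that("set-level evaluation composes the three indices sensibly", {
  set.seed(8)
  real <- matrix(runif(40 * 20), 40, 20)
  rep0 <- evaluateGeneration(real, real, composition_label = "DA-ZP-GAN-DAE-RZP")
  expect_lt(rep0$fid, 1e-6)
  expect_true(is.finite(rep0$pcc) && is.finite(rep0$ed))
  expect_equal(rep0$composition_label, "DA-ZP-GAN-DAE-RZP")

  # constant offset: PCC unchanged, ED grows with the offset
  off <- evaluateGeneration(real, real + 2)
  expect_equal(off$pcc, rep0$pcc, tolerance = 1e-10)
  expect_gt(off$ed, rep0$ed)
  off5 <- evaluateGeneration(real, real + 5)
  expect_gt(off5$ed, off$ed)

  # principal-component projection keeps the identity case at zero
  repk <- evaluateGeneration(real, real, fid_dims = 5)
  expect_lt(repk$fid, 1e-6)
  expect_error(evaluateGeneration(real, real[1:10, ]), "lengths differ")
})
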