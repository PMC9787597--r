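# The engine behind the GAN/DAE: analytic backprop checked against numerical
# gradients, and the stride/kernel length algebra of both convolution types.

ns <- asNamespace("RamanForge")

test_that("backpropagation matches numerical gradients on a mixed net", {
  set.seed(42)
  net <- ns$nn_sequential(
    ns$nn_conv1d(2, 3, 4, 2, 1, bias = TRUE, init = "uniform"),
    ns$nn_batchnorm1d(3),
    ns$nn_act("lrelu"),
    ns$nn_tconv1d(3, 2, 4, 2, 1, bias = TRUE, init = "uniform"),
    ns$nn_act("tanh"),
    ns$nn_conv1d(2, 2, 4, 1, 0, bias = TRUE, init = "uniform"),
    ns$nn_act("relu"),
    ns$nn_maxpool1d(2),
    ns$nn_dense(2 * 6, 3))
  x0 <- array(rnorm(2 * 16 * 4), c(2, 16, 4))
  tgt <- matrix(rnorm(3 * 4), 3, 4)
  lossfun <- function(model) {
    f <- ns$nn_model_fwd(model, x0, TRUE)
    sum((matrix(f$y, 3, 4) - tgt)^2) / 2
  }
  f <- ns$nn_model_fwd(net, x0, TRUE)
  bw <- ns$nn_model_bwd(f$model, f$caches,
                        array(matrix(f$y, 3, 4) - tgt, dim(f$y)))
  ga <- ns$nn_flatten_grads(f$model, bw$grads)
  p <- ns$nn_trainable(net)
  eps <- 1e-5
  for (nm in names(p)) {
    gnum <- p[[nm]] * 0
    for (i in seq_along(p[[nm]])) {
      p2 <- p
      p2[[nm]][i] <- p2[[nm]][i] + eps
      l1 <- lossfun(ns$nn_set_trainable(net, p2))
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      l0 <- lossfun(ns$nn_set_trainable(net, p2))
      gnum[i] <- (l1 - l0) / (2 * eps)
    }
    expect_lt(max(abs(gnum - ga[[nm]])), 1e-6)
  }
  # gradient w.r.t. the input as well
  gx <- bw$dx
  gxn <- x0 * 0
  for (i in seq_along(x0)) {
    xp <- x0; xp[i] <- xp[i] + eps
    l1 <- { f1 <- ns$nn_model_fwd(net, xp, TRUE)
            sum((matrix(f1$y, 3, 4) - tgt)^2) / 2 }
    xp[i] <- xp[i] - 2 * eps
    l0 <- { f0 <- ns$nn_model_fwd(net, xp, TRUE)
            sum((matrix(f0$y, 3, 4) - tgt)^2) / 2 }
    gxn[i] <- (l1 - l0) / (2 * eps)
  }
  expect_lt(max(abs(gxn - gx)), 1e-6)
})

test_that("stride-2 layers halve/double the length exactly", {
  for (L in c(32L, 64L, 160L)) {
    conv <- ns$nn_conv1d(1, 2, 4, 2, 1)
    y <- ns$nn_layer_fwd(conv, array(rnorm(L * 2), c(1, L, 2)), TRUE)$y
    expect_equal(dim(y), c(2L, L %/% 2L, 2L))
    tconv <- ns$nn_tconv1d(2, 1, 4, 2, 1)
    z <- ns$nn_layer_fwd(tconv, y, TRUE)$y
    expect_equal(dim(z), c(1L, L, 2L))
  }
})

test_that("transposed convolution is the exact adjoint of convolution", {
  # <conv(x), y> == <x, tconv(y)> when the two share one weight layout
  set.seed(7)
  K <- 4L; s <- 2L; p <- 1L; Cin <- 3L; Cout <- 2L; L <- 12L
  W <- matrix(rnorm(Cout * Cin * K, 0, 0.5), Cout, Cin * K)
  conv <- ns$nn_conv1d(Cin, Cout, K, s, p); conv$W <- W
  # tconv weight layout (C_in, C_out*K) maps to the same kernel when built
  # from the conv weight: tW[co_in = Cout -> rows swap]
  tconv <- ns$nn_tconv1d(Cout, Cin, K, s, p)
  tW <- matrix(0, Cout, Cin * K)
  for (k in seq_len(K))
    tW[, ((k - 1) * Cin + 1):(k * Cin)] <-
      W[, ((k - 1) * Cin + 1):(k * Cin)]
  tconv$W <- tW
  x <- array(rnorm(Cin * L), c(Cin, L, 1))
  y <- array(rnorm(Cout * (L / 2)), c(Cout, L / 2, 1))
  cx <- ns$nn_layer_fwd(conv, x, TRUE)$y
  ty <- ns$nn_layer_fwd(tconv, y, TRUE)$y
  expect_equal(sum(cx * y), sum(x * ty), tolerance = 1e-10)
})

test_that("max pooling picks block maxima and routes gradients to them", {
  x <- array(c(3, 1, 4, 1, 5, 9, 2, 6), c(1, 8, 1))
  mp <- ns$nn_maxpool1d(4L)
  f <- ns$nn_layer_fwd(mp, x, TRUE)
  expect_equal(as.numeric(f$y), c(4, 9))
  bw <- ns$nn_layer_bwd(mp, f$cache, array(c(10, 20), c(1, 2, 1)))
  expect_equal(as.numeric(bw$dx), c(0, 0, 10, 0, 0, 20, 0, 0))
})

test_that("optimizer updates follow the RMSprop and Adam recurrences", {
  p <- list(w = 1)
  g <- list(w = 2)
  opt <- ns$opt_init("rmsprop", p, lr = 0.01)
  su <- ns$opt_step(opt, p, g)
  v <- 0.01 * 4
  expect_equal(su$params$w, 1 - 0.01 * 2 / (sqrt(v) + 1e-8), tolerance = 1e-12)
  # clipping clamps the updated value
  su2 <- ns$opt_step(opt, p, g, clip = 0.5)
  expect_equal(su2$params$w, 0.5)

  opt <- ns$opt_init("adam", p, lr = 0.1)
  su <- ns$opt_step(opt, p, g)
  mh <- 0.2 / (1 - 0.9); vh <- 0.004 / (1 - 0.999)
  expect_equal(su$params$w, 1 - 0.1 * mh / (sqrt(vh) + 1e-8),
               tolerance = 1e-12)
})
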