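# Internal 1-D neural-network engine.
#
# Layers operate on arrays of shape (channels, length, batch).  Convolutions
# are expressed as im2col/col2im gather/scatter plus BLAS matrix products,
# with the hot kernels compiled in src/conv1d.cpp; the transposed convolution
# is the exact adjoint of the convolution, so the two share those primitives.
# Backpropagation is hand-derived and verified against numerical gradients in
# the test suite.
#
# Weight layout:
#   conv1d:  W is (C_out, C_in*K),  column index = ci + C_in *(k-1)
#   tconv1d: W is (C_in, C_out*K),  column index = co + C_out*(k-1)
# matching the row layout of the im2col matrix (channel fastest, kernel
# position slower), so a single matrix product performs the whole layer.

# ---- layer constructors -----------------------------------------------------

# init = "dcgan": N(0, 0.02) weights (GAN convention); "uniform": PyTorch-style
# U(-1/sqrt(fan_in), 1/sqrt(fan_in)) for conv + bias.
nn_conv1d <- function(C_in, C_out, K, stride = 1L, pad = 0L, bias = FALSE,
                      init = "dcgan") {
  n <- C_out * C_in * K
  W <- if (init == "dcgan") matrix(rnorm(n, 0, 0.02), C_out, C_in * K)
       else matrix(runif(n, -1, 1) / sqrt(C_in * K), C_out, C_in * K)
  b <- if (bias) runif(C_out, -1, 1) / sqrt(C_in * K) else NULL
  list(type = "conv1d", C_in = C_in, C_out = C_out, K = as.integer(K),
       stride = as.integer(stride), pad = as.integer(pad), W = W, b = b)
}

nn_tconv1d <- function(C_in, C_out, K, stride = 1L, pad = 0L, bias = FALSE,
                       init = "dcgan") {
  n <- C_in * C_out * K
  W <- if (init == "dcgan") matrix(rnorm(n, 0, 0.02), C_in, C_out * K)
       else matrix(runif(n, -1, 1) / sqrt(C_in * K), C_in, C_out * K)
  b <- if (bias) runif(C_out, -1, 1) / sqrt(C_in * K) else NULL
  list(type = "tconv1d", C_in = C_in, C_out = C_out, K = as.integer(K),
       stride = as.integer(stride), pad = as.integer(pad), W = W, b = b)
}

nn_batchnorm1d <- function(C, eps = 1e-5, momentum = 0.1) {
  list(type = "batchnorm1d", C = C, eps = eps, momentum = momentum,
       gamma = rnorm(C, 1, 0.02), beta = numeric(C),
       run_mean = numeric(C), run_var = rep(1, C))
}

nn_act <- function(kind, slope = 0.2)
  list(type = "act", kind = kind, slope = slope)

nn_maxpool1d <- function(K) list(type = "maxpool1d", K = as.integer(K))

nn_dense <- function(n_in, n_out) {
  list(type = "dense", n_in = n_in, n_out = n_out,
       W = matrix(runif(n_out * n_in, -1, 1) / sqrt(n_in), n_out, n_in),
       b = runif(n_out, -1, 1) / sqrt(n_in))
}

# ---- per-layer forward / backward ------------------------------------------

nn_layer_fwd <- function(layer, x, training) {
  B <- dim(x)[3]
  switch(layer$type,
    conv1d = {
      L_in <- dim(x)[2]
      res <- conv1d_fwd(x, layer$W, layer$b, layer$K, layer$stride, layer$pad)
      list(y = res$y, layer = layer,
           cache = list(cols = res$cols, L_in = L_in, B = B))
    },
    tconv1d = {
      y <- tconv1d_fwd(x, layer$W, layer$b, layer$K, layer$stride, layer$pad)
      list(y = y, layer = layer, cache = list(z = x, B = B))
    },
    batchnorm1d = {
      res <- batchnorm_fwd(x, layer$gamma, layer$beta, layer$run_mean,
                           layer$run_var, layer$eps, layer$momentum, training)
      if (training) {
        layer$run_mean <- as.numeric(res$run_mean)
        layer$run_var <- as.numeric(res$run_var)
      }
      list(y = res$y, layer = layer,
           cache = list(xhat = res$xhat, istd = as.numeric(res$istd),
                        training = training))
    },
    act = {
      if (layer$kind == "tanh") {
        y <- tanh(x)
        cache <- list(y = y)
      } else {
        # slope + (1-slope)*mask is 1 on the positive side, slope elsewhere
        slope <- if (layer$kind == "relu") 0 else layer$slope
        scale <- slope + (1 - slope) * (x > 0)
        y <- x * scale
        cache <- list(scale = scale)
      }
      list(y = y, layer = layer, cache = cache)
    },
    maxpool1d = {
      d <- dim(x); K <- layer$K
      L_out <- d[2] %/% K
      xs <- x[, seq_len(L_out * K), , drop = FALSE]
      y <- xs[, seq(1L, L_out * K, by = K), , drop = FALSE]
      arg <- array(1L, dim(y))
      for (k in 2:K) {
        cand <- xs[, seq(k, L_out * K, by = K), , drop = FALSE]
        upd <- cand > y
        y[upd] <- cand[upd]
        arg[upd] <- k
      }
      list(y = y, layer = layer,
           cache = list(arg = arg, d = d, L_out = L_out))
    },
    dense = {
      d <- dim(x)
      xm <- x; dim(xm) <- c(d[1] * d[2], d[3])
      y <- layer$W %*% xm + layer$b
      dim(y) <- c(layer$n_out, 1L, d[3])
      list(y = y, layer = layer, cache = list(xm = xm, d = d))
    },
    stop("unknown layer type"))
}

nn_layer_bwd <- function(layer, cache, dy) {
  switch(layer$type,
    conv1d = {
      res <- conv1d_bwd(dy, layer$W, cache$cols, !is.null(layer$b),
                        layer$K, layer$stride, layer$pad, cache$L_in)
      list(dx = res$dx, grads = list(W = res$dW, b = res$db))
    },
    tconv1d = {
      res <- tconv1d_bwd(dy, cache$z, layer$W, !is.null(layer$b),
                         layer$K, layer$stride, layer$pad)
      list(dx = res$dx, grads = list(W = res$dW, b = res$db))
    },
    batchnorm1d = {
      res <- batchnorm_bwd(dy, layer$gamma, cache$xhat, cache$istd,
                           cache$training)
      list(dx = res$dx,
           grads = list(gamma = as.numeric(res$dgamma),
                        beta = as.numeric(res$dbeta)))
    },
    act = {
      dx <- if (layer$kind == "tanh") dy * (1 - cache$y^2)
            else dy * cache$scale
      list(dx = dx, grads = NULL)
    },
    maxpool1d = {
      d <- cache$d; K <- layer$K; L_out <- cache$L_out
      dx <- array(0, d)
      for (k in seq_len(K)) {
        sel <- cache$arg == k
        sub <- dx[, seq(k, L_out * K, by = K), , drop = FALSE]
        sub[sel] <- dy[sel]
        dx[, seq(k, L_out * K, by = K), ] <- sub
      }
      list(dx = dx, grads = NULL)
    },
    dense = {
      d <- cache$d
      dym <- dy; dim(dym) <- c(layer$n_out, d[3])
      dW <- tcrossprod(dym, cache$xm)
      db <- rowSums(dym)
      dx <- crossprod(layer$W, dym)
      dim(dx) <- d
      list(dx = dx, grads = list(W = dW, b = db))
    },
    stop("unknown layer type"))
}

# ---- sequential model -------------------------------------------------------

nn_sequential <- function(...) list(layers = list(...))

nn_model_fwd <- function(model, x, training = TRUE) {
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    res <- nn_layer_fwd(model$layers[[i]], x, training)
    model$layers[[i]] <- res$layer   # batch-norm running stats may update
    caches[[i]] <- res$cache
    x <- res$y
  }
  list(y = x, caches = caches, model = model)
}

nn_model_bwd <- function(model, caches, dy) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    res <- nn_layer_bwd(model$layers[[i]], caches[[i]], dy)
    grads[i] <- list(res$grads)   # [[<-]] with NULL would drop the slot
    dy <- res$dx
  }
  list(grads = grads, dx = dy)
}

.PARAM_NAMES <- c("W", "b", "gamma", "beta")
.BUFFER_NAMES <- c("run_mean", "run_var")

nn_trainable <- function(model) {
  out <- list()
  for (i in seq_along(model$layers))
    for (nm in .PARAM_NAMES)
      if (!is.null(model$layers[[i]][[nm]]))
        out[[sprintf("L%02d.%s", i, nm)]] <- model$layers[[i]][[nm]]
  out
}

nn_set_trainable <- function(model, params) {
  for (key in names(params)) {
    i <- as.integer(substr(key, 2L, 3L))
    nm <- substr(key, 5L, nchar(key))
    model$layers[[i]][[nm]] <- params[[key]]
  }
  model
}

nn_buffers <- function(model) {
  out <- list()
  for (i in seq_along(model$layers))
    for (nm in .BUFFER_NAMES)
      if (!is.null(model$layers[[i]][[nm]]))
        out[[sprintf("L%02d.%s", i, nm)]] <- model$layers[[i]][[nm]]
  out
}

nn_set_buffers <- nn_set_trainable

# grads come back as a per-layer list; flatten to the nn_trainable naming
nn_flatten_grads <- function(model, grads) {
  out <- list()
  for (i in seq_along(grads))
    for (nm in names(grads[[i]]))
      if (!is.null(grads[[i]][[nm]]))
        out[[sprintf("L%02d.%s", i, nm)]] <- grads[[i]][[nm]]
  out
}

nn_add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

# ---- optimizers -------------------------------------------------------------

opt_init <- function(kind, params, lr,
                     alpha = 0.99, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(kind = kind, lr = lr, alpha = alpha, beta1 = beta1, beta2 = beta2,
       eps = eps, t = 0L,
       v = lapply(params, function(p) p * 0),
       m = if (kind == "adam") lapply(params, function(p) p * 0))
}

# clip > 0 additionally clamps every updated parameter into [-clip, clip]
# (the Wasserstein critic's weight clipping, fused into the update pass)
opt_step <- function(opt, params, grads, clip = 0) {
  opt$t <- opt$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (opt$kind == "rmsprop") {
      u <- rmsprop_update(params[[nm]], g, opt$v[[nm]], opt$lr, opt$alpha,
                          opt$eps, clip)
      params[[nm]] <- u$p
      opt$v[[nm]] <- u$v
    } else {                                       # adam
      u <- adam_update(params[[nm]], g, opt$m[[nm]], opt$v[[nm]], opt$lr,
                       opt$beta1, opt$beta2, opt$eps, opt$t)
      params[[nm]] <- u$p
      opt$m[[nm]] <- u$m
      opt$v[[nm]] <- u$v
    }
  }
  list(params = params, opt = opt)
}

# ---- parameter counting -----------------------------------------------------

#' Count trainable parameters of a network
#'
#' Counts every trainable scalar: convolution weights and biases, dense
#' weights and biases, and batch-norm scale/offset pairs.  Batch-norm running
#' statistics are buffers, not trainable scalars, and are excluded, matching
#' the usual deep-learning convention for "# Parameters" columns.
#'
#' @param model a model built by \code{\link{buildCritic}},
#'   \code{\link{buildGenerator}} or \code{\link{buildDAE}} (or any internal
#'   sequential model).
#' @return integer total; see \code{\link{layerParameters}} for the per-layer
#'   breakdown.
#' @examples
#' cfg <- ganConfig(datasize = 2688, epochs = 1)
#' countParameters(buildCritic(cfg))
#' @export
countParameters <- function(model) {
  sum(layerParameters(model)$parameters)
}

#' Per-layer trainable-parameter breakdown
#'
#' @inheritParams countParameters
#' @return data.frame with columns \code{layer}, \code{type},
#'   \code{parameters}.
#' @export
layerParameters <- function(model) {
  rows <- lapply(seq_along(model$layers), function(i) {
    ly <- model$layers[[i]]
    n <- 0L
    for (nm in .PARAM_NAMES) if (!is.null(ly[[nm]])) n <- n + length(ly[[nm]])
    data.frame(layer = i, type = ly$type, parameters = n)
  })
  do.call(rbind, rows)
}
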