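#' Configuration of the 1-D Wasserstein GAN
#'
#' Architecture and training regime of the spectrum generator/critic pair.
#' The critic halves the signal length four times (stride-2 convolutions with
#' kernel 4 and padding 1), then a final convolution with kernel
#' \code{datasize/16} collapses it to one unbounded score, so \code{datasize}
#' must be divisible by 16.  The generator mirrors this with transposed
#' convolutions from a \code{noise_size}-channel standard-normal code.
#' Training follows the Wasserstein scheme: RMSprop at learning rate 1e-4,
#' batch size 8, five critic updates per generator update, and every critic
#' parameter clipped into [-clip_c, clip_c] after each update.
#'
#' @param datasize (padded) spectrum length in channels; must be divisible
#'   by 16.
#' @param noise_size channel count of the generator's noise input.
#' @param base_channels width of the first critic layer; the channel ladder is
#'   1-b-2b-4b-8b-1.  The canonical width is 64; smaller values give a
#'   reduced-width network for scaled-down experiments.
#' @param batch_size minibatch size (default 8).
#' @param lr RMSprop learning rate (default 1e-4).
#' @param clip_c weight-clipping constant (default 0.01).
#' @param critic_updates critic updates per generator update (default 5).
#' @param epochs training epochs (one pass of ceiling(n/batch_size) outer
#'   steps).
#' @param rng_seed integer seed controlling initialization and batching.
#' @return validated list of class \code{"GanConfig"}.
#' @export
ganConfig <- function(datasize, noise_size = 100L, base_channels = 64L,
                      batch_size = 8L, lr = 1e-4, clip_c = 0.01,
                      critic_updates = 5L, epochs = 100L, rng_seed = 1L) {
  datasize <- as.integer(datasize)
  if (datasize %% 16L != 0L)
    stop("'datasize' must be divisible by 16 (four stride-2 halvings)")
  if (noise_size < 1) stop("'noise_size' must be >= 1")
  if (clip_c <= 0) stop("'clip_c' must be > 0")
  structure(list(datasize = datasize, noise_size = as.integer(noise_size),
                 base_channels = as.integer(base_channels),
                 batch_size = as.integer(batch_size), lr = lr,
                 clip_c = clip_c, critic_updates = as.integer(critic_updates),
                 epochs = as.integer(epochs), rng_seed = as.integer(rng_seed)),
            class = "GanConfig")
}

#' Build the critic (discriminator) network
#'
#' Five bias-free 1-D convolutions (channels 1-b-2b-4b-8b-1 with b =
#' \code{base_channels}; kernel 4, stride 2, padding 1 for layers 1-4; kernel
#' \code{datasize/16}, stride 1 for layer 5), batch normalization after layers
#' 2-4, leaky rectifiers (slope 0.2) after layers 1-4, and no final
#' activation: the output is one unbounded Wasserstein score per spectrum.
#'
#' @param cfg a \code{\link{ganConfig}}.
#' @return an internal sequential model; inspect with
#'   \code{\link{layerParameters}}.
#' @export
buildCritic <- function(cfg) {
  stopifnot(inherits(cfg, "GanConfig"))
  b <- cfg$base_channels
  nn_sequential(
    nn_conv1d(1L, b, 4L, 2L, 1L),
    nn_act("lrelu"),
    nn_conv1d(b, 2L * b, 4L, 2L, 1L),
    nn_batchnorm1d(2L * b),
    nn_act("lrelu"),
    nn_conv1d(2L * b, 4L * b, 4L, 2L, 1L),
    nn_batchnorm1d(4L * b),
    nn_act("lrelu"),
    nn_conv1d(4L * b, 8L * b, 4L, 2L, 1L),
    nn_batchnorm1d(8L * b),
    nn_act("lrelu"),
    nn_conv1d(8L * b, 1L, cfg$datasize %/% 16L, 1L, 0L))
}

#' Build the generator network
#'
#' A transposed convolution expands the \code{noise_size}-channel length-1
#' code to 8b channels of length \code{datasize/16}; four stride-2 transposed
#' convolutions (kernel 4, padding 1) then double the length to
#' \code{datasize} while narrowing 8b-4b-2b-b-1.  Batch normalization after
#' layers 1-4, a rectifier after layer 1, leaky rectifiers after layers 2-4,
#' and a hyperbolic-tangent output bounding spectra to [-1, 1].  All
#' convolutions are bias-free.
#'
#' @inheritParams buildCritic
#' @return an internal sequential model.
#' @export
buildGenerator <- function(cfg) {
  stopifnot(inherits(cfg, "GanConfig"))
  b <- cfg$base_channels
  nn_sequential(
    nn_tconv1d(cfg$noise_size, 8L * b, cfg$datasize %/% 16L, 1L, 0L),
    nn_batchnorm1d(8L * b),
    nn_act("relu"),
    nn_tconv1d(8L * b, 4L * b, 4L, 2L, 1L),
    nn_batchnorm1d(4L * b),
    nn_act("lrelu"),
    nn_tconv1d(4L * b, 2L * b, 4L, 2L, 1L),
    nn_batchnorm1d(2L * b),
    nn_act("lrelu"),
    nn_tconv1d(2L * b, b, 4L, 2L, 1L),
    nn_batchnorm1d(b),
    nn_act("lrelu"),
    nn_tconv1d(b, 1L, 4L, 2L, 1L),
    nn_act("tanh"))
}

#' Wasserstein critic and generator losses
#'
#' The critic maximizes the score gap between real and generated spectra, so
#' its minimized loss is \code{-(mean(real_scores) - mean(fake_scores))}; the
#' generator minimizes \code{-mean(fake_scores)}.
#'
#' @param real_scores,fake_scores numeric vectors of critic scores.
#' @return scalar loss.
#' @examples
#' criticLoss(c(1, 1), c(0, 0))   # -1
#' generatorLoss(c(0, 0))         # 0
#' @export
criticLoss <- function(real_scores, fake_scores) {
  if (!length(real_scores) || !length(fake_scores))
    stop("score vectors must be non-empty")
  -(mean(real_scores) - mean(fake_scores))
}

#' @rdname criticLoss
#' @export
generatorLoss <- function(fake_scores) {
  if (!length(fake_scores)) stop("score vector must be non-empty")
  -mean(fake_scores)
}

# fresh GAN training state: models, optimizers, RNG stream, counters
gan_init <- function(cfg) {
  old <- .save_rng()
  set.seed(cfg$rng_seed)
  G <- buildGenerator(cfg)
  D <- buildCritic(cfg)
  st <- list(cfg = cfg, G = G, D = D,
             optG = opt_init("rmsprop", nn_trainable(G), cfg$lr),
             optD = opt_init("rmsprop", nn_trainable(D), cfg$lr),
             rng = get(".Random.seed", envir = globalenv()),
             step = 0L, critic_batches = 0L,
             history = list())
  .restore_rng(old)
  structure(st, class = "ganState")
}

# advance a GAN state by `epochs` passes over x (matrix datasize x n, already
# on the [-1, 1] training scale); continues the state's own RNG stream
gan_run_epochs <- function(state, x, epochs) {
  cfg <- state$cfg
  n <- ncol(x); bs <- cfg$batch_size
  stopifnot(nrow(x) == cfg$datasize)
  steps <- ceiling(n / bs)
  old <- .save_rng(); on.exit(.restore_rng(old))
  assign(".Random.seed", state$rng, envir = globalenv())
  G <- state$G; D <- state$D; optG <- state$optG; optD <- state$optD
  hist <- state$history
  for (e in seq_len(epochs)) {
    for (stp in seq_len(steps)) {
      closs <- NA_real_
      for (j in seq_len(cfg$critic_updates)) {
        idx <- sample.int(n, bs, replace = n < bs)
        xb <- array(x[, idx], c(1L, cfg$datasize, bs))
        z <- array(rnorm(cfg$noise_size * bs), c(cfg$noise_size, 1L, bs))
        fG <- nn_model_fwd(G, z, TRUE); G <- fG$model
        fr <- nn_model_fwd(D, xb, TRUE); D <- fr$model
        ff <- nn_model_fwd(D, fG$y, TRUE); D <- ff$model
        closs <- criticLoss(as.numeric(fr$y), as.numeric(ff$y))
        gr <- nn_add_grads(
          nn_flatten_grads(D, nn_model_bwd(D, fr$caches,
            array(-1 / bs, dim(fr$y)))$grads),
          nn_flatten_grads(D, nn_model_bwd(D, ff$caches,
            array(1 / bs, dim(ff$y)))$grads))
        su <- opt_step(optD, nn_trainable(D), gr, clip = cfg$clip_c)
        optD <- su$opt
        D <- nn_set_trainable(D, su$params)
        state$critic_batches <- state$critic_batches + 1L
      }
      z <- array(rnorm(cfg$noise_size * bs), c(cfg$noise_size, 1L, bs))
      fG <- nn_model_fwd(G, z, TRUE); G <- fG$model
      ff <- nn_model_fwd(D, fG$y, TRUE); D <- ff$model
      gloss <- generatorLoss(as.numeric(ff$y))
      bD <- nn_model_bwd(D, ff$caches, array(-1 / bs, dim(ff$y)))
      bG <- nn_model_bwd(G, fG$caches, bD$dx)
      su <- opt_step(optG, nn_trainable(G), nn_flatten_grads(G, bG$grads))
      optG <- su$opt
      G <- nn_set_trainable(G, su$params)
      state$step <- state$step + 1L
      hist[[length(hist) + 1L]] <-
        c(step = state$step, critic_loss = closs, gen_loss = gloss)
    }
  }
  state$G <- G; state$D <- D; state$optG <- optG; state$optD <- optD
  state$history <- hist
  state$rng <- get(".Random.seed", envir = globalenv())
  state
}

#' Train the 1-D Wasserstein GAN
#'
#' Spectra (on the [0, 1] intensity scale) are rescaled to [-1, 1] to match
#' the generator's tanh output.  Each outer step performs
#' \code{cfg$critic_updates} critic updates -- every one followed by clipping
#' all critic parameters into [-clip_c, clip_c] -- and then one generator
#' update, per the Wasserstein training scheme.  Fully deterministic for a
#' fixed \code{cfg$rng_seed}.
#'
#' @param data a \linkS4class{SpectrumSet} or intensity matrix
#'   (channels x spectra) on the [0, 1] scale; all spectra must have length
#'   \code{cfg$datasize}.
#' @param cfg a \code{\link{ganConfig}}.
#' @param state optional \code{"ganState"} from a previous call; training then
#'   resumes (models, optimizer moments and RNG stream continue).
#' @param epochs number of epochs to run (defaults to \code{cfg$epochs}).
#' @return a \code{"ganState"} list with elements \code{G}, \code{D},
#'   \code{history} (data frame of per-step critic/generator losses),
#'   \code{critic_batches}, and internal optimizer/RNG state.
#' @examples
#' \donttest{
#' lib <- makeClassLibrary(1, length = 64, rng_seed = 1)
#' ds <- makeDataset(lib[[1]], n = 16, length = 64, rng_seed = 1)
#' st <- trainGAN(ds, ganConfig(64, base_channels = 8, epochs = 2))
#' }
#' @export
trainGAN <- function(data, cfg, state = NULL, epochs = NULL) {
  x <- if (is(data, "SpectrumSet")) intensities(data) else data
  if (nrow(x) != cfg$datasize)
    stop("spectra have length ", nrow(x), " but cfg$datasize is ",
         cfg$datasize)
  xs <- 2 * x - 1
  if (is.null(state)) state <- gan_init(cfg)
  gan_run_epochs(state, xs, if (is.null(epochs)) cfg$epochs else epochs)
}

#' Sample spectra from a trained generator
#'
#' Draws standard-normal noise codes, runs the generator in evaluation mode
#' (batch-norm running statistics), and maps the tanh output back from
#' [-1, 1] to the [0, 1] intensity scale.
#'
#' @param state a \code{"ganState"} (or a bare generator model).
#' @param n number of spectra to draw.
#' @param rng_seed optional seed; when given, the caller's RNG stream is left
#'   untouched.
#' @param cfg required only when passing a bare generator model.
#' @return a \linkS4class{SpectrumSet} of \code{n} generated spectra labeled
#'   \code{"generated"}.
#' @export
sampleGenerator <- function(state, n, rng_seed = NULL, cfg = NULL) {
  if (n < 1) stop("'n' must be >= 1")
  if (inherits(state, "ganState")) { G <- state$G; cfg <- state$cfg }
  else G <- state
  if (is.null(cfg)) stop("'cfg' is required with a bare generator model")
  if (!is.null(rng_seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(rng_seed)
  }
  z <- array(rnorm(cfg$noise_size * n), c(cfg$noise_size, 1L, n))
  y <- nn_model_fwd(G, z, training = FALSE)$y
  m <- matrix(y, cfg$datasize, n)
  SpectrumSet((m + 1) / 2, label = "generated")
}

#' @export
print.ganState <- function(x, ...) {
  cat("1-D Wasserstein GAN state\n")
  cat("  datasize:", x$cfg$datasize, " noise:", x$cfg$noise_size,
      " base channels:", x$cfg$base_channels, "\n")
  cat("  generator parameters:", countParameters(x$G), "\n")
  cat("  critic parameters:   ", countParameters(x$D), "\n")
  cat("  outer steps run:", x$step,
      " critic batches seen:", x$critic_batches, "\n")
  invisible(x)
}

# history as a data.frame
ganHistory <- function(state) {
  do.call(rbind, lapply(state$history, function(r)
    data.frame(step = r[["step"]], critic_loss = r[["critic_loss"]],
               gen_loss = r[["gen_loss"]])))
}
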