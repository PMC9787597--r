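#' Configuration of the convolutional denoising autoencoder
#'
#' The encoder applies three 1-D convolutions (channels 1-4-16-32, kernel 4,
#' stride 1, with bias), each shortening the signal by 3 channels; the decoder
#' mirrors it with three transposed convolutions (32-16-4-1), so the output
#' length equals the input length exactly (-9 then +9).  Training corrupts
#' clean spectra with additive Gaussian noise and minimizes the mean squared
#' error of the reconstruction against the clean original, with Adam at
#' learning rate 1e-3 and batch size 10.
#'
#' @param input_length spectrum length the DAE operates on; must exceed 9.
#' @param corruption_sigma sd of the Gaussian corruption added during
#'   training.  Defaults to 0.01, the jitter-noise bound of
#'   \code{\link{augmentationConfig}}, since the amplified jitter noise is
#'   what the DAE must remove.
#' @param batch_size minibatch size (default 10).
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs training epochs.
#' @param rng_seed integer seed.
#' @return validated list of class \code{"DaeConfig"}.
#' @export
daeConfig <- function(input_length, corruption_sigma = 0.01, batch_size = 10L,
                      lr = 1e-3, epochs = 100L, rng_seed = 1L) {
  input_length <- as.integer(input_length)
  if (input_length <= 9L)
    stop("'input_length' must exceed 9 (three kernel-4 contractions)")
  if (corruption_sigma < 0) stop("'corruption_sigma' must be >= 0")
  structure(list(input_length = input_length,
                 corruption_sigma = corruption_sigma,
                 batch_size = as.integer(batch_size), lr = lr,
                 epochs = as.integer(epochs), rng_seed = as.integer(rng_seed)),
            class = "DaeConfig")
}

#' Corrupt spectra with additive Gaussian noise
#'
#' The corruption distribution q(x~|x) used for denoising-autoencoder
#' training: x~ = x + iid N(0, sigma^2).
#'
#' @param x numeric vector, matrix (channels x spectra) or
#'   \linkS4class{SpectrumSet}.
#' @param sigma noise standard deviation, >= 0.
#' @return corrupted object of the same shape/type.
#' @export
corruptSpectra <- function(x, sigma) {
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (is(x, "SpectrumSet"))
    return(.respectra(x, corruptSpectra(intensities(x), sigma)))
  if (sigma == 0) return(x)
  x + rnorm(length(x), sd = sigma)
}

#' Build the denoising autoencoder network
#'
#' @param cfg a \code{\link{daeConfig}}.
#' @return an internal sequential model: encoder convolutions 1-4-16-32 then
#'   decoder transposed convolutions 32-16-4-1, all kernel 4, stride 1, with
#'   bias; rectifiers between layers and a linear output so denoised
#'   intensities are not clipped.
#' @export
buildDAE <- function(cfg) {
  stopifnot(inherits(cfg, "DaeConfig"))
  nn_sequential(
    nn_conv1d(1L, 4L, 4L, 1L, 0L, bias = TRUE, init = "uniform"),
    nn_act("relu"),
    nn_conv1d(4L, 16L, 4L, 1L, 0L, bias = TRUE, init = "uniform"),
    nn_act("relu"),
    nn_conv1d(16L, 32L, 4L, 1L, 0L, bias = TRUE, init = "uniform"),
    nn_act("relu"),
    nn_tconv1d(32L, 16L, 4L, 1L, 0L, bias = TRUE, init = "uniform"),
    nn_act("relu"),
    nn_tconv1d(16L, 4L, 4L, 1L, 0L, bias = TRUE, init = "uniform"),
    nn_act("relu"),
    nn_tconv1d(4L, 1L, 4L, 1L, 0L, bias = TRUE, init = "uniform"))
}

dae_init <- function(cfg) {
  old <- .save_rng()
  set.seed(cfg$rng_seed)
  model <- buildDAE(cfg)
  st <- list(cfg = cfg, model = model,
             opt = opt_init("adam", nn_trainable(model), cfg$lr),
             rng = get(".Random.seed", envir = globalenv()),
             history = list())
  .restore_rng(old)
  structure(st, class = "daeState")
}

dae_run_epochs <- function(state, clean, epochs) {
  cfg <- state$cfg
  n <- ncol(clean); bs <- cfg$batch_size
  stopifnot(nrow(clean) == cfg$input_length)
  old <- .save_rng(); on.exit(.restore_rng(old))
  assign(".Random.seed", state$rng, envir = globalenv())
  model <- state$model; opt <- state$opt; hist <- state$history
  for (e in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = bs)
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + bs - 1L, n)]
      b <- length(idx)
      xb <- clean[, idx, drop = FALSE]
      noisy <- xb + rnorm(length(xb), sd = cfg$corruption_sigma)
      xin <- array(noisy, c(1L, cfg$input_length, b))
      f <- nn_model_fwd(model, xin, TRUE); model <- f$model
      resid <- f$y - array(xb, c(1L, cfg$input_length, b))
      loss <- mean(resid^2)
      bwd <- nn_model_bwd(model, f$caches, 2 * resid / length(resid))
      su <- opt_step(opt, nn_trainable(model), nn_flatten_grads(model, bwd$grads))
      opt <- su$opt
      model <- nn_set_trainable(model, su$params)
      hist[[length(hist) + 1L]] <- loss
    }
  }
  state$model <- model; state$opt <- opt; state$history <- hist
  state$rng <- get(".Random.seed", envir = globalenv())
  state
}

#' Train the denoising autoencoder
#'
#' Each step draws a minibatch of clean spectra, corrupts it with fresh
#' Gaussian noise of sd \code{cfg$corruption_sigma}, and takes an Adam step on
#' the mean squared error between the reconstruction and the clean batch.
#' Deterministic for a fixed \code{cfg$rng_seed}.
#'
#' @param clean a \linkS4class{SpectrumSet} or matrix (channels x spectra) of
#'   clean spectra on the [0, 1] scale.
#' @param cfg a \code{\link{daeConfig}}.
#' @param state optional \code{"daeState"} to resume from.
#' @param epochs epochs to run (defaults to \code{cfg$epochs}).
#' @return a \code{"daeState"} with elements \code{model}, \code{history}
#'   (per-step MSE losses) and internal optimizer/RNG state.
#' @export
trainDAE <- function(clean, cfg, state = NULL, epochs = NULL) {
  x <- if (is(clean, "SpectrumSet")) intensities(clean) else clean
  if (nrow(x) != cfg$input_length)
    stop("spectra have length ", nrow(x), " but cfg$input_length is ",
         cfg$input_length)
  if (is.null(state)) state <- dae_init(cfg)
  dae_run_epochs(state, x, if (is.null(epochs)) cfg$epochs else epochs)
}

#' Denoise spectra with a trained autoencoder
#'
#' A deterministic forward pass; the output has exactly the input length
#' (the encoder's -9 channels are restored by the decoder's +9).
#'
#' @param state a \code{"daeState"} from \code{\link{trainDAE}}.
#' @param x a \linkS4class{SpectrumSet} or matrix (channels x spectra) with
#'   spectrum length \code{cfg$input_length}.
#' @return denoised object of the same type and shape.
#' @export
denoise <- function(state, x) {
  stopifnot(inherits(state, "daeState"))
  if (is(x, "SpectrumSet"))
    return(.respectra(x, denoise(state, intensities(x))))
  if (nrow(x) != state$cfg$input_length)
    stop("spectra have length ", nrow(x), " but the DAE was built for ",
         state$cfg$input_length)
  xin <- array(x, c(1L, nrow(x), ncol(x)))
  y <- nn_model_fwd(state$model, xin, training = FALSE)$y
  matrix(y, nrow(x), ncol(x))
}

#' @export
print.daeState <- function(x, ...) {
  cat("Denoising autoencoder state\n")
  cat("  input length:", x$cfg$input_length,
      " corruption sigma:", x$cfg$corruption_sigma, "\n")
  cat("  parameters:", countParameters(x$model), "\n")
  cat("  steps run:", length(x$history), "\n")
  invisible(x)
}
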