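#' Random-transformation augmentation configuration
#'
#' Jittering adds iid Gaussian noise whose standard deviation is itself drawn
#' uniformly from [0, \code{sigma_max}] for every augmented spectrum, so the
#' augmented set spans noise levels "ranging from 0 to a predetermined value".
#' Shifting translates the whole spectrum horizontally by a displacement drawn
#' uniformly from the integers [-\code{shift_scale}, +\code{shift_scale}],
#' filling vacated channels with zeros.  When both methods are enabled the
#' shift is applied first so the noise is not translated.
#'
#' @param sigma_max upper bound of the jitter noise sd (intensity units, on
#'   [0,1]-normalized spectra); default 0.01.
#' @param shift_scale maximum horizontal shift in channels; default 10.
#' @param n_out number of augmented spectra to produce.
#' @param methods subset of \code{c("jitter", "shift")}.
#' @param rng_seed integer seed.
#' @return validated list of class \code{"AugmentationConfig"}.
#' @export
augmentationConfig <- function(sigma_max = 0.01, shift_scale = 10L,
                               n_out = 100L, methods = c("jitter", "shift"),
                               rng_seed = 1L) {
  if (sigma_max < 0) stop("'sigma_max' must be >= 0")
  if (shift_scale < 0) stop("'shift_scale' must be >= 0")
  if (n_out < 1) stop("'n_out' must be >= 1")
  methods <- match.arg(methods, c("jitter", "shift"), several.ok = TRUE)
  structure(list(sigma_max = sigma_max, shift_scale = as.integer(shift_scale),
                 n_out = as.integer(n_out), methods = methods,
                 rng_seed = as.integer(rng_seed)),
            class = "AugmentationConfig")
}

#' Jitter a spectrum with Gaussian noise of random amplitude
#'
#' @param x numeric vector (one spectrum).
#' @param sigma_max noise-sd upper bound; the actual sd is drawn uniformly
#'   from [0, sigma_max].
#' @return jittered numeric vector, same length.
#' @export
jitterSpectrum <- function(x, sigma_max) {
  if (sigma_max < 0) stop("'sigma_max' must be >= 0")
  if (sigma_max == 0) return(x)
  sigma <- runif(1, 0, sigma_max)
  x + rnorm(length(x), sd = sigma)
}

#' Shift a spectrum horizontally with zero fill
#'
#' @param x numeric vector (one spectrum).
#' @param d integer displacement in channels; positive moves intensities
#'   toward higher channel indices.  Vacated channels become exactly 0.
#' @return shifted numeric vector, same length.
#' @export
shiftSpectrum <- function(x, d) {
  L <- length(x)
  d <- as.integer(d)
  if (abs(d) >= L) stop("|d| must be smaller than the spectrum length")
  if (d == 0L) return(x)
  y <- numeric(L)
  if (d > 0L) y[(d + 1L):L] <- x[1L:(L - d)]
  else        y[1L:(L + d)] <- x[(1L - d):L]
  y
}

#' Expand a seed set by random jitter/shift augmentation
#'
#' Seeds are consumed round-robin until \code{cfg$n_out} augmented spectra
#' exist; labels are inherited from the seed each copy came from.  With shift
#' enabled, the displacement is drawn uniformly from the integers
#' [-shift_scale, shift_scale]; with jitter enabled, noise is added after any
#' shift.  Fully deterministic for a fixed \code{cfg$rng_seed}.
#'
#' @param seed_set a \linkS4class{SpectrumSet}.
#' @param cfg an \code{\link{augmentationConfig}}.
#' @return a \linkS4class{SpectrumSet} with exactly \code{cfg$n_out} spectra.
#' @examples
#' lib <- makeClassLibrary(1, length = 128, rng_seed = 1)
#' seeds <- makeDataset(lib[[1]], n = 2, length = 128, rng_seed = 1)
#' aug <- augmentSet(seeds, augmentationConfig(n_out = 20, rng_seed = 7))
#' @export
augmentSet <- function(seed_set, cfg = augmentationConfig()) {
  stopifnot(is(seed_set, "SpectrumSet"), inherits(cfg, "AugmentationConfig"))
  x <- intensities(seed_set)
  L <- nrow(x); n_seed <- ncol(x)
  if (cfg$shift_scale >= L) stop("'shift_scale' must be below spectrum length")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$rng_seed)
  out <- matrix(0, L, cfg$n_out)
  labs <- character(cfg$n_out)
  seed_labs <- spectrumLabels(seed_set)
  for (i in seq_len(cfg$n_out)) {
    j <- (i - 1L) %% n_seed + 1L
    s <- x[, j]
    if ("shift" %in% cfg$methods && cfg$shift_scale > 0) {
      d <- sample.int(2L * cfg$shift_scale + 1L, 1L) - cfg$shift_scale - 1L
      s <- shiftSpectrum(s, d)
    }
    if ("jitter" %in% cfg$methods)
      s <- jitterSpectrum(s, cfg$sigma_max)
    out[, i] <- s
    labs[i] <- seed_labs[j]
  }
  .respectra(seed_set, out, label = labs)
}
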