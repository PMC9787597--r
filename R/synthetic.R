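#' Describe one spectral peak
#'
#' Peaks are parameterized by a 0-based channel index, a relative amplitude,
#' a half-width at half-maximum (HWHM) in channels, and a kernel shape.
#' Lorentzian profiles are the default, the typical lineshape of Raman bands;
#' Gaussian profiles are available for instrument-broadened peaks.
#'
#' @param center 0-based channel index of the peak maximum.
#' @param amplitude peak height, dimensionless, > 0.
#' @param width HWHM in channels, > 0.
#' @param shape \code{"lorentzian"} or \code{"gaussian"}.
#' @return A list of class \code{"PeakModel"}.
#' @examples
#' peakModel(100, 1, 5)
#' @export
peakModel <- function(center, amplitude = 1, width = 5,
                      shape = c("lorentzian", "gaussian")) {
  shape <- match.arg(shape)
  if (amplitude <= 0) stop("'amplitude' must be > 0")
  if (width <= 0) stop("'width' must be > 0")
  if (center < 0) stop("'center' must be >= 0")
  structure(list(center = center, amplitude = amplitude,
                 width = width, shape = shape),
            class = "PeakModel")
}

# evaluate one peak kernel on 0-based channel positions
.peak_kernel <- function(peak, x) {
  u <- (x - peak$center) / peak$width
  switch(peak$shape,
    lorentzian = peak$amplitude / (1 + u^2),
    # 2^(-u^2) makes 'width' the HWHM for the Gaussian kernel too
    gaussian   = peak$amplitude * 2^(-u^2))
}

#' Simulate one Raman-like spectrum
#'
#' Sums peak kernels, adds a smooth random low-order cosine baseline and iid
#' Gaussian channel noise, then (by default) min-max normalizes to [0, 1].
#'
#' @param peaks list of \code{\link{peakModel}} objects (possibly empty).
#' @param length number of channels L.
#' @param baseline_amp baseline amplitude; 0 disables the baseline.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param rng_seed integer seed; the call is deterministic given the seed.
#' @param normalize min-max normalize to [0, 1] (skipped automatically when
#'   the signal is constant).  Set \code{FALSE} to obtain the raw kernel sum,
#'   e.g. when checking analytic lineshape properties.
#' @return numeric vector of length \code{length}.
#' @examples
#' s <- makeSpectrum(list(peakModel(100, 1, 5)), length = 256, rng_seed = 1)
#' @export
makeSpectrum <- function(peaks = list(), length, baseline_amp = 0,
                         noise_sigma = 0, rng_seed = 1, normalize = TRUE) {
  if (length <= 0) stop("'length' must be positive")
  if (baseline_amp < 0 || noise_sigma < 0)
    stop("'baseline_amp' and 'noise_sigma' must be >= 0")
  for (p in peaks)
    if (p$center >= length)
      stop("peak center ", p$center, " out of range for length ", length)
  x <- seq_len(length) - 1
  y <- numeric(length)
  for (p in peaks) y <- y + .peak_kernel(p, x)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(rng_seed)
  if (baseline_amp > 0) {
    coef <- runif(3, -1, 1)
    phase <- runif(3, 0, 2 * pi)
    t <- x / (length - 1)
    for (j in 1:3)
      y <- y + baseline_amp * coef[j] * cos(pi * j * t + phase[j])
  }
  if (noise_sigma > 0) y <- y + rnorm(length, sd = noise_sigma)
  if (normalize) {
    r <- range(y)
    if (r[2] > r[1]) y <- (y - r[1]) / (r[2] - r[1])
  }
  y
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Draw a library of distinct synthetic spectrum classes
#'
#' Each class receives a random set of peaks; classes are re-drawn until no
#' two classes share more than half of their peak centers to within +/- 2
#' channels, so class identities stay spectrally distinguishable (standing in
#' for chemically distinct compounds).
#'
#' @param n_classes number of classes, >= 1.
#' @param length spectrum length in channels.
#' @param peaks_per_class integer range \code{c(min, max)} for the peak count.
#' @param rng_seed integer seed.
#' @param max_tries bounded retries for the distinctness constraint.
#' @return named list; element \code{class_k} is a list of
#'   \code{\link{peakModel}} objects.
#' @examples
#' lib <- makeClassLibrary(4, length = 256, rng_seed = 1)
#' @export
makeClassLibrary <- function(n_classes, length = 2688,
                             peaks_per_class = c(3L, 8L), rng_seed = 1,
                             max_tries = 200L) {
  if (n_classes < 1) stop("'n_classes' must be >= 1")
  peaks_per_class <- rep(as.integer(peaks_per_class), length.out = 2L)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(rng_seed)
  margin <- max(2, round(0.05 * length))
  wmax <- max(4, round(length / 120))
  draw_class <- function() {
    k <- if (peaks_per_class[1] == peaks_per_class[2]) peaks_per_class[1]
         else sample(peaks_per_class[1]:peaks_per_class[2], 1L)
    centers <- sort(sample(margin:(length - margin - 1L), k))
    lapply(seq_len(k), function(i)
      peakModel(centers[i],
                amplitude = runif(1, 0.25, 1),
                width = runif(1, 3, wmax)))
  }
  overlap_frac <- function(a, b) {
    ca <- vapply(a, `[[`, numeric(1), "center")
    cb <- vapply(b, `[[`, numeric(1), "center")
    hits <- vapply(ca, function(c0) any(abs(cb - c0) <= 2), logical(1))
    mean(hits)
  }
  lib <- list()
  for (cls in seq_len(n_classes)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- draw_class()
      if (all(vapply(lib, function(prev)
            overlap_frac(cand, prev) <= 0.5 && overlap_frac(prev, cand) <= 0.5,
            logical(1)))) { ok <- TRUE; break }
    }
    if (!ok) stop("could not draw ", n_classes,
                  " mutually distinct classes in ", max_tries, " tries")
    lib[[paste0("class_", cls)]] <- cand
  }
  lib
}

#' Sample a dataset of noisy replicates of one synthetic class
#'
#' The class template (peaks + baseline, min-max normalized) is fixed by the
#' class seed; each replicate adds fresh iid Gaussian noise to that template,
#' so noiseless replicates are identical and noisy replicates differ only by
#' the noise term.
#'
#' @param peaks list of \code{\link{peakModel}} objects defining the class
#'   (one element of \code{\link{makeClassLibrary}}'s result).
#' @param n number of spectra to draw.
#' @param length spectrum length in channels.
#' @param noise_sigma per-channel Gaussian noise sd (on the [0, 1] intensity
#'   scale).
#' @param baseline_amp baseline amplitude of the class template.
#' @param label class label attached to every spectrum.
#' @param rng_seed integer seed.
#' @return a \linkS4class{SpectrumSet} with \code{n} spectra.
#' @examples
#' lib <- makeClassLibrary(1, length = 256, rng_seed = 1)
#' ds <- makeDataset(lib[[1]], n = 10, length = 256, rng_seed = 2)
#' @export
makeDataset <- function(peaks, n, length = 2688, noise_sigma = 0.01,
                        baseline_amp = 0.1, label = "class_1", rng_seed = 1) {
  if (n < 1) stop("'n' must be >= 1")
  template <- makeSpectrum(peaks, length = length, baseline_amp = baseline_amp,
                           noise_sigma = 0, rng_seed = rng_seed)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(rng_seed + 1L)
  x <- matrix(rnorm(length * n, sd = noise_sigma), length, n) + template
  SpectrumSet(x, label = label,
              meta = list(template = template, noise_sigma = noise_sigma,
                          rng_seed = rng_seed))
}
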