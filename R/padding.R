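#' Zero-pad both ends of every spectrum
#'
#' Appending P zero channels to each end before GAN training confines the
#' endpoint artifacts caused by the spectrum's discontinuous ends to a
#' disposable region; \code{\link{removePadding}} cuts that region away from
#' generated spectra.  The default P = 64 with the canonical 2688-channel grid
#' yields a padded length of 2816, divisible by 16 as the GAN's four stride-2
#' halvings require.
#'
#' @param x a \linkS4class{SpectrumSet} or an intensity matrix
#'   (channels x spectra).
#' @param pad_len non-negative integer P, channels added to EACH end.
#' @return same type as the input, with \code{2 * pad_len} extra channels.
#' @examples
#' addZeroPadding(matrix(1:3, 3, 1), 2)
#' @export
addZeroPadding <- function(x, pad_len = 64L) {
  pad_len <- as.integer(pad_len)
  if (pad_len < 0) stop("'pad_len' must be >= 0")
  if (is(x, "SpectrumSet"))
    return(.respectra(x, addZeroPadding(intensities(x), pad_len)))
  if (pad_len == 0L) return(x)
  z <- matrix(0, pad_len, ncol(x))
  rbind(z, x, z)
}

#' Cut the padded region from both ends of every spectrum
#'
#' Exactly \code{pad_len} channels are discarded from each end regardless of
#' their values; artifact channels are removed, not inspected.
#'
#' @inheritParams addZeroPadding
#' @return same type as the input, with \code{2 * pad_len} fewer channels.
#' @examples
#' removePadding(addZeroPadding(matrix(1:3, 3, 1), 2), 2)
#' @export
removePadding <- function(x, pad_len = 64L) {
  pad_len <- as.integer(pad_len)
  if (pad_len < 0) stop("'pad_len' must be >= 0")
  if (is(x, "SpectrumSet"))
    return(.respectra(x, removePadding(intensities(x), pad_len)))
  if (pad_len == 0L) return(x)
  L <- nrow(x)
  if (L <= 2L * pad_len) stop("spectrum length must exceed 2 * pad_len")
  x[(pad_len + 1L):(L - pad_len), , drop = FALSE]
}
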