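#' Fit Gaussian moments to a set of spectra
#'
#' Sample mean per channel and sample covariance (divisor n-1), with a small
#' ridge \code{epsilon * I} added to the covariance so the Frechet distance
#' stays well-posed when spectra outnumber samples.
#'
#' @param x a \linkS4class{SpectrumSet} or matrix (channels x spectra) with
#'   at least 2 spectra.
#' @param epsilon ridge added to the covariance diagonal (default 1e-6).
#' @return list of class \code{"GaussianMoments"} with elements \code{m}
#'   (mean vector) and \code{C} (covariance matrix).
#' @export
estimateMoments <- function(x, epsilon = 1e-6) {
  if (is(x, "SpectrumSet")) x <- intensities(x)
  if (ncol(x) < 2L) stop("at least 2 spectra are required")
  m <- rowMeans(x)
  C <- cov(t(x)) + diag(epsilon, nrow(x))
  structure(list(m = m, C = C), class = "GaussianMoments")
}

#' Squared Frechet distance between two Gaussians
#'
#' d^2((m, C), (m_w, C_w)) = ||m - m_w||^2 + Tr(C + C_w - 2 (C C_w)^{1/2}),
#' the quantity usually reported as FID.  The matrix square root is computed
#' symmetrically as sqrt(C)^T C_w sqrt(C) via eigendecompositions; tiny
#' negative eigenvalues from round-off are clipped to zero, so the result is
#' non-negative and symmetric in its arguments.  The squared distance is
#' returned (no square root is taken).
#'
#' @param a,b \code{"GaussianMoments"} objects (see
#'   \code{\link{estimateMoments}}) of equal dimension.
#' @return non-negative scalar d^2.
#' @examples
#' a <- structure(list(m = 0, C = matrix(1)), class = "GaussianMoments")
#' b <- structure(list(m = 1, C = matrix(4)), class = "GaussianMoments")
#' frechetDistance(a, b)   # 2
#' @export
frechetDistance <- function(a, b) {
  if (length(a$m) != length(b$m)) stop("dimension mismatch")
  Ca <- as.matrix(a$C); Cb <- as.matrix(b$C)
  ea <- eigen(Ca, symmetric = TRUE)
  S <- ea$vectors %*% (sqrt(pmax(ea$values, 0)) * t(ea$vectors))
  ev <- eigen(S %*% Cb %*% S, symmetric = TRUE, only.values = TRUE)$values
  tr_sqrt <- sum(sqrt(pmax(ev, 0)))
  sum((a$m - b$m)^2) + sum(diag(Ca)) + sum(diag(Cb)) - 2 * tr_sqrt
}

#' Pearson correlation of two spectra
#'
#' r = sum((x - m_x)(y - m_y)) / sqrt(sum((x - m_x)^2) sum((y - m_y)^2)).
#'
#' @param x,y numeric vectors of equal length >= 2, neither constant.
#' @return r in [-1, 1].
#' @export
pearsonCC <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("at least 2 channels are required")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation is undefined for a constant spectrum")
  cor(x, y)
}

#' Euclidean distance between two spectra
#'
#' @param x,y numeric vectors of equal length.
#' @return sqrt(sum((y_i - x_i)^2)).
#' @examples
#' euclideanDist(c(0, 0), c(3, 4))   # 5
#' @export
euclideanDist <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  sqrt(sum((y - x)^2))
}

#' Score a generated spectrum set against a real one
#'
#' The Frechet distance is computed between Gaussian moments fitted to the
#' two sets (optionally after projecting both onto the leading principal
#' components of the real set, useful when channels far outnumber samples).
#' Pearson correlation and Euclidean distance are averaged over generated
#' spectra, each compared against the mean real spectrum -- a pairing-free,
#' stable convention.
#'
#' @param real,generated \linkS4class{SpectrumSet}s or matrices
#'   (channels x spectra) of one common spectrum length.
#' @param composition_label pipeline-variant tag carried into the report,
#'   e.g. \code{"DA-ZP-GAN-DAE-RZP"}.
#' @param fid_dims optional number of principal components for the Frechet
#'   computation; NULL uses the raw channel space.
#' @return list of class \code{"MetricsReport"} with \code{fid}, \code{pcc},
#'   \code{ed}, \code{composition_label}.
#' @export
evaluateGeneration <- function(real, generated, composition_label = "",
                               fid_dims = NULL) {
  xr <- if (is(real, "SpectrumSet")) intensities(real) else real
  xg <- if (is(generated, "SpectrumSet")) intensities(generated) else generated
  if (nrow(xr) != nrow(xg)) stop("real and generated spectrum lengths differ")
  pr <- xr; pg <- xg
  if (!is.null(fid_dims)) {
    k <- min(fid_dims, nrow(xr), ncol(xr) - 1L)
    pca <- prcomp(t(xr), center = TRUE, rank. = k)
    pr <- t(predict(pca, t(xr)))
    pg <- t(predict(pca, t(xg)))
  }
  fid <- frechetDistance(estimateMoments(pr), estimateMoments(pg))
  mref <- rowMeans(xr)
  pcc <- mean(apply(xg, 2L, pearsonCC, y = mref))
  ed <- mean(apply(xg, 2L, euclideanDist, y = mref))
  structure(list(fid = fid, pcc = pcc, ed = ed,
                 composition_label = composition_label),
            class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("%-22s FID %8.4g  PCC %8.4f  ED %8.4g\n",
              if (nzchar(x$composition_label)) x$composition_label else "-",
              x$fid, x$pcc, x$ed))
  invisible(x)
}
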