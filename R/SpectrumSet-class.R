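#' SpectrumSet: a collection of same-length 1-D Raman spectra
#'
#' An S4 container extending \linkS4class{SummarizedExperiment}.  Rows are
#' spectral channels (the Raman-shift axis), columns are individual spectra.
#' The single assay \code{"intensity"} holds the intensity matrix; per-spectrum
#' class labels live in \code{colData()$label} and an optional Raman-shift axis
#' (cm^-1) in \code{rowData()$shift}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; no extra slots are added.
#' @name SpectrumSet-class
#' @exportClass SpectrumSet
setClass("SpectrumSet", contains = "SummarizedExperiment")

setValidity("SpectrumSet", function(object) {
  if (!"intensity" %in% names(assays(object)))
    return("assay 'intensity' is required")
  x <- assay(object, "intensity")
  if (ncol(x) < 1L)
    return("a SpectrumSet must contain at least one spectrum")
  if (!all(is.finite(x)))
    return("all intensities must be finite")
  if (!"label" %in% names(colData(object)))
    return("colData must carry a 'label' column")
  if ("shift" %in% names(rowData(object))) {
    sh <- rowData(object)$shift
    if (any(diff(sh) <= 0))
      return("the Raman-shift axis must be strictly increasing")
  }
  TRUE
})

#' Construct a SpectrumSet
#'
#' @param intensities numeric matrix, channels x spectra, or a numeric vector
#'   for a single spectrum.
#' @param label character or factor vector of class labels, length one
#'   (recycled) or one per spectrum.  Defaults to \code{"unknown"}.
#' @param shift optional strictly increasing Raman-shift axis (cm^-1), one
#'   value per channel.
#' @param meta optional named list of provenance metadata.
#' @return A \linkS4class{SpectrumSet}.
#' @examples
#' s <- SpectrumSet(matrix(runif(64), 16, 4), label = "demo")
#' nChannels(s); nSpectra(s)
#' @export
SpectrumSet <- function(intensities, label = "unknown", shift = NULL,
                        meta = list()) {
  if (is.null(dim(intensities)))
    intensities <- matrix(as.numeric(intensities), ncol = 1L)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (length(label) == 1L) label <- rep(label, ncol(intensities))
  if (length(label) != ncol(intensities))
    stop("'label' must have one entry per spectrum")
  rd <- if (is.null(shift)) NULL else {
    if (length(shift) != nrow(intensities))
      stop("'shift' must have one value per channel")
    DataFrame(shift = as.numeric(shift))
  }
  dimnames(intensities) <- NULL
  se <- SummarizedExperiment(
    assays  = list(intensity = intensities),
    colData = DataFrame(label = as.character(label)))
  if (!is.null(rd)) rowData(se) <- rd
  obj <- methods::new("SpectrumSet", se)
  metadata(obj) <- meta
  obj
}

#' @importFrom SummarizedExperiment `rowData<-`
NULL

# ---- accessors --------------------------------------------------------------

#' Intensity matrix of a SpectrumSet
#'
#' @param object a \linkS4class{SpectrumSet}.
#' @return numeric matrix (channels x spectra).
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname intensities
#' @export
setMethod("intensities", "SpectrumSet", function(object)
  assay(object, "intensity"))

#' Class labels of the spectra in a SpectrumSet
#'
#' @param object a \linkS4class{SpectrumSet}.
#' @return character vector, one label per spectrum.
#' @export
setGeneric("spectrumLabels", function(object) standardGeneric("spectrumLabels"))

#' @rdname spectrumLabels
#' @export
setMethod("spectrumLabels", "SpectrumSet", function(object)
  colData(object)$label)

#' Number of channels (spectrum length)
#' @param object a \linkS4class{SpectrumSet}.
#' @return integer.
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname nChannels
#' @export
setMethod("nChannels", "SpectrumSet", function(object) nrow(object))

#' Number of spectra in the set
#' @param object a \linkS4class{SpectrumSet}.
#' @return integer.
#' @export
setGeneric("nSpectra", function(object) standardGeneric("nSpectra"))

#' @rdname nSpectra
#' @export
setMethod("nSpectra", "SpectrumSet", function(object) ncol(object))

#' Raman-shift axis, or NULL when the set is indexed by bare channels
#' @param object a \linkS4class{SpectrumSet}.
#' @return numeric vector or NULL.
#' @export
setGeneric("shiftAxis", function(object) standardGeneric("shiftAxis"))

#' @rdname shiftAxis
#' @export
setMethod("shiftAxis", "SpectrumSet", function(object) {
  rd <- rowData(object)
  if ("shift" %in% names(rd)) rd$shift else NULL
})

setMethod("show", "SpectrumSet", function(object) {
  cat("SpectrumSet with", nSpectra(object), "spectra of",
      nChannels(object), "channels\n")
  labs <- table(spectrumLabels(object))
  cat("labels:", paste(sprintf("%s (%d)", names(labs), labs),
                       collapse = ", "), "\n")
  if (!is.null(shiftAxis(object))) {
    rng <- range(shiftAxis(object))
    cat(sprintf("Raman shift axis: %.1f .. %.1f cm^-1\n", rng[1], rng[2]))
  }
  rng <- range(intensities(object))
  cat(sprintf("intensity range: [%.4g, %.4g]\n", rng[1], rng[2]))
})

# internal: rebuild a set with a new intensity matrix, keeping labels where
# the spectrum count is unchanged
.respectra <- function(object, x, label = NULL) {
  if (is.null(label)) {
    label <- if (ncol(x) == nSpectra(object)) spectrumLabels(object)
             else rep(spectrumLabels(object)[1L], ncol(x))
  }
  SpectrumSet(x, label = label,
              shift = if (nrow(x) == nChannels(object)) shiftAxis(object),
              meta = metadata(object))
}
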