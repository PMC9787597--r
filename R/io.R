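#' Write / read one spectrum as two-column delimited text
#'
#' Columns are \code{raman_shift} and \code{intensity}, tab-separated with a
#' header line.  When the set carries no shift axis, the 0-based channel index
#' is written instead.
#'
#' @param x a \linkS4class{SpectrumSet} (the indicated column) .
#' @param path output file.
#' @param which column (spectrum) index to write.
#' @return \code{path}, invisibly.
#' @export
writeSpectrumTxt <- function(x, path, which = 1L) {
  stopifnot(is(x, "SpectrumSet"))
  axis <- shiftAxis(x)
  if (is.null(axis)) axis <- seq_len(nChannels(x)) - 1
  df <- data.frame(raman_shift = axis, intensity = intensities(x)[, which])
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSpectrumTxt
#' @param label label to attach to the spectrum read back.
#' @return for the reader, a one-spectrum \linkS4class{SpectrumSet}.
#' @export
readSpectrumTxt <- function(path, label = "unknown") {
  df <- read.table(path, header = TRUE, sep = "\t")
  SpectrumSet(matrix(df[[2]], ncol = 1), label = label, shift = df[[1]])
}

#' Write / read a SpectrumSet as a matrix CSV
#'
#' Rows are spectra; the first header row carries the channel axis.  A
#' \code{label} column (first column) keeps the class labels.
#'
#' @param x a \linkS4class{SpectrumSet}.
#' @param path output file.
#' @return \code{path} invisibly (writer); a \linkS4class{SpectrumSet}
#'   (reader).
#' @export
writeSpectraCSV <- function(x, path) {
  stopifnot(is(x, "SpectrumSet"))
  axis <- shiftAxis(x)
  if (is.null(axis)) axis <- seq_len(nChannels(x)) - 1
  m <- t(intensities(x))
  colnames(m) <- as.character(axis)
  df <- data.frame(label = spectrumLabels(x), m, check.names = FALSE)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSpectraCSV
#' @export
readSpectraCSV <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", check.names = FALSE)
  axis <- suppressWarnings(as.numeric(names(df)[-1]))
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  dimnames(m) <- NULL
  SpectrumSet(m, label = df[[1]],
              shift = if (!anyNA(axis) && all(diff(axis) > 0)) axis)
}

#' Write / read a dataset manifest (JSON)
#'
#' The manifest records file paths, labels, spectrum length and the seed used
#' to build a dataset, so command-line stages can hand sets to each other.
#'
#' @param paths character vector of spectrum or matrix files.
#' @param labels class labels parallel to \code{paths}.
#' @param length spectrum length in channels.
#' @param seed integer seed recorded for provenance.
#' @param path manifest file to write.
#' @return \code{path} invisibly (writer); a list (reader).
#' @export
writeManifest <- function(paths, labels, length, seed, path) {
  jsonlite::write_json(
    list(files = paths, labels = labels, length = length, seed = seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
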