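# Containers for processed spectra: one 1D trace, or an ordered stack of
# rows sharing a ppm axis (pseudo-2D).

#' Construct a 1D spectrum
#'
#' The axis is normalized to strictly ascending ppm (descending input is
#' reversed together with the intensities, as Bruker axes are stored
#' high-to-low).
#'
#' @param ppm strictly monotone chemical-shift axis (ppm).
#' @param intensity intensity vector, same length as `ppm`.
#' @param sf_mhz spectrometer frequency in MHz (used to report couplings in
#'   Hz), or `NA` if unknown.
#' @param meta optional named list of extra metadata.
#' @return object of class `nmr_spectrum` with elements `ppm`, `intensity`,
#'   `meta`.
#' @export
spectrum1d <- function(ppm, intensity, sf_mhz = NA_real_, meta = list()) {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity)) {
    stop("'ppm' and 'intensity' must have equal length")
  }
  if (anyNA(ppm) || anyNA(intensity)) stop("spectrum contains NA values")
  d <- diff(ppm)
  if (length(d) && all(d < 0)) {
    ppm <- rev(ppm); intensity <- rev(intensity); d <- -rev(d)
  }
  if (length(d) && any(d <= 0)) stop("'ppm' axis must be strictly monotone")
  meta$sf_mhz <- sf_mhz
  structure(list(ppm = ppm, intensity = intensity, meta = meta),
            class = "nmr_spectrum")
}

#' Construct a pseudo-2D spectrum series
#'
#' @param ppm shared chemical-shift axis (ppm; normalized ascending).
#' @param intensities numeric matrix, one row per 1D trace.
#' @param labels unique ordered row labels (default: acquisition index).
#' @param sf_mhz spectrometer frequency (MHz) or `NA`.
#' @param meta optional metadata list.
#' @return object of class `nmr_series`.
#' @export
spectrum_series <- function(ppm, intensities, labels = NULL,
                            sf_mhz = NA_real_, meta = list()) {
  ppm <- as.numeric(ppm)
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(ppm)) {
    stop("each intensity row must match the axis length")
  }
  if (anyNA(ppm) || anyNA(intensities)) stop("series contains NA values")
  d <- diff(ppm)
  if (length(d) && all(d < 0)) {
    ppm <- rev(ppm)
    intensities <- intensities[, rev(seq_len(ncol(intensities))), drop = FALSE]
    d <- -rev(d)
  }
  if (length(d) && any(d <= 0)) stop("'ppm' axis must be strictly monotone")
  if (is.null(labels)) labels <- seq_len(nrow(intensities))
  if (anyDuplicated(labels)) stop("row labels must be unique")
  if (length(labels) != nrow(intensities)) {
    stop("'labels' must have one entry per row")
  }
  meta$sf_mhz <- sf_mhz
  structure(list(ppm = ppm, intensities = intensities, labels = labels,
                 meta = meta),
            class = "nmr_series")
}

#' Extract one row of a series as a 1D spectrum
#' @param series an `nmr_series`.
#' @param row row index (1-based).
#' @return an `nmr_spectrum`.
#' @export
series_row <- function(series, row) {
  stopifnot(inherits(series, "nmr_series"))
  if (row < 1 || row > nrow(series$intensities)) stop("row index out of range")
  meta <- series$meta
  meta$row <- row
  meta$label <- series$labels[row]
  spectrum1d(series$ppm, series$intensities[row, ],
             sf_mhz = series$meta$sf_mhz, meta = meta)
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat("<nmr_spectrum> ", length(x$ppm), " points, ",
      format(min(x$ppm)), "..", format(max(x$ppm)), " ppm\n", sep = "")
  invisible(x)
}

#' @export
print.nmr_series <- function(x, ...) {
  cat("<nmr_series> ", nrow(x$intensities), " rows x ", length(x$ppm),
      " points, ", format(min(x$ppm)), "..", format(max(x$ppm)),
      " ppm\n", sep = "")
  invisible(x)
}
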