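# Delimited-text spectra: column 1 is the ppm axis, columns 2..k are
# intensity rows (one column per pseudo-2D increment).

.detect_sep <- function(lines) {
  for (sep in c("\t", ",", ";")) {
    n <- lengths(strsplit(lines, sep, fixed = TRUE))
    if (all(n == n[1L]) && n[1L] >= 2L) return(sep)
  }
  "" # whitespace
}

#' Read a spectrum from a delimited text file
#'
#' Accepts tab-, comma-, semicolon- or whitespace-separated numeric
#' columns, with an optional single header line.  One intensity column
#' yields an [spectrum1d()]; several yield a [spectrum_series()] with one
#' row per column.  Descending ppm axes are normalized to ascending.
#'
#' @param path input file.
#' @param sep field separator; `NULL` (default) auto-detects.
#' @param sf_mhz spectrometer frequency (MHz), if known.
#' @return `nmr_spectrum` or `nmr_series`.
#' @export
read_text_spectrum <- function(path, sep = NULL, sf_mhz = NA_real_) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("'", path, "': empty file")
  if (is.null(sep)) sep <- .detect_sep(lines)
  first_vals <- strsplit(trimws(lines[[1L]]), if (sep == "") "[[:space:]]+" else sep)[[1L]]
  header <- anyNA(suppressWarnings(as.numeric(first_vals)))
  df <- utils::read.table(text = lines, sep = sep, header = header,
                          colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 2L) {
    stop("'", path, "': need at least 2 columns (ppm, intensity), found ", ncol(df))
  }
  num <- suppressWarnings(lapply(df, as.numeric))
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]) & !is.na(df[[j]]))
    if (length(bad)) {
      stop("'", path, "': non-numeric value '", df[[j]][bad[1L]],
           "' at data row ", bad[1L], ", column ", j)
    }
  }
  ppm <- num[[1L]]
  if (ncol(df) == 2L) {
    spectrum1d(ppm, num[[2L]], sf_mhz = sf_mhz, meta = list(source = path))
  } else {
    spectrum_series(ppm, t(do.call(cbind, num[-1L])),
                    sf_mhz = sf_mhz, meta = list(source = path))
  }
}

.fmt_num <- function(x) {
  # shortest decimal representation that round-trips a double
  vapply(x, function(v) formatC(v, digits = 17, format = "g"), character(1))
}

#' Write a spectrum to a delimited text file
#'
#' Writes full double precision (round-trip lossless), '.' decimal
#' separator, one ppm column followed by one column per intensity row.
#'
#' @param x an `nmr_spectrum` or `nmr_series`.
#' @param path output file.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_text_spectrum <- function(x, path, sep = "\t") {
  if (inherits(x, "nmr_spectrum")) {
    mat <- cbind(x$ppm, x$intensity)
    hdr <- c("ppm", "intensity")
  } else if (inherits(x, "nmr_series")) {
    mat <- cbind(x$ppm, t(x$intensities))
    hdr <- c("ppm", paste0("row_", x$labels))
  } else stop("'x' must be an nmr_spectrum or nmr_series")
  con <- file(path, "wb") # binary mode: stable newlines across platforms
  on.exit(close(con))
  writeLines(paste(hdr, collapse = sep), con)
  body <- apply(mat, 1L, function(r) paste(.fmt_num(r), collapse = sep))
  writeLines(body, con)
  invisible(path)
}
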