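# Bruker processed-data reader (1D "1r" and pseudo-2D "2rr"), plus a
# fixture writer used by the test suite and the synthetic bench.
#
# Supported subset: integer processed data (DTYPP = 0, int32) without
# submatrix blocking; the ppm axis is reconstructed from the processing
# parameters as ppm_i = OFFSET - i * SW_p / (SF * SI), i = 0..SI-1 (first
# point at OFFSET, step SW_p/(SF*SI), stored high-to-low).

.read_jcamp_pars <- function(path) {
  if (!file.exists(path)) stop("Bruker parameter file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  hits <- grep("^##\\$", lines, value = TRUE)
  keys <- sub("^##\\$([^=]+)=.*$", "\\1", hits)
  vals <- sub("^##\\$[^=]+=\\s*", "", hits)
  out <- as.list(vals)
  names(out) <- keys
  out
}

.need_par <- function(pars, key, path) {
  if (is.null(pars[[key]])) {
    stop("missing parameter '", key, "' in '", path, "'")
  }
  as.numeric(pars[[key]])
}

.bruker_axis <- function(offset, sw_p, sf, si) {
  offset - (seq_len(si) - 1) * sw_p / (sf * si)
}

.read_bruker_ints <- function(path, n, bytordp) {
  if (!file.exists(path)) stop("Bruker data file not found: '", path, "'")
  endian <- if (bytordp == 0) "little" else "big"
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "integer", n = n, size = 4L, endian = endian)
  if (length(v) != n) {
    stop("'", path, "': truncated data file (expected ", n,
         " points, read ", length(v), ")")
  }
  v
}

#' Read a Bruker processed spectrum
#'
#' Reads pre-processed (referenced, phased, baseline-corrected) Bruker
#' data: `pdata/<procno>/1r` for 1D experiments or `pdata/<procno>/2rr`
#' for pseudo-2D stacks, with the ppm axis reconstructed from `procs`
#' (`OFFSET`, `SW_p`, `SF`, `SI`) and intensities scaled by
#' `2^NC_proc`.
#'
#' @param dir dataset directory (the folder containing the experiment
#'   numbers).
#' @param expno experiment number (subdirectory name).
#' @param procno processing number under `pdata`.
#' @return `nmr_spectrum` for 1D data; `nmr_series` (one row per
#'   increment, in acquisition order) when `2rr`/`proc2s` are present.
#' @export
read_bruker <- function(dir, expno = 1, procno = 1) {
  pdir <- file.path(dir, expno, "pdata", procno)
  procs_path <- file.path(pdir, "procs")
  pars <- .read_jcamp_pars(procs_path)
  si <- as.integer(.need_par(pars, "SI", procs_path))
  offset <- .need_par(pars, "OFFSET", procs_path)
  sw_p <- .need_par(pars, "SW_p", procs_path)
  sf <- .need_par(pars, "SF", procs_path)
  nc <- if (is.null(pars$NC_proc)) 0 else as.numeric(pars$NC_proc)
  bytordp <- if (is.null(pars$BYTORDP)) 0 else as.numeric(pars$BYTORDP)
  dtypp <- if (is.null(pars$DTYPP)) 0 else as.numeric(pars$DTYPP)
  if (dtypp != 0) stop("only integer processed data (DTYPP = 0) is supported")
  ppm <- .bruker_axis(offset, sw_p, sf, si)

  f2rr <- file.path(pdir, "2rr")
  if (file.exists(f2rr)) {
    proc2s_path <- file.path(pdir, "proc2s")
    pars2 <- .read_jcamp_pars(proc2s_path)
    nrows <- as.integer(.need_par(pars2, "SI", proc2s_path))
    v <- .read_bruker_ints(f2rr, si * nrows, bytordp) * 2^nc
    mat <- matrix(v, nrow = nrows, ncol = si, byrow = TRUE)
    spectrum_series(ppm, mat, sf_mhz = sf,
                    meta = list(source = pdir, expno = expno, procno = procno))
  } else {
    v <- .read_bruker_ints(file.path(pdir, "1r"), si, bytordp) * 2^nc
    spectrum1d(ppm, v, sf_mhz = sf,
               meta = list(source = pdir, expno = expno, procno = procno))
  }
}

#' Write a Bruker-layout fixture directory
#'
#' Writes a spectrum or series in the processed-data subset understood by
#' [read_bruker()] (int32 data scaled by `2^NC_proc`, `procs`/`proc2s`
#' parameter files).  Intended for tests and synthetic fixtures -- the
#' integer quantization makes the round trip approximate in intensity
#' (relative error about `2^-28`) while axis metadata round-trips exactly.
#'
#' @param x `nmr_spectrum` or `nmr_series` (strictly uniform ppm grid).
#' @param dir,expno,procno target layout (created as needed).
#' @return the `pdata` path, invisibly.
#' @export
write_bruker <- function(x, dir, expno = 1, procno = 1) {
  is2d <- inherits(x, "nmr_series")
  if (!is2d && !inherits(x, "nmr_spectrum")) {
    stop("'x' must be an nmr_spectrum or nmr_series")
  }
  ppm <- x$ppm
  si <- length(ppm)
  step <- diff(ppm)
  if (max(abs(step - step[1])) > 1e-9 * abs(step[1])) {
    stop("Bruker layout requires a uniform ppm grid")
  }
  sf <- if (is.finite(x$meta$sf_mhz %||% NA_real_)) x$meta$sf_mhz else 500
  sw_p <- step[1] * si * sf
  offset <- ppm[si] # axis is stored descending: first stored point = max ppm
  vals <- if (is2d) as.vector(t(x$intensities[, si:1, drop = FALSE]))
          else rev(x$intensity)
  amax <- max(abs(vals), 1e-300)
  nc <- ceiling(log2(amax / 2^28))
  ints <- as.integer(round(vals / 2^nc))

  pdir <- file.path(dir, expno, "pdata", procno)
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  pfmt <- function(v) formatC(v, digits = 17, format = "g")
  writeLines(c(
    "##TITLE= Processing parameters",
    paste0("##$BYTORDP= 0"),
    paste0("##$DTYPP= 0"),
    paste0("##$NC_proc= ", nc),
    paste0("##$OFFSET= ", pfmt(offset)),
    paste0("##$SF= ", pfmt(sf)),
    paste0("##$SI= ", si),
    paste0("##$SW_p= ", pfmt(sw_p)),
    "##END="
  ), file.path(pdir, "procs"))
  if (is2d) {
    writeLines(c(
      "##TITLE= F1 processing parameters",
      paste0("##$SI= ", nrow(x$intensities)),
      "##END="
    ), file.path(pdir, "proc2s"))
  }
  con <- file(file.path(pdir, if (is2d) "2rr" else "1r"), "wb")
  writeBin(ints, con, size = 4L, endian = "little")
  close(con)
  invisible(pdir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
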