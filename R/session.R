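# Reproducible sessions: an append-only record of inputs, configuration,
# peaks, signals and fit results, saved as a versioned self-describing
# JSON archive and exported to CSV.

.SESSION_SCHEMA <- 1L

#' Create an analysis session
#'
#' @param config optional named list recording run configuration.
#' @param provenance optional named list of input paths/checksums.
#' @return object of class `nmr_session`.
#' @export
new_session <- function(config = list(), provenance = list()) {
  s <- structure(
    list(schema_version = .SESSION_SCHEMA,
         provenance = provenance, config = config,
         peaks = list(), signals = list(), fits = list(),
         log = character(0)),
    class = "nmr_session"
  )
  session_log(s, "session created")
}

#' Append a timestamped entry to the session log
#' @param session an `nmr_session`.
#' @param message log text.
#' @return the updated session.
#' @export
session_log <- function(session, message) {
  stamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  session$log <- c(session$log, paste0(stamp, "Z ", message))
  session
}

#' Record a fit result in a session
#'
#' @param session an `nmr_session`.
#' @param fit an `nmr_fit`.
#' @param spectrum_id identifier of the fitted spectrum/row.
#' @return the updated session.
#' @export
add_fit <- function(session, fit, spectrum_id = "spectrum_1") {
  stopifnot(inherits(session, "nmr_session"), inherits(fit, "nmr_fit"))
  session$fits[[length(session$fits) + 1L]] <-
    list(spectrum_id = spectrum_id, fit = fit)
  session_log(session, paste0("fit recorded for '", spectrum_id, "'"))
}

#' Save a session archive
#'
#' Writes a single-file, versioned JSON archive with full double
#' precision (17 significant digits), so that re-exported CSVs are
#' byte-identical after a reload.
#'
#' @param session an `nmr_session`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_session <- function(session, path) {
  stopifnot(inherits(session, "nmr_session"))
  payload <- jsonlite::serializeJSON(unclass(session), digits = 17)
  obj <- list(format = "multipletfit-session",
              schema_version = .SESSION_SCHEMA,
              payload = as.character(payload))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), path)
  invisible(path)
}

#' Load a session archive
#'
#' Rejects files that are not session archives or that carry a newer
#' schema version.  Every load appends a log entry.
#'
#' @param path archive path.
#' @return the restored `nmr_session`.
#' @export
load_session <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("'", path, "' is not a readable session archive: ",
                         conditionMessage(e))
                  })
  if (!identical(obj$format, "multipletfit-session")) {
    stop("'", path, "' is not a multipletfit session archive")
  }
  if (obj$schema_version > .SESSION_SCHEMA) {
    stop("session schema version ", obj$schema_version,
         " is newer than the supported version ", .SESSION_SCHEMA,
         "; upgrade the package to load this archive")
  }
  session <- jsonlite::unserializeJSON(obj$payload)
  class(session) <- "nmr_session"
  for (i in seq_along(session$fits)) {
    class(session$fits[[i]]$fit) <- "nmr_fit"
  }
  session_log(session, paste0("session loaded from '", path, "'"))
}

#' Export session results to CSV
#'
#' Writes `params.csv` (one row per fitted parameter plus derived area
#' and FWHM rows, with sd, 95% normal-approximation confidence interval,
#' bound and convergence flags), `curves.csv` (experimental, total fitted
#' and per-signal curves on the region grid) and `run.log`.  Numbers are
#' written at full double precision with a '.' decimal separator.
#'
#' @param session an `nmr_session` containing at least one fit.
#' @param out_dir output directory (created if needed).
#' @return named character vector of the written file paths, invisibly.
#' @export
export_results <- function(session, out_dir) {
  stopifnot(inherits(session, "nmr_session"))
  if (!length(session$fits)) stop("session contains no fit results")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  prows <- list()
  crows <- list()
  for (entry in session$fits) {
    f <- entry$fit
    sid <- entry$spectrum_id
    for (s in f$signals) {
      p <- s$params
      prows[[length(prows) + 1L]] <- data.frame(
        spectrum = sid, region_min = f$region[1], region_max = f$region[2],
        signal = s$id, model = s$model, parameter = p$name,
        value = p$value, sd = p$sd,
        ci_lower = p$value - 1.96 * p$sd, ci_upper = p$value + 1.96 * p$sd,
        at_bound = p$at_bound, converged = f$converged,
        stringsAsFactors = FALSE
      )
      d <- f$derived[f$derived$signal == s$id, , drop = FALSE]
      extra <- data.frame(
        spectrum = sid, region_min = f$region[1], region_max = f$region[2],
        signal = s$id, model = s$model,
        parameter = c("area", "fwhm"),
        value = c(d$area[1], d$fwhm[1]),
        sd = c(d$area_sd[1], NA_real_),
        ci_lower = c(d$area[1] - 1.96 * d$area_sd[1], NA_real_),
        ci_upper = c(d$area[1] + 1.96 * d$area_sd[1], NA_real_),
        at_bound = FALSE, converged = f$converged,
        stringsAsFactors = FALSE
      )
      hz <- grep("_hz$", names(d), value = TRUE)
      for (h in hz) {
        if (is.finite(d[[h]][1])) {
          extra <- rbind(extra, utils::modifyList(extra[1L, ], list(
            parameter = h, value = d[[h]][1], sd = NA_real_,
            ci_lower = NA_real_, ci_upper = NA_real_
          )))
        }
      }
      prows[[length(prows) + 1L]] <- extra
    }
    cm <- data.frame(spectrum = sid, ppm = f$x, experimental = f$y,
                     fitted = f$fitted, stringsAsFactors = FALSE)
    for (j in seq_len(ncol(f$curves))) {
      cm[[paste0("signal_", colnames(f$curves)[j])]] <- f$curves[, j]
    }
    crows[[length(crows) + 1L]] <- cm
  }

  params <- do.call(rbind, prows)
  curves <- NULL
  for (cm in crows) curves <- .rbind_fill(curves, cm)

  paths <- c(params = file.path(out_dir, "params.csv"),
             curves = file.path(out_dir, "curves.csv"),
             log = file.path(out_dir, "run.log"))
  .write_csv_c(params, paths[["params"]])
  .write_csv_c(curves, paths[["curves"]])
  con <- file(paths[["log"]], "wb")
  writeLines(session$log, con)
  close(con)
  invisible(paths)
}

# locale-independent CSV writer, full double precision
.write_csv_c <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) {
      out <- .fmt_num(col)
      out[is.na(col)] <- "NA"
      out
    } else as.character(col)
  })
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  con <- file(path, "wb")
  writeLines(lines, con)
  close(con)
  invisible(path)
}

#' @export
print.nmr_session <- function(x, ...) {
  cat("<nmr_session> schema ", x$schema_version, ", ", length(x$fits),
      " fit(s), ", length(x$log), " log entries\n", sep = "")
  invisible(x)
}
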