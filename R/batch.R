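# Row-by-row fitting of a pseudo-2D series with reference-spectrum
# parameter propagation.

#' Plan a batch fit over a series
#'
#' The reference row is fitted first, then the remaining rows in two
#' outward passes: `reference + 1 ... n`, then `reference - 1 ... 1`.
#' In `"prev"` mode each row is initialized from its already-fitted
#' neighbour on the reference side; in `"ref"` mode every row is
#' initialized from the reference fit.
#'
#' @param series an `nmr_series`.
#' @param reference reference row index (1-based).
#' @param mode `"prev"` (default) or `"ref"`.
#' @return object of class `nmr_batch_plan` with the visit `order`.
#' @export
plan_batch <- function(series, reference, mode = c("prev", "ref")) {
  stopifnot(inherits(series, "nmr_series"))
  mode <- match.arg(mode)
  n <- nrow(series$intensities)
  if (reference < 1 || reference > n) {
    stop("reference row ", reference, " out of range 1..", n)
  }
  up <- if (reference < n) seq.int(reference + 1L, n) else integer(0)
  down <- if (reference > 1L) seq.int(reference - 1L, 1L) else integer(0)
  structure(
    list(series = series, reference = as.integer(reference), mode = mode,
         order = c(as.integer(reference), up, down)),
    class = "nmr_batch_plan"
  )
}

# re-resolve a fitted signal's bounds around new initial values
.propagate_signal <- function(signal, fitted_params) {
  model <- get_model(signal$model)
  inits <- fitted_params$value
  signal$params <- .resolve_bounds(model$specs, inits,
                                   allow_negative = signal$allow_negative)
  signal
}

#' Run a planned batch fit
#'
#' Fits the reference row from the supplied signal instances, then visits
#' the remaining rows in plan order.  Propagated initial values carry
#' their relative bounds with them (re-resolved around the new inits), so
#' drifting peaks stay trackable without unbounded wander; absolute
#' bounds are fixed by the model specs.  A failed row (non-convergence)
#' is retried once from the reference fit with global refinement enabled,
#' then recorded as failed; subsequent rows fall back to the reference
#' initialization.  A reference-row failure aborts the batch.
#'
#' @param plan an [plan_batch()] result.
#' @param reg the fit [region()].
#' @param signals resolved `nmr_signal` list for the reference row.
#' @param options fitting options passed to [fit_problem()].
#' @return object of class `nmr_batch`: `fits` (per-row `nmr_fit`, in row
#'   order), `table` (long format: `row`, `label`, `signal`, `parameter`,
#'   `value`, `sd`, `converged`), and `failures` (row indices with
#'   diagnostics).
#' @export
run_batch <- function(plan, reg, signals, options = list()) {
  stopifnot(inherits(plan, "nmr_batch_plan"))
  series <- plan$series
  if (inherits(signals, "nmr_signal")) signals <- list(signals)

  ref_spec <- series_row(series, plan$reference)
  ref_prob <- fit_problem(ref_spec, reg, signals, options)
  ref_fit <- fit_signals(ref_prob)
  if (!ref_fit$converged) {
    stop("reference row ", plan$reference, " failed to fit: ", ref_fit$message)
  }

  n <- nrow(series$intensities)
  fits <- vector("list", n)
  fits[[plan$reference]] <- ref_fit
  failures <- list()
  prev_ok <- list() # last successful fit on each side of the reference

  for (row in plan$order[-1L]) {
    side <- if (row > plan$reference) "up" else "down"
    src <- if (plan$mode == "ref") ref_fit
           else prev_ok[[side]] %||% ref_fit
    sigs <- lapply(seq_along(signals), function(i) {
      .propagate_signal(signals[[i]], src$signals[[i]]$params)
    })
    spec <- series_row(series, row)
    prob <- fit_problem(spec, reg, sigs, options)
    res <- tryCatch(fit_signals(prob), error = function(e) e)
    failed <- inherits(res, "error") || !res$converged
    if (failed) {
      # one retry from the reference with global refinement on
      sigs2 <- lapply(seq_along(signals), function(i) {
        .propagate_signal(signals[[i]], ref_fit$signals[[i]]$params)
      })
      opts2 <- utils::modifyList(options, list(global_refine = TRUE))
      prob2 <- fit_problem(spec, reg, sigs2, opts2)
      res2 <- tryCatch(fit_signals(prob2), error = function(e) e)
      if (!inherits(res2, "error") && res2$converged) {
        res <- res2
        failed <- FALSE
      } else {
        failures[[length(failures) + 1L]] <- list(
          row = row,
          message = if (inherits(res, "error")) conditionMessage(res)
                    else res$message
        )
        if (!inherits(res, "error")) fits[[row]] <- res
        next
      }
    }
    fits[[row]] <- res
    if (plan$mode == "prev") prev_ok[[side]] <- res
  }

  rows <- which(!vapply(fits, is.null, logical(1)))
  table <- do.call(rbind, lapply(rows, function(r) {
    f <- fits[[r]]
    do.call(rbind, lapply(f$signals, function(s) {
      data.frame(row = r, label = series$labels[r], signal = s$id,
                 parameter = s$params$name, value = s$params$value,
                 sd = s$params$sd, converged = f$converged,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(table) <- NULL
  structure(list(fits = fits, table = table, failures = failures,
                 plan = plan),
            class = "nmr_batch")
}

#' @export
print.nmr_batch <- function(x, ...) {
  n <- length(x$fits)
  cat("<nmr_batch> ", n, " rows, ", length(x$failures), " failure(s), ",
      "reference row ", x$plan$reference, " (mode ", x$plan$mode, ")\n",
      sep = "")
  invisible(x)
}
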