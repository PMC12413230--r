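# Peak picking within a region, grouping of peaks into signals, and
# derivation of initial parameter values and bounds.

#' Define a spectral region
#'
#' @param ppm_min,ppm_max closed interval bounds in ppm (`ppm_min < ppm_max`).
#' @return object of class `nmr_region` (numeric length-2 vector).
#' @export
region <- function(ppm_min, ppm_max) {
  if (!is.finite(ppm_min) || !is.finite(ppm_max) || ppm_min >= ppm_max) {
    stop("need ppm_min < ppm_max")
  }
  structure(c(ppm_min, ppm_max), class = "nmr_region")
}

.region_idx <- function(spectrum, reg) {
  if (reg[1] < min(spectrum$ppm) - 1e-12 || reg[2] > max(spectrum$ppm) + 1e-12) {
    stop("region [", reg[1], ", ", reg[2], "] lies outside the spectrum axis")
  }
  idx <- which(spectrum$ppm >= reg[1] & spectrum$ppm <= reg[2])
  if (length(idx) < 8L) stop("region must contain at least 8 grid points")
  idx
}

# robust noise level from the outer fraction of region samples on each side
.estimate_noise <- function(y, edge_frac = 0.1) {
  n <- length(y)
  k <- max(4L, floor(edge_frac * n))
  d <- c(y[seq_len(k)], y[seq.int(n - k + 1L, n)])
  1.4826 * stats::median(abs(d - stats::median(d)))
}

#' Automated peak picking in a region
#'
#' Finds local maxima (strictly greater than both neighbours; a plateau of
#' equal maximal samples yields one peak at its centre point) whose apex
#' *and* topographic prominence exceed the detection threshold.  The
#' prominence requirement (apex height above the highest saddle separating
#' the peak from higher ground) discards noise wiggles riding on the
#' flanks of real peaks, which pass a bare height threshold.  The
#' `"auto"` threshold is `k * sigma_noise`, with `sigma_noise` the
#' median-absolute-deviation estimate over the outer 10% of region
#' samples on each side.
#'
#' @param spectrum an `nmr_spectrum`.
#' @param reg an [region()] within the spectrum axis.
#' @param threshold numeric intensity threshold, or `"auto"` (default).
#' @param k multiplier for the auto threshold (default 5).
#' @return data frame of class `nmr_peaks` with columns `position`,
#'   `intensity`, `source` (`"auto"`), sorted by ppm.
#' @export
pick_peaks <- function(spectrum, reg, threshold = "auto", k = 5) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  idx <- .region_idx(spectrum, reg)
  y <- spectrum$intensity[idx]
  x <- spectrum$ppm[idx]
  thr <- if (identical(threshold, "auto")) k * .estimate_noise(y) else as.numeric(threshold)

  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nruns <- length(r$values)
  apex <- integer(0)
  for (i in seq_len(nruns)) {
    left_ok <- i == 1L || r$values[i - 1L] < r$values[i]
    right_ok <- i == nruns || r$values[i + 1L] < r$values[i]
    if (i > 1L && i < nruns && left_ok && right_ok) {
      apex <- c(apex, starts[i] + (r$lengths[i] - 1L) %/% 2L)
    }
  }
  apex <- apex[y[apex] > thr]
  apex <- apex[.prominence(y, apex) > thr]
  out <- data.frame(position = x[apex], intensity = y[apex],
                    source = rep("auto", length(apex)),
                    stringsAsFactors = FALSE)
  class(out) <- c("nmr_peaks", "data.frame")
  out
}

# topographic prominence of each candidate apex: height above the higher
# of the two saddles on the walk towards higher ground (or the region edge)
.prominence <- function(y, apex) {
  vapply(apex, function(i) {
    h <- y[i]
    lmin <- h; j <- i
    while (j > 1L && y[j] <= h) { j <- j - 1L; lmin <- min(lmin, y[j]) }
    rmin <- h; j <- i
    while (j < length(y) && y[j] <= h) { j <- j + 1L; rmin <- min(rmin, y[j]) }
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Add a manually specified peak
#'
#' @param peaks an `nmr_peaks` data frame (possibly empty).
#' @param position apex position (ppm).
#' @param intensity apex intensity.
#' @return updated peak list, sorted by ppm.
#' @export
add_peak <- function(peaks, position, intensity) {
  out <- rbind(as.data.frame(peaks),
               data.frame(position = position, intensity = intensity,
                          source = "manual", stringsAsFactors = FALSE))
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("nmr_peaks", "data.frame")
  out
}

#' Group peaks into a signal
#'
#' Binds a set of picked/manual peaks to a multiplet model.  The number of
#' peaks must equal the model's peak count; the same peaks may be grouped
#' into several signals to describe overlapping multiplets sharing a peak.
#'
#' @param peaks `nmr_peaks` rows belonging to the signal.
#' @param model model name (see [list_models()]) or `nmr_model`.
#' @param id signal identifier (default: the model name).
#' @param reg the signal's [region()] (optional until fitting).
#' @param allow_negative permit negative total intensity (difference
#'   spectra); default `FALSE` keeps the lower bound of `I` at zero.
#' @return an unresolved `nmr_signal`; run [initialize_parameters()] to
#'   derive starting values and bounds.
#' @export
group_signal <- function(peaks, model, id = NULL, reg = NULL,
                         allow_negative = FALSE) {
  model <- resolve_model(model)
  if (nrow(peaks) != model$n_peaks) {
    stop("model '", model$name, "' expects ", model$n_peaks,
         " peak(s), got ", nrow(peaks))
  }
  structure(
    list(id = id %||% model$name, model = model$name,
         peaks = as.data.frame(peaks), region = reg,
         allow_negative = allow_negative,
         params = NULL, suggested = suggest_models(model$n_peaks)),
    class = "nmr_signal"
  )
}

# measure full width at half maximum around one apex; NA if unresolvable
.measure_fwhm <- function(x, y, i) {
  half <- y[i] / 2
  l <- i; while (l > 1L && y[l] > half) l <- l - 1L
  r <- i; while (r < length(y) && y[r] > half) r <- r + 1L
  if (y[l] > half || y[r] > half) return(NA_real_)
  xl <- x[l] + (x[l + 1L] - x[l]) * (half - y[l]) / (y[l + 1L] - y[l])
  xr <- x[r - 1L] + (x[r] - x[r - 1L]) * (half - y[r - 1L]) / (y[r] - y[r - 1L])
  xr - xl
}

.resolve_bounds <- function(specs, inits, allow_negative = FALSE) {
  out <- data.frame(name = specs$name, init = inits,
                    lower = NA_real_, upper = NA_real_,
                    value = NA_real_, sd = NA_real_, at_bound = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(specs))) {
    if (specs$mode[i] == "absolute") {
      lo <- specs$lower[i]; up <- specs$upper[i]
    } else if (specs$name[i] != "lw" &&
               (specs$unit[i] == "ppm" || specs$name[i] == "x0" ||
                grepl("^J", specs$name[i]))) {
      # position-like: signed ppm offsets around the init
      lo <- inits[i] + specs$lower[i]; up <- inits[i] + specs$upper[i]
    } else {
      # scale-like: multiplicative factors around the init
      lo <- inits[i] * specs$lower[i]; up <- inits[i] * specs$upper[i]
      if (lo > up) { tmp <- lo; lo <- up; up <- tmp } # negative init
    }
    if (grepl("^J", specs$name[i])) lo <- max(lo, 0)
    if (specs$name[i] == "I" && !allow_negative) lo <- max(lo, 0)
    if (!(lo <= inits[i] && inits[i] <= up)) {
      stop("resolved bounds do not bracket the initial value for '",
           specs$name[i], "' (init ", format(inits[i]), ", bounds [",
           format(lo), ", ", format(up), "])")
    }
    out$lower[i] <- lo; out$upper[i] <- up
  }
  out
}

#' Derive initial parameter values and bounds for a signal
#'
#' Initialization follows the peak list: the signal chemical shift is the
#' centre of the member peak positions, the total intensity is the sum of
#' apex intensities (component weights sum to one, so resolved apexes add
#' up to `I`), and each coupling constant is solved from the inter-peak
#' spacings by least squares against the pattern's offset coefficients
#' (for a doublet this is the position difference; for a doublet of
#' doublets `J1 = ((p3+p4)-(p1+p2))/2`, `J2 = ((p4-p3)+(p2-p1))/2`).  The
#' linewidth starts from the median measured half-height width of the
#' member peaks when resolvable, falling back to the model default or, for
#' heavily overlapped regions, `region span / (20 n_peaks)`.  Relative
#' bounds from the model specs are then resolved around these inits.
#'
#' @param signal an `nmr_signal` from [group_signal()].
#' @param spectrum the `nmr_spectrum` the peaks came from.
#' @return the signal with a resolved `params` table (columns `name`,
#'   `init`, `lower`, `upper`, `value`, `sd`, `at_bound`).  Idempotent:
#'   re-running reproduces the same state.
#' @export
initialize_parameters <- function(signal, spectrum) {
  stopifnot(inherits(signal, "nmr_signal"))
  model <- get_model(signal$model)
  pk <- signal$peaks[order(signal$peaks$position), , drop = FALSE]
  pos <- pk$position

  if (model$n_peaks > 1L && any(diff(pos) <= 0)) {
    stop("model '", model$name, "' requires ", model$n_peaks,
         " distinct peak positions; coincident peaks suggest a ",
         "lower-multiplicity model")
  }

  x0 <- mean(pos)
  I <- sum(pk$intensity)
  jn <- model$j_names
  J <- numeric(0)
  if (length(jn)) {
    # offsets of the canonical pattern, sorted as positions sort
    jcanon <- 3^(1 - seq_along(jn))
    ord <- order(as.vector(model$offsets %*% jcanon))
    C <- model$offsets[ord, , drop = FALSE]
    J <- as.vector(stats::lm.fit(cbind(1, C), pos)$coefficients[-1L])
    J <- pmax(J, 0)
    names(J) <- jn
  }

  reg <- signal$region %||% region(min(spectrum$ppm), max(spectrum$ppm))
  idx <- .region_idx(spectrum, reg)
  x <- spectrum$ppm[idx]; y <- spectrum$intensity[idx]
  wds <- vapply(pos, function(p) {
    i <- idx[which.min(abs(x - p))] - idx[1L] + 1L
    .measure_fwhm(x, y, i)
  }, numeric(1))
  lw <- if (any(is.finite(wds))) stats::median(wds, na.rm = TRUE) / 2
        else model$specs$init[model$specs$name == "lw"]
  if (!is.finite(lw) || lw <= 0) lw <- (reg[2] - reg[1]) / (20 * model$n_peaks)

  defaults <- stats::setNames(model$specs$init, model$specs$name)
  inits <- c(x0 = x0, I = I, lw = lw, a = unname(defaults["a"]), J)
  inits <- inits[model$specs$name]
  signal$params <- .resolve_bounds(model$specs, unname(inits),
                                  allow_negative = signal$allow_negative)
  signal$region <- reg
  signal
}

#' Build a resolved signal directly from parameter values
#'
#' Convenience for synthetic work and scripted fits: takes concrete
#' initial values (e.g. perturbed ground truth) and resolves the model's
#' default bounds around them, skipping peak picking.
#'
#' @param model model name or `nmr_model`.
#' @param values named vector/list of initial values covering `x0`, `I`,
#'   `lw`, `a` and all couplings.
#' @param reg the signal's [region()].
#' @param id signal identifier.
#' @param allow_negative permit negative `I`.
#' @return a resolved `nmr_signal`.
#' @export
signal_instance <- function(model, values, reg, id = NULL,
                            allow_negative = FALSE) {
  model <- resolve_model(model)
  values <- unlist(values)
  miss <- setdiff(model$specs$name, names(values))
  if (length(miss)) stop("missing value(s): ", paste(miss, collapse = ", "))
  inits <- unname(values[model$specs$name])
  sig <- structure(
    list(id = id %||% model$name, model = model$name,
         peaks = data.frame(position = numeric(0), intensity = numeric(0),
                            source = character(0)),
         region = reg, allow_negative = allow_negative,
         params = .resolve_bounds(model$specs, inits,
                                  allow_negative = allow_negative),
         suggested = character(0)),
    class = "nmr_signal"
  )
  sig
}

#' @export
print.nmr_signal <- function(x, ...) {
  cat("<nmr_signal> '", x$id, "' (model ", x$model, ")\n", sep = "")
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}
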