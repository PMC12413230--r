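# Signal models: first-order multiplet patterns built on the pseudo-Voigt
# profile, plus the declarative constructor used both for the built-in
# library and for user-defined models.

.default_specs <- function(j_names) {
  base <- data.frame(
    name  = c("x0", "I", "lw", "a"),
    init  = c(NA, NA, 0.001, 0.5),
    lower = c(-0.05, 0.01, 0.1, 0),
    upper = c(0.05, 100, 10, 1),
    mode  = c("relative", "relative", "relative", "absolute"),
    unit  = c("ppm", "intensity", "ppm", "dimensionless"),
    stringsAsFactors = FALSE
  )
  if (length(j_names)) {
    base <- rbind(base, data.frame(
      name = j_names, init = NA_real_,
      lower = -0.05, upper = 0.05,
      mode = "relative", unit = "ppm",
      stringsAsFactors = FALSE
    ))
  }
  base
}

#' Construct a multiplet signal model
#'
#' A signal model couples (i) a first-order multiplet pattern -- component
#' peak offsets expressed as signed half-integer combinations of named
#' coupling constants, with mirror-symmetric relative weights summing to
#' one -- with (ii) a table of parameter specifications (default initial
#' value, bounds, and bound mode) used by the optimizer.
#'
#' Every model has the shape parameters `x0` (signal chemical shift, ppm),
#' `I` (total signal intensity, distributed over component peaks by the
#' pattern weights), `lw` (width parameter, ppm) and `a` (Gaussian
#' fraction), plus one parameter per named coupling constant (ppm).
#'
#' Bound modes: `"absolute"` bounds are taken as-is; `"relative"` bounds
#' are resolved around the initial value when a signal is initialized --
#' additively for position-like parameters (`x0`, couplings; the numbers
#' are signed ppm offsets) and multiplicatively for scale-like parameters
#' (`I`, `lw`; the numbers are factors).
#'
#' @param name model name (unique in the registry).
#' @param offsets numeric matrix with one row per component peak and one
#'   column per coupling constant (may have zero columns for a singlet);
#'   entry `(i, k)` is the coefficient of coupling `k` in the ppm offset of
#'   peak `i` from `x0`.
#' @param weights positive relative amplitudes, one per peak; normalized to
#'   sum to one.
#' @param j_names names of the coupling-constant parameters, one per offset
#'   column.
#' @param specs optional data frame overriding the default parameter
#'   specifications (columns `name`, `init`, `lower`, `upper`, `mode`,
#'   `unit`).
#' @return an object of class `nmr_model`.
#' @seealso [first_order_multiplet()] for the usual constructor,
#'   [register_model()], [simulate_signal()].
#' @export
signal_model <- function(name, offsets, weights, j_names = character(),
                         specs = NULL) {
  offsets <- as.matrix(offsets)
  if (length(j_names) == 0L && ncol(offsets) == 0L) {
    offsets <- matrix(0, nrow = nrow(offsets), ncol = 0L)
  }
  if (ncol(offsets) != length(j_names)) {
    stop("model '", name, "': 'offsets' must have one column per entry of 'j_names'")
  }
  if (nrow(offsets) != length(weights)) {
    stop("model '", name, "': 'offsets' and 'weights' must describe the same number of peaks")
  }
  if (any(weights <= 0)) {
    stop("model '", name, "': 'weights' must be positive")
  }
  weights <- weights / sum(weights)

  # first-order patterns are mirror symmetric: check at canonical, distinct
  # coupling values so degenerate coincidences cannot mask asymmetry
  jcanon <- 3^(1 - seq_along(j_names))
  pos <- as.vector(offsets %*% jcanon)
  if (length(pos) == 0L) pos <- rep(0, length(weights))
  ord <- order(pos)
  if (max(abs(sort(pos) + rev(sort(pos)))) > 1e-9) {
    stop("model '", name, "': 'offsets' must be symmetric about 0")
  }
  if (max(abs(weights[ord] - rev(weights[ord]))) > 1e-9) {
    stop("model '", name, "': 'weights' must be mirror-symmetric")
  }

  if (is.null(specs)) specs <- .default_specs(j_names)
  needed <- c("x0", "I", "lw", "a", j_names)
  if (!all(needed %in% specs$name)) {
    stop("model '", name, "': missing parameter spec for ",
         paste(setdiff(needed, specs$name), collapse = ", "))
  }
  if (anyDuplicated(specs$name)) {
    stop("model '", name, "': duplicated parameter spec names")
  }
  ok_init <- is.na(specs$init) | specs$mode == "relative" |
    (specs$lower <= specs$init & specs$init <= specs$upper)
  if (!all(ok_init)) {
    stop("model '", name, "': default init outside bounds for parameter '",
         specs$name[!ok_init][1L], "'")
  }
  specs <- specs[match(needed, specs$name), , drop = FALSE]
  rownames(specs) <- NULL

  structure(
    list(name = name, n_peaks = nrow(offsets), j_names = j_names,
         offsets = offsets, weights = weights, specs = specs),
    class = "nmr_model"
  )
}

#' Build a first-order multiplet by successive splitting
#'
#' Constructs the pattern produced by coupling to groups of equivalent
#' nuclei: each entry of `splits` is the multiplicity contributed by one
#' coupling constant (2 = doublet splitting, 3 = triplet splitting, ...).
#' Offsets are centred multiples of each coupling and the weights are the
#' binomial convolution, e.g. `c(3)` gives 1:2:1, `c(2, 2)` a doublet of
#' doublets with four equal peaks, and `c(2, 3)` a doublet of triplets.
#'
#' @param name model name.
#' @param splits integer vector of per-coupling multiplicities (>= 2);
#'   empty for a singlet.
#' @param j_names coupling parameter names; defaults to `"J"` for a single
#'   coupling and `"J1"`, `"J2"`, ... otherwise.
#' @inheritParams signal_model
#' @return an `nmr_model`.
#' @examples
#' dt <- first_order_multiplet("doublet_of_triplets", c(2, 3))
#' dt$weights # 1/8 1/4 1/8 mirrored
#' @export
first_order_multiplet <- function(name, splits, j_names = NULL, specs = NULL) {
  splits <- as.integer(splits)
  if (any(splits < 2L)) stop("'splits' entries must be >= 2")
  if (is.null(j_names)) {
    j_names <- if (length(splits) <= 1L) rep("J", length(splits))
               else paste0("J", seq_along(splits))
  }
  if (length(j_names) != length(splits)) {
    stop("'j_names' must match 'splits' in length")
  }
  offsets <- matrix(0, nrow = 1, ncol = 0)
  weights <- 1
  for (k in seq_along(splits)) {
    m <- splits[k]
    off_k <- seq_len(m) - (m + 1) / 2          # centred multiples of J_k
    w_k <- choose(m - 1, seq_len(m) - 1) / 2^(m - 1)
    offsets <- cbind(
      offsets[rep(seq_len(nrow(offsets)), each = m), , drop = FALSE],
      rep(off_k, times = nrow(offsets))
    )
    weights <- as.vector(outer(w_k, weights))
  }
  colnames(offsets) <- j_names
  signal_model(name, offsets, weights, j_names, specs = specs)
}

#' @export
print.nmr_model <- function(x, ...) {
  cat("<nmr_model> ", x$name, ": ", x$n_peaks, " peak(s)",
      if (length(x$j_names)) paste0(", couplings ", paste(x$j_names, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' Expand a multiplet pattern into component peaks
#'
#' Given a signal chemical shift and concrete coupling-constant values,
#' returns the component-peak positions and relative weights.  A doublet
#' with coupling `J` yields peaks at `x0 +/- J/2` with weights 1/2; a
#' triplet peaks at `x0 - J, x0, x0 + J` with weights 1/4, 1/2, 1/4; a
#' doublet of doublets the four sign combinations `x0 +/- J1/2 +/- J2/2`.
#'
#' @param model an `nmr_model` or a registered model name.
#' @param x0 signal chemical shift (ppm).
#' @param J named numeric vector/list of coupling constants (ppm); all
#'   values must be non-negative.  May be empty for a singlet.
#' @return data frame with columns `position` (ppm, ascending) and
#'   `weight` (summing to 1).
#' @export
expand_multiplet <- function(model, x0, J = numeric()) {
  model <- resolve_model(model)
  J <- unlist(J)
  if (length(model$j_names)) {
    if (!all(model$j_names %in% names(J))) {
      stop("missing coupling value(s): ",
           paste(setdiff(model$j_names, names(J)), collapse = ", "))
    }
    J <- J[model$j_names]
    if (any(J < 0)) stop("coupling constants must be >= 0")
    pos <- x0 + as.vector(model$offsets %*% J)
  } else {
    pos <- rep(x0, model$n_peaks)
  }
  ord <- order(pos)
  data.frame(position = pos[ord], weight = model$weights[ord])
}

#' Simulate one signal on a chemical-shift grid
#'
#' Sums the pseudo-Voigt profiles of the component peaks given by
#' [expand_multiplet()].  Component `i` has apex height `I * weight_i`; all
#' components share `lw` and `a`.
#'
#' @param model an `nmr_model` or registered model name.
#' @param values named list/vector with entries `x0`, `I`, `lw`, `a` and
#'   one entry per coupling-constant name of the model.
#' @param x chemical-shift grid (ppm).
#' @return intensity vector, same length as `x`.
#' @export
simulate_signal <- function(model, values, x) {
  model <- resolve_model(model)
  values <- as.list(values)
  needed <- model$specs$name
  miss <- setdiff(needed, names(values))
  if (length(miss)) {
    stop("missing parameter value(s) for model '", model$name, "': ",
         paste(miss, collapse = ", "))
  }
  pk <- expand_multiplet(model, values$x0,
                         unlist(values[model$j_names]))
  y <- numeric(length(x))
  for (i in seq_len(nrow(pk))) {
    y <- y + pseudo_voigt(x, pk$position[i], values$I * pk$weight[i],
                          values$lw, values$a)
  }
  y
}

#' Simulate a spectrum as a sum of signals
#'
#' @param signals list of `list(model = , values = )` entries, where
#'   `model` is an `nmr_model` or registered name and `values` the
#'   parameter map for [simulate_signal()].
#' @param x chemical-shift grid (ppm); must be non-empty.
#' @return intensity vector: the elementwise sum of the individual signal
#'   simulations (zero vector for an empty signal list).
#' @export
simulate_spectrum <- function(signals, x) {
  if (!length(x)) stop("'x' must be a non-empty grid")
  y <- numeric(length(x))
  for (s in signals) {
    ys <- simulate_signal(s$model, s$values, x)
    if (length(ys) != length(y)) stop("signal simulated on a mismatched grid")
    y <- y + ys
  }
  y
}
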