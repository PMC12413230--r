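# Model registry: the built-in multiplet library plus user-registered models.

.model_registry <- new.env(parent = emptyenv())

.builtin_models <- function() {
  list(
    first_order_multiplet("singlet", integer()),
    first_order_multiplet("doublet", 2L),
    first_order_multiplet("triplet", 3L),
    first_order_multiplet("quadruplet", 4L),
    first_order_multiplet("doublet_of_doublets", c(2L, 2L))
  )
}

.register_builtins <- function() {
  for (m in .builtin_models()) {
    assign(m$name, m, envir = .model_registry)
  }
}

resolve_model <- function(model) {
  if (inherits(model, "nmr_model")) return(model)
  if (is.character(model) && length(model) == 1L) return(get_model(model))
  stop("expected an 'nmr_model' or a registered model name")
}

#' Register a signal model
#'
#' Makes a model available to [suggest_models()], [group_signal()] and the
#' fitting machinery.  Names must be unique; pass `overwrite = TRUE` to
#' replace an existing (non-built-in) definition.
#'
#' @param model an `nmr_model` (see [signal_model()],
#'   [first_order_multiplet()], [read_model_file()]).
#' @param overwrite replace an existing model of the same name.
#' @return the model name, invisibly.
#' @export
register_model <- function(model, overwrite = FALSE) {
  if (!inherits(model, "nmr_model")) stop("'model' must be an 'nmr_model'")
  if (!overwrite && exists(model$name, envir = .model_registry)) {
    stop("a model named '", model$name, "' is already registered")
  }
  assign(model$name, model, envir = .model_registry)
  invisible(model$name)
}

#' Remove a registered model
#' @param name model name.
#' @export
unregister_model <- function(name) {
  if (exists(name, envir = .model_registry)) {
    rm(list = name, envir = .model_registry)
  }
  invisible(NULL)
}

#' Retrieve a registered model by name
#' @param name model name.
#' @return an `nmr_model`.
#' @export
get_model <- function(name) {
  if (!exists(name, envir = .model_registry)) {
    stop("no registered model named '", name, "'; see list_models()")
  }
  get(name, envir = .model_registry)
}

#' List registered model names
#' @return character vector, sorted.
#' @export
list_models <- function() {
  sort(ls(envir = .model_registry))
}

#' Suggest models matching a peak count
#'
#' Returns every registered model whose pattern has exactly `n_peaks`
#' component peaks, ordered by name: e.g. four peaks suggests both the
#' doublet of doublets and the quadruplet.
#'
#' @param n_peaks number of picked peaks (>= 1).
#' @return character vector of model names (possibly empty).
#' @export
suggest_models <- function(n_peaks) {
  if (n_peaks < 1) stop("'n_peaks' must be >= 1")
  nm <- list_models()
  nm[vapply(nm, function(n) get_model(n)$n_peaks == n_peaks, logical(1))]
}

#' Load a user-defined model from a declarative JSON file
#'
#' The file holds one model: its name, coupling names, per-peak offset
#' coefficients (signed half-integer combinations of the couplings),
#' relative weights, and optional parameter-spec overrides.  Example:
#'
#' ```json
#' {
#'   "name": "doublet_of_triplets",
#'   "j_names": ["J1", "J2"],
#'   "offsets": [[-0.5,-1],[-0.5,0],[-0.5,1],[0.5,-1],[0.5,0],[0.5,1]],
#'   "weights": [1, 2, 1, 1, 2, 1],
#'   "specs": [
#'     {"name": "lw", "init": 0.002, "lower": 0.1, "upper": 10,
#'      "mode": "relative", "unit": "ppm"}
#'   ]
#' }
#' ```
#'
#' @param path path to the model file.
#' @param register register the model after parsing (default `TRUE`).
#' @return the `nmr_model`, invisibly.
#' @export
read_model_file <- function(path, register = TRUE) {
  def <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (f in c("name", "offsets", "weights")) {
    if (is.null(def[[f]])) stop("model file '", path, "': missing field '", f, "'")
  }
  j_names <- if (is.null(def$j_names)) character() else as.character(def$j_names)
  offsets <- as.matrix(def$offsets)
  if (length(j_names) == 0L) offsets <- matrix(0, nrow = length(def$weights), ncol = 0)
  specs <- .default_specs(j_names)
  if (!is.null(def$specs)) {
    ov <- as.data.frame(def$specs, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(ov))) {
      j <- match(ov$name[i], specs$name)
      if (is.na(j)) stop("model file '", path, "': spec for unknown parameter '", ov$name[i], "'")
      for (col in intersect(names(ov), c("init", "lower", "upper", "mode", "unit"))) {
        if (!is.na(ov[[col]][i])) specs[[col]][j] <- ov[[col]][i]
      }
    }
  }
  m <- signal_model(def$name, offsets, as.numeric(def$weights), j_names, specs = specs)
  if (register) register_model(m)
  invisible(m)
}
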