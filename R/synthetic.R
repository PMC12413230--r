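# Synthetic spectra and series with known ground truth, and the
# parameter-recovery / multiplet-vs-peaks experiments built on them.

#' Define a synthetic ground truth
#'
#' @param signals list of `list(model = , values = , id = )` entries:
#'   a registered model name (or `nmr_model`) with a complete named
#'   parameter map.
#' @param from,to,n ppm grid specification (ascending, `n` points).
#' @param sigma standard deviation of the additive i.i.d. Gaussian noise
#'   (intensity units); 0 for noiseless.
#' @param seed RNG seed: the same truth generates bit-identical spectra.
#' @param sf_mhz spectrometer frequency (MHz) attached to the output.
#' @return object of class `nmr_truth`.
#' @export
ground_truth <- function(signals, from, to, n, sigma = 0, seed = 1L,
                         sf_mhz = 500) {
  stopifnot(from < to, n >= 8, sigma >= 0)
  for (s in signals) resolve_model(s$model) # fail early on unknown models
  structure(list(signals = signals, from = from, to = to, n = as.integer(n),
                 sigma = sigma, seed = as.integer(seed), sf_mhz = sf_mhz),
            class = "nmr_truth")
}

.truth_grid <- function(truth) seq(truth$from, truth$to, length.out = truth$n)

.truth_clean <- function(truth, x = .truth_grid(truth)) {
  simulate_spectrum(lapply(truth$signals, function(s) {
    list(model = s$model, values = s$values)
  }), x)
}

#' Generate a synthetic 1D spectrum
#'
#' Simulates the truth's signals on its grid and adds seeded i.i.d.
#' Gaussian noise of standard deviation `sigma` (`sigma = 0` returns the
#' exact simulation).
#'
#' @param truth an [ground_truth()].
#' @return an `nmr_spectrum`.
#' @export
generate_spectrum <- function(truth) {
  stopifnot(inherits(truth, "nmr_truth"))
  x <- .truth_grid(truth)
  y <- .truth_clean(truth, x)
  if (truth$sigma > 0) {
    y <- y + .with_seed(truth$seed,
                        stats::rnorm(length(x), 0, truth$sigma))
  }
  spectrum1d(x, y, sf_mhz = truth$sf_mhz, meta = list(synthetic = TRUE))
}

#' Trajectory presets for synthetic series
#'
#' Time functions of the 0-based row index used by [generate_series()]:
#' exponential decay `v0 exp(-t / tau)`, linear drift `v0 + slope t`, and
#' a logistic rise from `v0` to `v0 + vmax`.
#'
#' @param v0 starting value.
#' @param tau decay constant (rows).
#' @param slope drift per row.
#' @param vmax logistic amplitude.
#' @param rate logistic steepness (per row).
#' @param midpoint logistic midpoint (row).
#' @return a function of `t`.
#' @name trajectories
NULL

#' @rdname trajectories
#' @export
traj_exponential <- function(v0, tau) function(t) v0 * exp(-t / tau)

#' @rdname trajectories
#' @export
traj_linear <- function(v0, slope) function(t) v0 + slope * t

#' @rdname trajectories
#' @export
traj_logistic <- function(v0, vmax, rate, midpoint) {
  function(t) v0 + vmax / (1 + exp(-rate * (t - midpoint)))
}

#' Coupled intensity trajectories of a three-step enzymatic cascade
#'
#' Closed-form solution of the linear cascade A -> B -> C -> D (a
#' glucose -> glucose-6-phosphate -> fructose-6-phosphate ->
#' fructose-1,6-bisphosphate shape): the substrate decays exponentially,
#' the two intermediates accumulate transiently, and the product rises
#' sigmoid-like to the initial substrate amount.
#'
#' @param A0 initial substrate intensity.
#' @param k rate constants per row, length 3, all distinct.
#' @return named list of four trajectory functions (`A`, `B`, `C`, `D`).
#' @export
traj_cascade <- function(A0 = 1, k = c(0.30, 0.20, 0.12)) {
  stopifnot(length(k) == 3, all(k > 0), !anyDuplicated(k))
  k1 <- k[1]; k2 <- k[2]; k3 <- k[3]
  list(
    A = function(t) A0 * exp(-k1 * t),
    B = function(t) A0 * k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t)),
    C = function(t) A0 * k1 * k2 * (
      exp(-k1 * t) / ((k2 - k1) * (k3 - k1)) +
      exp(-k2 * t) / ((k1 - k2) * (k3 - k2)) +
      exp(-k3 * t) / ((k1 - k3) * (k2 - k3))),
    D = function(t) A0 * (1 -
      k2 * k3 * exp(-k1 * t) / ((k2 - k1) * (k3 - k1)) -
      k1 * k3 * exp(-k2 * t) / ((k1 - k2) * (k3 - k2)) -
      k1 * k2 * exp(-k3 * t) / ((k1 - k3) * (k2 - k3)))
  )
}

#' Generate a synthetic pseudo-2D series
#'
#' Row `r` (0-based time `t = r - 1`) uses the truth parameters with the
#' trajectory functions applied; per-row noise is seeded from the truth
#' seed so the whole series is reproducible.
#'
#' @param truth an [ground_truth()]; its parameter values are the row-0
#'   state unless a trajectory overrides them.
#' @param trajectories list of `list(signal = , param = , fn = )`
#'   entries: `signal` a signal index into `truth$signals`, `param` a
#'   parameter name, `fn` a function of the 0-based row index.
#' @param n_rows number of rows.
#' @param labels optional row labels (default `1:n_rows`).
#' @return list with `series` (an `nmr_series`) and `truth_table` (long
#'   data frame: `row`, `signal`, `parameter`, `value`).
#' @export
generate_series <- function(truth, trajectories, n_rows, labels = NULL) {
  stopifnot(inherits(truth, "nmr_truth"), n_rows >= 1)
  x <- .truth_grid(truth)
  mat <- matrix(0, nrow = n_rows, ncol = length(x))
  tt <- list()
  noise <- if (truth$sigma > 0) {
    .with_seed(truth$seed,
               matrix(stats::rnorm(n_rows * length(x), 0, truth$sigma),
                      nrow = n_rows))
  }
  for (r in seq_len(n_rows)) {
    t <- r - 1
    sigs <- truth$signals
    for (tr in trajectories) {
      v <- tr$fn(t)
      p <- tr$param
      ok <- switch(p,
                   lw = v > 0,
                   a = v >= 0 && v <= 1,
                   I = v >= 0,
                   !grepl("^J", p) || v >= 0)
      if (!is.finite(v) || !ok) {
        stop("trajectory for signal ", tr$signal, " parameter '", p,
             "' produced an out-of-bounds value (", format(v),
             ") at row ", r)
      }
      sigs[[tr$signal]]$values[[p]] <- v
    }
    for (i in seq_along(sigs)) {
      tt[[length(tt) + 1L]] <- data.frame(
        row = r, signal = i,
        parameter = names(sigs[[i]]$values),
        value = unlist(sigs[[i]]$values),
        stringsAsFactors = FALSE
      )
    }
    mat[r, ] <- simulate_spectrum(lapply(sigs, function(s) {
      list(model = s$model, values = s$values)
    }), x)
    if (!is.null(noise)) mat[r, ] <- mat[r, ] + noise[r, ]
  }
  truth_table <- do.call(rbind, tt)
  rownames(truth_table) <- NULL
  list(series = spectrum_series(x, mat, labels = labels,
                                sf_mhz = truth$sf_mhz,
                                meta = list(synthetic = TRUE)),
       truth_table = truth_table)
}

#' Perturb true parameter values into starting values
#'
#' Emulates initialization error for recovery experiments.  `I`, `lw`,
#' `a` and couplings are scaled by `1 + frac * u` with `u ~ U(-1, 1)`
#' (`a` clipped to `[0, 1]`).  Position-like perturbations are bounded by
#' the lineshape scale, because in practice they come from the peak list
#' and are grid-accurate: the chemical shift (whose ppm origin is
#' arbitrary, so a relative perturbation would be meaningless) is shifted
#' by `frac * u * 5 lw`, and a coupling shift is capped at `2 lw` so
#' that large couplings (many linewidths) are not displaced out of the
#' optimization basin.
#'
#' @param values named true parameter list.
#' @param frac perturbation fraction (default 0.1).
#' @param rfun function drawing `n` values in `[-1, 1]`; default uniform.
#'   Call inside seeded code for reproducibility.
#' @return perturbed named list.
#' @export
perturb_values <- function(values, frac = 0.1,
                           rfun = function(n) stats::runif(n, -1, 1)) {
  values <- as.list(values)
  u <- rfun(length(values))
  names(u) <- names(values)
  lw <- values$lw
  out <- values
  for (p in names(values)) {
    out[[p]] <- if (p == "x0") {
      values$x0 + frac * u[[p]] * 5 * lw
    } else if (grepl("^J", p)) {
      values[[p]] + sign(u[[p]]) * min(frac * abs(u[[p]]) * values[[p]],
                                       2 * lw)
    } else {
      values[[p]] * (1 + frac * u[[p]])
    }
  }
  out$a <- min(max(out$a, 0), 1)
  out
}

#' The triplet-plus-quartet validation design
#'
#' Two overlapping multiplets on one grid: a 1:2:1 triplet and a 1:3:3:1
#' quartet whose centres are `gap_lw` linewidths apart, with noise set
#' from the signal-to-noise ratio SNR = (max noiseless intensity) / sigma.
#'
#' @param gap_lw centre-to-centre gap in units of `lw` (default 20,
#'   well separated; 5 is heavy overlap).
#' @param snr signal-to-noise ratio (`Inf` for noiseless).
#' @param seed RNG seed.
#' @param lw linewidth parameter (ppm).
#' @return an [ground_truth()] with signals `triplet` and `quadruplet`.
#' @export
triplet_quartet_truth <- function(gap_lw = 20, snr = Inf, seed = 1L,
                                  lw = 0.004) {
  gap <- gap_lw * lw
  sigs <- list(
    list(id = "triplet", model = "triplet",
         values = list(x0 = 2.1 + gap / 2, I = 1.0, lw = lw, a = 0.5,
                       J = 0.03)),
    list(id = "quadruplet", model = "quadruplet",
         values = list(x0 = 2.1 - gap / 2, I = 0.8, lw = lw, a = 0.5,
                       J = 0.02))
  )
  truth <- ground_truth(sigs, from = 1.7, to = 2.5, n = 2048,
                        sigma = 0, seed = seed)
  if (is.finite(snr)) {
    truth$sigma <- max(.truth_clean(truth)) / snr
  }
  truth
}

#' Acetate-like isotopologue ground truth
#'
#' Four co-located methyl signals mimicking the isotopic forms of
#' acetate: a singlet (no carbon-13), a doublet with a small two-bond
#' coupling, a doublet with a large one-bond coupling (ratio about 20),
#' and a doublet of doublets combining both.  Species amounts are given
#' as fractions of the total intensity.
#'
#' @param fractions length-4 fractions (singlet, small-J doublet,
#'   large-J doublet, doublet of doublets); need not sum to 1 exactly
#'   (they are normalized).
#' @param total total intensity across species.
#' @param snr signal-to-noise ratio (`Inf` for noiseless).
#' @param seed RNG seed.
#' @return an [ground_truth()]; couplings are 6 Hz and 127 Hz at 500 MHz
#'   (0.012 and 0.254 ppm).
#' @export
acetate_truth <- function(fractions = c(0.05, 0.10, 0.75, 0.10),
                          total = 1, snr = Inf, seed = 1L) {
  stopifnot(length(fractions) == 4, all(fractions > 0))
  fr <- fractions / sum(fractions)
  x0 <- 1.90; lw <- 0.002; a <- 0.5
  j_small <- 6 / 500; j_large <- 127 / 500
  sigs <- list(
    list(id = "s", model = "singlet",
         values = list(x0 = x0, I = total * fr[1], lw = lw, a = a)),
    list(id = "d_small", model = "doublet",
         values = list(x0 = x0, I = total * fr[2], lw = lw, a = a,
                       J = j_small)),
    list(id = "d_large", model = "doublet",
         values = list(x0 = x0, I = total * fr[3], lw = lw, a = a,
                       J = j_large)),
    list(id = "dd", model = "doublet_of_doublets",
         values = list(x0 = x0, I = total * fr[4], lw = lw, a = a,
                       J1 = j_large, J2 = j_small))
  )
  truth <- ground_truth(sigs, from = 1.55, to = 2.25, n = 4096,
                        sigma = 0, seed = seed, sf_mhz = 500)
  if (is.finite(snr)) truth$sigma <- max(.truth_clean(truth)) / snr
  truth
}

# fit one generated spectrum from perturbed-truth starts; returns the
# nmr_fit and the per-parameter relative errors against the truth
.fit_truth_once <- function(truth, frac = 0.1, options = list()) {
  spec <- generate_spectrum(truth)
  reg <- region(truth$from, truth$to)
  starts <- .with_seed(truth$seed + 31L, lapply(truth$signals, function(s) {
    perturb_values(s$values, frac = frac)
  }))
  sigs <- lapply(seq_along(truth$signals), function(i) {
    signal_instance(truth$signals[[i]]$model, starts[[i]], reg,
                    id = truth$signals[[i]]$id %||% paste0("signal_", i))
  })
  prob <- fit_problem(spec, reg, sigs, options)
  fit <- fit_signals(prob)
  err <- do.call(rbind, lapply(seq_along(truth$signals), function(i) {
    tv <- unlist(truth$signals[[i]]$values)
    p <- fit$signals[[i]]$params
    data.frame(signal = sigs[[i]]$id, parameter = p$name,
               truth = unname(tv[p$name]), estimate = p$value, sd = p$sd,
               rel_error = (p$value - unname(tv[p$name])) / unname(tv[p$name]),
               stringsAsFactors = FALSE)
  }))
  list(fit = fit, errors = err)
}

#' Parameter-recovery experiment over overlap and noise levels
#'
#' For each cell of the design (centre gap in linewidth units x SNR), the
#' triplet-plus-quartet spectrum is generated `replicates` times with
#' fresh noise, fitted from 10%-perturbed-truth starts, and the
#' per-parameter estimation errors are tabulated.
#'
#' @param gaps centre gaps in units of `lw` (default `c(20, 10, 5)`).
#' @param snrs SNR levels (default `c(Inf, 100, 50, 20)`).
#' @param replicates replicates per cell (default 20).
#' @param seed master seed; replicate seeds derive from it.
#' @param options fitting options.
#' @return list with `report` (per cell and parameter: mean bias, median
#'   absolute relative error, sd-calibration ratio = mean reported sd /
#'   ensemble sd of the estimates, convergence rate) and `details` (one
#'   row per replicate and parameter).
#' @export
recovery_experiment <- function(gaps = c(20, 10, 5),
                                snrs = c(Inf, 100, 50, 20),
                                replicates = 20, seed = 1L,
                                options = list()) {
  stopifnot(length(gaps) >= 1, length(snrs) >= 1, replicates >= 1)
  details <- list()
  rep_seeds <- .with_seed(seed, matrix(
    sample.int(.Machine$integer.max %/% 2, length(gaps) * length(snrs) * replicates),
    ncol = replicates))
  cell <- 0L
  for (gap in gaps) for (snr in snrs) {
    cell <- cell + 1L
    for (r in seq_len(replicates)) {
      truth <- triplet_quartet_truth(gap_lw = gap, snr = snr,
                                     seed = rep_seeds[cell, r])
      res <- tryCatch(.fit_truth_once(truth, options = options),
                      error = function(e) e)
      if (inherits(res, "error")) {
        details[[length(details) + 1L]] <- data.frame(
          gap = gap, snr = snr, rep = r, signal = NA, parameter = NA,
          truth = NA, estimate = NA, sd = NA, rel_error = NA,
          converged = FALSE, stringsAsFactors = FALSE)
      } else {
        d <- res$errors
        d$gap <- gap; d$snr <- snr; d$rep <- r
        d$converged <- res$fit$converged
        details[[length(details) + 1L]] <- d
      }
    }
  }
  details <- Reduce(.rbind_fill, details)

  key <- interaction(details$gap, details$snr, details$signal,
                     details$parameter, drop = TRUE)
  report <- do.call(rbind, lapply(split(details, key), function(d) {
    conv <- d$converged & is.finite(d$rel_error)
    data.frame(
      gap = d$gap[1], snr = d$snr[1], signal = d$signal[1],
      parameter = d$parameter[1],
      bias = mean(d$rel_error[conv]),
      median_abs_rel_error = stats::median(abs(d$rel_error[conv])),
      sd_ratio = if (sum(conv) > 2 && stats::sd(d$estimate[conv]) > 0)
        stats::median(d$sd[conv]) / stats::sd(d$estimate[conv]) else NA_real_,
      convergence_rate = mean(d$converged),
      replicates = nrow(d),
      stringsAsFactors = FALSE
    )
  }))
  rownames(report) <- NULL
  list(report = report, details = details)
}

#' Multiplet versus independent-peak fitting comparison
#'
#' The comparative experiment behind constrained multiplet fitting: each
#' replicate of a noisy doublet is fitted (a) with the doublet model over
#' the full region and (b) as two unconstrained, independently fitted
#' singlets -- each alone in its own half-region, split at the doublet
#' centre, which is how software that treats every peak as an independent
#' signal operates.  In (b) the coupling is estimated from the position
#' difference and the intensity from the sum; the unmodelled tail of the
#' neighbouring component biases both.  Errors are paired per replicate.
#'
#' @param truth a doublet [ground_truth()] (single signal, model
#'   `"doublet"`, coupling at least 5 linewidths).
#' @param replicates number of replicates.
#' @param seed master seed.
#' @param options fitting options.
#' @return data frame with per-replicate absolute errors of `J` and `I`
#'   under both approaches.
#' @export
multiplet_vs_peaks_experiment <- function(truth, replicates = 20, seed = 1L,
                                          options = list()) {
  stopifnot(inherits(truth, "nmr_truth"))
  if (length(truth$signals) != 1 ||
      resolve_model(truth$signals[[1]]$model)$name != "doublet") {
    stop("'truth' must hold a single doublet signal")
  }
  tv <- truth$signals[[1]]$values
  if (tv$J < 2 * tv$lw) {
    stop("need J >= 2 lw: below that the two-singlet alternative cannot ",
         "resolve the components at all")
  }
  rep_seeds <- .with_seed(seed, sample.int(.Machine$integer.max %/% 2,
                                           replicates))
  reg <- region(truth$from, truth$to)
  out <- lapply(seq_len(replicates), function(r) {
    tr <- truth
    tr$seed <- rep_seeds[r]
    spec <- generate_spectrum(tr)
    starts <- .with_seed(tr$seed + 31L, perturb_values(tv))

    # (a) constrained doublet
    sig_a <- signal_instance("doublet", starts, reg, id = "doublet")
    fit_a <- fit_signals(fit_problem(spec, reg, list(sig_a), options))
    pa <- stats::setNames(fit_a$signals[[1]]$params$value,
                          fit_a$signals[[1]]$params$name)

    # (b) each component fitted independently as a singlet in its own
    # half-region (the neighbouring peak is not modelled)
    mk <- function(side, nm) {
      half <- if (side < 0) region(truth$from, starts$x0)
              else region(starts$x0, truth$to)
      sig <- signal_instance("singlet",
                             list(x0 = starts$x0 + side * starts$J / 2,
                                  I = starts$I / 2, lw = starts$lw,
                                  a = starts$a),
                             half, id = nm)
      fit_signals(fit_problem(spec, half, list(sig), options))
    }
    pb <- lapply(list(mk(-1, "left"), mk(1, "right")), function(f) {
      stats::setNames(f$signals[[1]]$params$value, f$signals[[1]]$params$name)
    })
    J_b <- abs(pb[[2]][["x0"]] - pb[[1]][["x0"]])
    I_b <- pb[[1]][["I"]] + pb[[2]][["I"]]

    data.frame(rep = r,
               J_multiplet = pa[["J"]], J_singlets = J_b,
               I_multiplet = pa[["I"]], I_singlets = I_b,
               J_err_multiplet = abs(pa[["J"]] - tv$J),
               J_err_singlets = abs(J_b - tv$J),
               I_err_multiplet = abs(pa[["I"]] - tv$I),
               I_err_singlets = abs(I_b - tv$I),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
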