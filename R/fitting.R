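# Bounded least-squares fitting of one region: cost assembly over the
# region's signals, L-BFGS-B minimization (optional seeded
# differential-evolution refinement first), and covariance-based
# parameter uncertainties.

#' Assemble a fit problem for one region
#'
#' Collects the experimental points inside the region and the resolved
#' signal instances into a flat bounded parameter vector.  Parameters
#' whose lower and upper bounds coincide are held fixed.
#'
#' @param spectrum an `nmr_spectrum`.
#' @param reg a [region()]; defaults to the first signal's region.
#' @param signals list of resolved `nmr_signal` objects (see
#'   [initialize_parameters()] / [signal_instance()]).
#' @param options list of fitting options: `global_refine` (default
#'   `FALSE`) runs a seeded differential-evolution search before the
#'   quasi-Newton descent; `seed` (default 1) seeds it; `maxit` (default
#'   1000) L-BFGS-B iteration cap; `factr` (default 10) L-BFGS-B relative
#'   reduction tolerance; `de_pop`, `de_maxgen` (defaults `15 * k` and
#'   200) differential-evolution population and generation caps.
#' @return object of class `nmr_problem`.
#' @export
fit_problem <- function(spectrum, reg = NULL, signals, options = list()) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  if (inherits(signals, "nmr_signal")) signals <- list(signals)
  for (s in signals) {
    if (is.null(s$params)) {
      stop("signal '", s$id, "' is not resolved; run initialize_parameters()")
    }
  }
  reg <- reg %||% signals[[1L]]$region
  idx <- .region_idx(spectrum, reg)

  free <- do.call(rbind, lapply(seq_along(signals), function(i) {
    p <- signals[[i]]$params
    data.frame(signal = i, name = p$name, init = p$init,
               lower = p$lower, upper = p$upper,
               free = p$lower < p$upper, stringsAsFactors = FALSE)
  }))

  opts <- utils::modifyList(
    list(global_refine = FALSE, seed = 1L, maxit = 1000L, factr = 100,
         lmm = 20L, de_pop = NULL, de_maxgen = 200L, de_f = 0.8,
         de_cr = 0.9),
    options
  )

  # index map into the full parameter vector, for the fast model curve
  layout <- lapply(seq_along(signals), function(i) {
    m <- get_model(signals[[i]]$model)
    rows <- which(free$signal == i)
    nm <- free$name[rows]
    list(offsets = m$offsets, weights = m$weights,
         i_x0 = rows[nm == "x0"], i_I = rows[nm == "I"],
         i_lw = rows[nm == "lw"], i_a = rows[nm == "a"],
         i_J = rows[match(m$j_names, nm)])
  })
  structure(
    list(x = spectrum$ppm[idx], y = spectrum$intensity[idx],
         region = reg, signals = signals, table = free, layout = layout,
         sf_mhz = spectrum$meta$sf_mhz %||% NA_real_, options = opts),
    class = "nmr_problem"
  )
}

# model curve from the full parameter vector, avoiding per-call
# data-frame construction (this is the optimizer's hot path)
.curve_full <- function(problem, full) {
  x <- problem$x
  y <- numeric(length(x))
  for (L in problem$layout) {
    pos <- full[L$i_x0] +
      (if (length(L$i_J)) as.vector(L$offsets %*% full[L$i_J]) else
         numeric(nrow(L$offsets)))
    I <- full[L$i_I]; lw <- full[L$i_lw]; a <- full[L$i_a]
    for (p in seq_along(pos)) {
      d2 <- ((x - pos[p]) / lw)^2
      y <- y + I * L$weights[p] * (a * exp(-d2 / 2) + (1 - a) / (1 + d2))
    }
  }
  y
}

# expand a free-parameter vector to per-signal named value lists
.signal_values <- function(problem, p_free) {
  tab <- problem$table
  full <- tab$init
  full[tab$free] <- p_free
  lapply(seq_along(problem$signals), function(i) {
    rows <- tab$signal == i
    stats::setNames(as.list(full[rows]), tab$name[rows])
  })
}

.model_curve <- function(problem, p_free) {
  full <- problem$table$init
  full[problem$table$free] <- p_free
  .curve_full(problem, full)
}

#' Sum-of-squared-residuals cost of a fit problem
#'
#' `c(p) = sum_i (a_i - y_i(p))^2` over the region grid, with `a` the
#' experimental intensities and `y(p)` the summed signal simulation.
#'
#' @param problem an `nmr_problem`.
#' @param p free-parameter vector (the rows of `problem$table` with
#'   `free == TRUE`, in order); must lie within bounds.
#' @return non-negative scalar.
#' @export
fit_cost <- function(problem, p) {
  tab <- problem$table[problem$table$free, , drop = FALSE]
  if (length(p) != nrow(tab)) {
    stop("expected ", nrow(tab), " free parameters, got ", length(p))
  }
  bad <- which(p < tab$lower - 1e-12 | p > tab$upper + 1e-12)
  if (length(bad)) {
    stop("parameter '", tab$name[bad[1L]], "' of signal ",
         tab$signal[bad[1L]], " violates its bounds")
  }
  sum((problem$y - .model_curve(problem, p))^2)
}

# run code under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# differential evolution (rand/1/bin) on the unit box, seeded by caller
.de_optimize <- function(fn, u0, pop, gens, F = 0.8, CR = 0.9) {
  k <- length(u0)
  P <- matrix(stats::runif(pop * k), nrow = pop)
  P[1L, ] <- u0
  costs <- apply(P, 1L, fn)
  nev <- pop
  for (g in seq_len(gens)) {
    for (i in seq_len(pop)) {
      r <- sample(seq_len(pop)[-i], 3L)
      mut <- P[r[1L], ] + F * (P[r[2L], ] - P[r[3L], ])
      mut <- pmin(pmax(mut, 0), 1)
      cross <- stats::runif(k) < CR
      cross[sample.int(k, 1L)] <- TRUE
      trial <- ifelse(cross, mut, P[i, ])
      ct <- fn(trial); nev <- nev + 1L
      if (ct < costs[i]) { P[i, ] <- trial; costs[i] <- ct }
    }
  }
  b <- which.min(costs)
  list(par = P[b, ], value = costs[b], n_eval = nev)
}

#' Fit a region
#'
#' Minimizes the sum-of-squares cost under the parameter bounds with
#' L-BFGS-B, starting from the initialization (optionally preceded by a
#' seeded differential-evolution refinement whose best point seeds the
#' descent).  The optimizer works on parameters rescaled to the unit
#' bound box for conditioning; a second L-BFGS-B polish run is performed
#' from the first optimum.  The reported cost never exceeds the cost at
#' initialization (the initial point is returned if no improvement is
#' found).
#'
#' @param problem an `nmr_problem`.
#' @return object of class `nmr_fit`: the signals with fitted `value`,
#'   `sd` and `at_bound` filled in, `cost`, `init_cost`, `converged`,
#'   `message`, `n_eval`, `residuals`, per-signal fitted curves
#'   (`curves`, one column per signal plus `total`), and a `derived`
#'   table (area, FWHM, couplings in Hz when the spectrometer frequency
#'   is known).
#' @export
fit_signals <- function(problem) {
  stopifnot(inherits(problem, "nmr_problem"))
  tab <- problem$table
  fr <- tab$free
  lo <- tab$lower[fr]; up <- tab$upper[fr]
  k <- sum(fr)
  scale <- up - lo
  to_u <- function(p) (p - lo) / scale
  to_p <- function(u) lo + u * scale

  ynorm <- sum(problem$y^2)
  if (ynorm == 0) ynorm <- 1
  fn_u <- function(u) {
    yv <- .model_curve(problem, to_p(u))
    v <- sum((problem$y - yv)^2) / ynorm
    if (!is.finite(v)) {
      stop("non-finite cost at parameter vector (",
           paste(format(to_p(u)), collapse = ", "), ")")
    }
    v
  }

  p0 <- tab$init[fr]
  u0 <- to_u(p0)
  c0 <- fn_u(u0) * ynorm
  n_eval <- 1L

  ustart <- u0
  if (k > 0L && isTRUE(problem$options$global_refine)) {
    pop <- problem$options$de_pop %||% (15L * k)
    de <- .with_seed(problem$options$seed,
                     .de_optimize(fn_u, u0, pop = pop,
                                  gens = problem$options$de_maxgen,
                                  F = problem$options$de_f,
                                  CR = problem$options$de_cr))
    n_eval <- n_eval + de$n_eval
    if (de$value * ynorm <= c0) ustart <- de$par
  }

  converged <- TRUE
  msg <- "converged"
  ubest <- ustart
  if (k > 0L) {
    ctrl <- list(maxit = problem$options$maxit, factr = problem$options$factr,
                 lmm = problem$options$lmm, ndeps = rep(1e-8, k))
    r1 <- stats::optim(ustart, fn_u, method = "L-BFGS-B",
                       lower = rep(0, k), upper = rep(1, k), control = ctrl)
    r2 <- stats::optim(r1$par, fn_u, method = "L-BFGS-B",
                       lower = rep(0, k), upper = rep(1, k), control = ctrl)
    n_eval <- n_eval + (r1$counts[1L] + r2$counts[1L]) * (k + 1L)
    best <- if (r2$value <= r1$value) r2 else r1
    # the polish run making no further relative progress means we are at a
    # stationary point even when the line search aborts on FD-gradient noise
    stationary <- abs(r1$value - r2$value) <= 1e-9 * max(r1$value, 1e-300)
    converged <- best$convergence == 0L || stationary
    msg <- if (best$convergence == 0L) "converged"
      else if (converged) "converged (line search saturated at stationary point)"
      else paste0("L-BFGS-B did not converge: ", best$message %||% best$convergence)
    ubest <- best$par
  }

  p_hat <- to_p(ubest)
  c_hat <- sum((problem$y - .model_curve(problem, p_hat))^2)
  if (c_hat > c0) { # never report a point worse than the initialization
    p_hat <- p0
    c_hat <- c0
    msg <- paste(msg, "(no improvement over initialization)")
  }

  resid <- problem$y - .model_curve(problem, p_hat)
  unc <- .fit_uncertainty(problem, p_hat, c_hat)

  # write values back into the signal parameter tables
  full <- tab$init
  full[fr] <- p_hat
  sd_full <- rep(NA_real_, nrow(tab))
  sd_full[fr] <- unc$sd
  atb_full <- rep(FALSE, nrow(tab))
  atb_full[fr] <- unc$at_bound
  signals <- problem$signals
  curves <- matrix(0, nrow = length(problem$x), ncol = length(signals),
                   dimnames = list(NULL, vapply(signals, `[[`, "", "id")))
  vals <- .signal_values(problem, p_hat)
  derived <- NULL
  for (i in seq_along(signals)) {
    rows <- which(tab$signal == i)
    signals[[i]]$params$value <- full[rows]
    signals[[i]]$params$sd <- sd_full[rows]
    signals[[i]]$params$at_bound <- atb_full[rows]
    curves[, i] <- simulate_signal(signals[[i]]$model, vals[[i]], problem$x)
    v <- vals[[i]]
    area_k <- v$lw * (v$a * sqrt(2 * pi) + (1 - v$a) * pi)
    iI <- rows[tab$name[rows] == "I"]
    mod <- get_model(signals[[i]]$model)
    drow <- data.frame(signal = signals[[i]]$id, model = signals[[i]]$model,
                       area = v$I * area_k,
                       area_sd = sd_full[iI] * area_k,
                       fwhm = peak_fwhm(v$lw, v$a),
                       stringsAsFactors = FALSE)
    for (jn in mod$j_names) {
      drow[[paste0(jn, "_hz")]] <-
        if (is.finite(problem$sf_mhz)) v[[jn]] * problem$sf_mhz else NA_real_
    }
    derived <- .rbind_fill(derived, drow)
  }

  structure(
    list(signals = signals, cost = c_hat, init_cost = c0,
         converged = converged, message = msg, n_eval = n_eval,
         singular = unc$singular, s2 = unc$s2,
         residuals = resid, x = problem$x, y = problem$y,
         fitted = rowSums(curves), curves = curves, derived = derived,
         region = problem$region, sf_mhz = problem$sf_mhz),
    class = "nmr_fit"
  )
}

# rbind data frames with differing columns, filling with NA, keeping order
.rbind_fill <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in setdiff(names(b), names(a))) a[[nm]] <- NA
  for (nm in setdiff(names(a), names(b))) b[[nm]] <- NA
  rbind(a, b[names(a)])
}

# forward-finite-difference residual Jacobian and covariance-based sd
.fit_uncertainty <- function(problem, p_hat, cost) {
  tab <- problem$table[problem$table$free, , drop = FALSE]
  k <- nrow(tab)
  n <- length(problem$y)
  at_bound <- k > 0 &
    (p_hat - tab$lower <= 1e-8 * (tab$upper - tab$lower) |
     tab$upper - p_hat <= 1e-8 * (tab$upper - tab$lower))
  if (k == 0L) {
    return(list(sd = numeric(0), at_bound = logical(0),
                singular = FALSE, s2 = NA_real_))
  }
  if (n <= k) {
    return(list(sd = rep(NA_real_, k), at_bound = at_bound,
                singular = TRUE, s2 = NA_real_))
  }
  y0 <- .model_curve(problem, p_hat)
  J <- matrix(0, nrow = n, ncol = k)
  for (j in seq_len(k)) {
    h <- 1e-6 * max(abs(p_hat[j]), tab$upper[j] - tab$lower[j])
    pj <- p_hat
    if (p_hat[j] + h > tab$upper[j]) h <- -h # step backward at the bound
    pj[j] <- p_hat[j] + h
    J[, j] <- (.model_curve(problem, pj) - y0) / h
  }
  s2 <- cost / (n - k)
  jtj <- crossprod(J)
  cov <- tryCatch(s2 * solve(jtj), error = function(e) NULL)
  singular <- is.null(cov)
  if (singular) { # pseudo-inverse fallback
    sv <- svd(jtj)
    pos <- sv$d > max(sv$d) * 1e-12
    inv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    cov <- s2 * inv
  }
  sd <- sqrt(pmax(diag(cov), 0))
  list(sd = sd, at_bound = at_bound, singular = singular, s2 = s2)
}

#' Standard deviations of fitted parameters
#'
#' Recomputes the covariance-based uncertainties of a fit: the residual
#' Jacobian at the optimum (forward finite differences, relative step
#' `1e-6`, stepping away from active bounds), the residual variance
#' `s^2 = cost / (n - k)`, and `sd = sqrt(diag(s^2 (J'J)^-1))`.
#' Parameters at an active bound are flagged: their curvature-based sd is
#' unreliable.
#'
#' @param fit an `nmr_fit`.
#' @param problem the `nmr_problem` it came from.
#' @return data frame with columns `signal`, `name`, `value`, `sd`,
#'   `at_bound`.
#' @export
fit_uncertainty <- function(fit, problem) {
  tab <- problem$table
  fr <- tab$free
  p_hat <- unlist(lapply(seq_along(fit$signals), function(i) {
    fit$signals[[i]]$params$value
  }))[fr]
  unc <- .fit_uncertainty(problem, p_hat, fit$cost)
  out <- data.frame(signal = tab$signal[fr], name = tab$name[fr],
                    value = p_hat, sd = unc$sd, at_bound = unc$at_bound,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.nmr_fit <- function(x, ...) {
  cat("<nmr_fit> cost ", format(x$cost), " (", x$message, "), ",
      length(x$signals), " signal(s)\n", sep = "")
  for (s in x$signals) {
    cat("  ", s$id, " [", s$model, "]\n", sep = "")
    p <- s$params
    cat(paste0("    ", format(p$name, width = 4), " = ",
               formatC(p$value, digits = 6, format = "g"),
               " +/- ", formatC(p$sd, digits = 3, format = "g"),
               ifelse(p$at_bound, " (at bound)", ""), "\n"), sep = "")
  }
  invisible(x)
}
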