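# Shared fixture builders: everything is generated in code at test time.

# single doublet world used for cost/fit/comparison tests
doublet_truth <- function(J = 0.02, lw = 0.004, snr = Inf, seed = 1L,
                          n = 1024L) {
  tr <- ground_truth(
    list(list(id = "d", model = "doublet",
              values = list(x0 = 2.0, I = 1, lw = lw, a = 0.5, J = J))),
    from = 1.8, to = 2.2, n = n, seed = seed
  )
  if (is.finite(snr)) {
    tr$sigma <- max(multipletfit:::.truth_clean(tr)) / snr
  }
  tr
}

singlet_truth <- function(snr = Inf, seed = 1L, n = 1024L) {
  tr <- ground_truth(
    list(list(id = "s", model = "singlet",
              values = list(x0 = 2.0, I = 5, lw = 0.004, a = 0.5))),
    from = 1.8, to = 2.2, n = n, seed = seed
  )
  if (is.finite(snr)) {
    tr$sigma <- max(multipletfit:::.truth_clean(tr)) / snr
  }
  tr
}

# resolved signal instances at the truth values (unperturbed starts)
truth_signals <- function(truth, reg = region(truth$from, truth$to)) {
  lapply(seq_along(truth$signals), function(i) {
    s <- truth$signals[[i]]
    signal_instance(s$model, s$values, reg, id = s$id %||% paste0("sig", i))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rel_errors <- function(fit, truth) {
  unlist(lapply(seq_along(truth$signals), function(i) {
    tv <- unlist(truth$signals[[i]]$values)
    p <- fit$signals[[i]]$params
    (p$value - unname(tv[p$name])) / unname(tv[p$name])
  }))
}
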