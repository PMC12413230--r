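test_that("pick_peaks finds multiplet components on noiseless spectra", {
  tr <- doublet_truth(J = 0.08) # J = 20 lw, well resolved
  sp <- generate_spectrum(tr)
  reg <- region(1.8, 2.2)
  pk <- pick_peaks(sp, reg, threshold = 0.01)
  expect_equal(nrow(pk), 2)
  step <- diff(sp$ppm[1:2])
  expect_lt(max(abs(pk$position - c(1.96, 2.04))), step)

  # flat zero spectrum: nothing to find
  flat <- spectrum1d(sp$ppm, numeric(length(sp$ppm)))
  expect_equal(nrow(pick_peaks(flat, reg, threshold = 0)), 0)

  # triplet: centre apex ~ 2x the outer apexes
  tr3 <- ground_truth(list(list(model = "triplet",
                                values = list(x0 = 2.0, I = 1, lw = 0.004,
                                              a = 0.5, J = 0.06))),
                      from = 1.8, to = 2.2, n = 2048)
  pk3 <- pick_peaks(generate_spectrum(tr3), reg, threshold = 0.01)
  expect_equal(nrow(pk3), 3)
  expect_equal(pk3$intensity[2] / pk3$intensity[1], 2, tolerance = 0.05)
})

test_that("plateaus yield a single centred peak and regions are validated", {
  ppm <- seq(0, 1, length.out = 101)
  y <- numeric(101); y[48:52] <- 5 # 5-point plateau centred at index 50
  sp <- spectrum1d(ppm, y)
  pk <- pick_peaks(sp, region(0, 1), threshold = 1)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$position, ppm[50])

  expect_error(pick_peaks(sp, region(-1, 0.5), threshold = 1), "outside")
  expect_error(region(0.7, 0.2), "ppm_min < ppm_max")
})

test_that("auto threshold suppresses noise-level maxima", {
  tr <- doublet_truth(J = 0.08, snr = 60, seed = 9)
  sp <- generate_spectrum(tr)
  pk <- pick_peaks(sp, region(1.8, 2.2)) # k = 5 default
  expect_equal(nrow(pk), 2) # only the two real components survive
})

test_that("group_signal enforces the peak count and permits shared peaks", {
  pk2 <- data.frame(position = c(1.95, 2.05), intensity = c(4.9, 5.1),
                    source = "auto")
  sig <- group_signal(pk2, "doublet")
  expect_s3_class(sig, "nmr_signal")
  expect_null(sig$params)
  expect_identical(sig$suggested, "doublet")

  expect_error(group_signal(pk2, "triplet"), "expects 3 peak")

  # the same peaks may be grouped into two different signals (overlap)
  sig2 <- group_signal(pk2, "doublet", id = "other")
  expect_s3_class(sig2, "nmr_signal")
  expect_false(identical(sig$id, sig2$id))
})

test_that("initialization derives x0, I and J from the peak list", {
  tr <- doublet_truth(J = 0.1)
  sp <- generate_spectrum(tr)
  pk <- data.frame(position = c(1.95, 2.05), intensity = c(4.9, 5.1),
                   source = "auto")
  sig <- initialize_parameters(group_signal(pk, "doublet",
                                            reg = region(1.8, 2.2)), sp)
  p <- stats::setNames(sig$params$init, sig$params$name)
  expect_equal(p[["x0"]], 2.00)
  expect_equal(p[["J"]], 0.10)
  expect_equal(p[["I"]], 10, tolerance = 1e-12)

  # doublet of doublets: exact inversion of the offset formula
  pkdd <- data.frame(position = c(-0.25, -0.15, 0.15, 0.25),
                     intensity = rep(1, 4), source = "auto")
  spdd <- spectrum1d(seq(-0.5, 0.5, length.out = 512),
                     simulate_signal("doublet_of_doublets",
                                     list(x0 = 0, I = 4, lw = 0.01, a = 0.5,
                                          J1 = 0.4, J2 = 0.1),
                                     seq(-0.5, 0.5, length.out = 512)))
  sdd <- initialize_parameters(group_signal(pkdd, "doublet_of_doublets",
                                            reg = region(-0.5, 0.5)), spdd)
  pdd <- stats::setNames(sdd$params$init, sdd$params$name)
  expect_equal(pdd[["J1"]], 0.4)
  expect_equal(pdd[["J2"]], 0.1)
  expect_equal(pdd[["x0"]], 0)

  # singlet: straight from the peak
  pk1 <- data.frame(position = 3.2, intensity = 7, source = "manual")
  sp1 <- spectrum1d(seq(2.7, 3.7, length.out = 512),
                    pseudo_voigt(seq(2.7, 3.7, length.out = 512), 3.2, 7,
                                 0.01, 0.5))
  s1 <- initialize_parameters(group_signal(pk1, "singlet",
                                           reg = region(2.7, 3.7)), sp1)
  p1 <- stats::setNames(s1$params$init, s1$params$name)
  expect_equal(p1[["x0"]], 3.2)
  expect_equal(p1[["I"]], 7)

  # coincident peaks cannot seed a genuine multiplet
  pkc <- data.frame(position = c(2, 2), intensity = c(1, 1), source = "auto")
  expect_error(initialize_parameters(group_signal(pkc, "doublet",
                                                  reg = region(1.8, 2.2)), sp),
               "lower-multiplicity")
})

test_that("picking + initialization recover every built-in pattern", {
  lw <- 0.002
  reg <- region(1.0, 3.0)
  x <- seq(1.0, 3.0, length.out = 2^13)
  step <- diff(x[1:2])
  for (nm in c("singlet", "doublet", "triplet", "quadruplet",
               "doublet_of_doublets")) {
    m <- get_model(nm)
    J <- stats::setNames(rep(25 * lw, length(m$j_names)), m$j_names)
    if (length(J) > 1) J[1] <- 80 * lw
    v <- c(list(x0 = 2.0, I = 2, lw = lw, a = 0.5), as.list(J))
    sp <- spectrum1d(x, simulate_signal(m, v, x))
    pk <- pick_peaks(sp, reg, threshold = max(sp$intensity) / 50)
    expect_equal(nrow(pk), m$n_peaks, info = nm)
    sig <- initialize_parameters(group_signal(pk, nm, reg = reg), sp)
    p <- stats::setNames(sig$params$init, sig$params$name)
    expect_lt(abs(p[["x0"]] - 2.0), step, label = paste(nm, "x0"))
    for (jn in m$j_names) {
      expect_lt(abs(p[[jn]] - J[[jn]]), 2 * step, label = paste(nm, jn))
    }
    expect_equal(p[["I"]], 2, tolerance = 0.05)
    # bounds bracket inits
    expect_true(all(sig$params$lower <= sig$params$init &
                    sig$params$init <= sig$params$upper), info = nm)
    # idempotence
    sig2 <- initialize_parameters(sig, sp)
    expect_identical(sig2$params, sig$params)
  }
})
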