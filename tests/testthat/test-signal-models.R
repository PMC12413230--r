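test_that("pseudo_voigt matches its closed form at anchor points", {
  # apex equals h for any mixing fraction
  for (a in c(0, 0.25, 0.5, 1)) {
    expect_equal(pseudo_voigt(2.0, x0 = 2.0, h = 10, lw = 0.01, a = a), 10)
  }
  # Lorentzian half maximum at one linewidth from the centre
  expect_equal(pseudo_voigt(2.01, x0 = 2.0, h = 1, lw = 0.01, a = 0), 0.5)
  # Gaussian value exp(-1/2) at one linewidth (lw acts as sigma)
  expect_equal(pseudo_voigt(2.01, x0 = 2.0, h = 1, lw = 0.01, a = 1),
               exp(-0.5))
  # even function of (x - x0)
  x <- seq(-0.1, 0.1, length.out = 101)
  y <- pseudo_voigt(2.0 + x, x0 = 2.0, h = 3, lw = 0.007, a = 0.3)
  expect_equal(y, rev(y))
})

test_that("pseudo_voigt rejects invalid shape parameters", {
  expect_error(pseudo_voigt(1, 0, 1, lw = 0, a = 0.5), "lw")
  expect_error(pseudo_voigt(1, 0, 1, lw = -0.1, a = 0.5), "lw")
  expect_error(pseudo_voigt(1, 0, 1, lw = 0.1, a = -0.1), "\\[0, 1\\]")
  expect_error(pseudo_voigt(1, 0, 1, lw = 0.1, a = 1.2), "\\[0, 1\\]")
})

test_that("expand_multiplet places component peaks correctly", {
  # doublet at xs +/- J/2
  d <- expand_multiplet("doublet", x0 = 2.0, J = c(J = 0.1))
  expect_equal(d$position, c(1.95, 2.05))
  expect_equal(d$weight, c(0.5, 0.5))

  # doublet of doublets: four sign combinations, equal weights
  dd <- expand_multiplet("doublet_of_doublets", x0 = 0,
                         J = c(J1 = 0.4, J2 = 0.1))
  expect_equal(dd$position, c(-0.25, -0.15, 0.15, 0.25))
  expect_equal(dd$weight, rep(0.25, 4))

  # degenerate coupling: all peaks collapse onto xs, weights still sum to 1
  for (m in c("doublet", "triplet", "quadruplet")) {
    e <- expand_multiplet(m, x0 = 1.5, J = c(J = 0))
    expect_true(all(e$position == 1.5))
    expect_equal(sum(e$weight), 1)
  }
  dd0 <- expand_multiplet("doublet_of_doublets", 1.5, c(J1 = 0, J2 = 0))
  expect_true(all(dd0$position == 1.5))
  expect_equal(sum(dd0$weight), 1)

  # triplet/quadruplet offsets and binomial weights
  t3 <- expand_multiplet("triplet", 2.0, c(J = 0.04))
  expect_equal(t3$position, c(1.96, 2.0, 2.04))
  expect_equal(t3$weight, c(0.25, 0.5, 0.25))
  q4 <- expand_multiplet("quadruplet", 0, c(J = 0.1))
  expect_equal(q4$position, c(-0.15, -0.05, 0.05, 0.15))
  expect_equal(q4$weight, c(1, 3, 3, 1) / 8)

  expect_error(expand_multiplet("doublet", 2.0, c(Jx = 0.1)), "missing")
  expect_error(expand_multiplet("doublet", 2.0, c(J = -0.1)), ">= 0")
})

test_that("simulate_signal distributes intensity over component peaks", {
  x <- seq(1.0, 5.0, length.out = 8001)
  # singlet: apex equals I
  y <- simulate_signal("singlet", list(x0 = 3.2, I = 5, lw = 0.004, a = 0.5), x)
  expect_equal(max(y), 5, tolerance = 1e-6)

  # doublet with J >> lw: each component apex is I/2 up to the twin's tail
  lw <- 0.004; J <- 40 * lw
  v <- list(x0 = 3.0, I = 2, lw = lw, a = 0.5)
  v$J <- J
  yc <- simulate_signal("doublet", v, 3.0 + J / 2)
  tail_bound <- 1 * (0.5 * exp(-(J / lw)^2 / 2) + 0.5 / (1 + (J / lw)^2))
  expect_lt(abs(yc - 1.0), tail_bound + 1e-12)
  expect_gt(yc, 1.0) # the tail only adds

  # triplet: centre apex ~ 2x outer apex for J >> lw
  vt <- list(x0 = 3.0, I = 1, lw = lw, a = 0.5, J = 30 * lw)
  apexes <- simulate_signal("triplet", vt, 3.0 + c(-30 * lw, 0, 30 * lw))
  expect_equal(apexes[2] / apexes[1], 2, tolerance = 0.01)
  expect_equal(apexes[1], apexes[3])

  expect_error(
    simulate_signal("doublet", list(x0 = 1, I = 1, lw = 0.01, a = 0.5), x),
    "missing parameter"
  )
})

test_that("simulate_spectrum is an exact elementwise sum of signals", {
  x <- seq(0, 4, length.out = 4001)
  expect_equal(simulate_spectrum(list(), x), numeric(length(x)))
  expect_error(simulate_spectrum(list(), numeric(0)), "non-empty")

  s1 <- list(model = "doublet",
             values = list(x0 = 1.0, I = 1, lw = 0.004, a = 0.2, J = 0.05))
  s2 <- list(model = "doublet",
             values = list(x0 = 3.0, I = 2, lw = 0.006, a = 0.8, J = 0.08))
  y1 <- simulate_signal(s1$model, s1$values, x)
  y2 <- simulate_signal(s2$model, s2$values, x)
  expect_identical(simulate_spectrum(list(s1), x), y1)
  expect_equal(simulate_spectrum(list(s1, s2), x), y1 + y2)
  # order invariance
  expect_equal(simulate_spectrum(list(s2, s1), x),
               simulate_spectrum(list(s1, s2), x))
})

test_that("suggest_models returns exactly the registered models per peak count", {
  expect_identical(suggest_models(1), "singlet")
  expect_identical(suggest_models(2), "doublet")
  expect_identical(suggest_models(3), "triplet")
  expect_identical(suggest_models(4), c("doublet_of_doublets", "quadruplet"))
  expect_identical(suggest_models(5), character(0))
  expect_error(suggest_models(0), ">= 1")
})

test_that("custom models can be registered, with invariants enforced", {
  unregister_model("doublet_of_triplets")
  dt <- first_order_multiplet("doublet_of_triplets", c(2L, 3L))
  expect_equal(sort(dt$weights), sort(rep(c(1, 2, 1, 1, 2, 1) / 8, 1)))
  register_model(dt)
  expect_true("doublet_of_triplets" %in% suggest_models(6))

  # duplicate names are rejected
  expect_error(register_model(first_order_multiplet("doublet", 2L)),
               "already registered")

  # asymmetric offsets violate the first-order pattern invariant
  expect_error(
    signal_model("bad", offsets = matrix(c(-0.5, 0.7), ncol = 1),
                 weights = c(0.5, 0.5), j_names = "J"),
    "symmetric"
  )
  # asymmetric weights too
  expect_error(
    signal_model("bad", offsets = matrix(c(-0.5, 0.5), ncol = 1),
                 weights = c(0.3, 0.7), j_names = "J"),
    "mirror"
  )
  unregister_model("doublet_of_triplets")
})

test_that("declarative model files load and register", {
  unregister_model("doublet_of_triplets")
  path <- system.file("extdata", "doublet_of_triplets.json",
                      package = "multipletfit")
  expect_true(nzchar(path))
  m <- read_model_file(path)
  expect_s3_class(m, "nmr_model")
  expect_equal(m$n_peaks, 6)
  expect_true("doublet_of_triplets" %in% suggest_models(6))
  # its pattern: doublet splitting J1, triplet splitting J2
  e <- expand_multiplet(m, 0, c(J1 = 0.4, J2 = 0.1))
  expect_equal(e$position,
               c(-0.3, -0.2, -0.1, 0.1, 0.2, 0.3))
  expect_equal(e$weight, c(1, 2, 1, 1, 2, 1) / 8)
  unregister_model("doublet_of_triplets")
})

test_that("apex identity and weight normalization hold for all built-ins", {
  lw <- 0.002
  for (nm in list_models()) {
    m <- get_model(nm)
    expect_equal(sum(m$weights), 1, info = nm)
    J <- stats::setNames(rep(50 * lw, length(m$j_names)), m$j_names)
    if (length(J) > 1) J[1] <- 150 * lw # keep every pairwise gap > 20 lw
    v <- c(list(x0 = 2.0, I = 3, lw = lw, a = 0.4), as.list(J))
    pk <- expand_multiplet(m, 2.0, J)
    expect_gt(min(diff(c(-Inf, pk$position))), 0) # sorted
    if (m$n_peaks > 1) expect_gt(min(diff(pk$position)), 20 * lw)
    x <- seq(1.5, 2.5, length.out = 40001)
    y <- simulate_signal(m, v, x)
    expect_equal(max(y), 3 * max(m$weights), tolerance = 1e-3, info = nm)
  }
})

test_that("integral of a signal is proportional to I, independent of J and xs", {
  set.seed(99)
  lw <- 0.003
  a <- 0.35
  konst <- lw * (a * sqrt(2 * pi) + (1 - a) * pi) # analytic area for I = 1
  for (i in 1:10) {
    m <- get_model(sample(list_models(), 1))
    I <- runif(1, 0.5, 5)
    xs <- runif(1, -1, 1)
    J <- stats::setNames(runif(length(m$j_names), 5 * lw, 20 * lw), m$j_names)
    v <- c(list(x0 = xs, I = I, lw = lw, a = a), as.list(J))
    x <- seq(xs - 200 * lw, xs + 200 * lw, length.out = 20001)
    y <- simulate_signal(m, v, x)
    area <- sum((y[-1] + y[-length(y)]) / 2 * diff(x))
    # Lorentzian tails beyond 200 lw hold ~0.2% of the area
    expect_equal(area / I, konst, tolerance = 0.005, info = m$name)
  }
})

test_that("a = 1 and a = 0 reduce to pure Gaussian / Lorentzian sums", {
  x <- seq(1.5, 2.5, length.out = 2001)
  xs <- 2.0; I <- 2; lw <- 0.01; J <- 0.08
  gauss <- function(x, x0, h) h * exp(-(x - x0)^2 / (2 * lw^2))
  lorentz <- function(x, x0, h) h / (1 + ((x - x0) / lw)^2)
  vg <- list(x0 = xs, I = I, lw = lw, a = 1, J = J)
  vl <- list(x0 = xs, I = I, lw = lw, a = 0, J = J)
  ref_g <- gauss(x, xs - J / 2, 1) + gauss(x, xs + J / 2, 1)
  ref_l <- lorentz(x, xs - J / 2, 1) + lorentz(x, xs + J / 2, 1)
  expect_equal(simulate_signal("doublet", vg, x), ref_g)
  expect_equal(simulate_signal("doublet", vl, x), ref_l)
})

test_that("every built-in signal is symmetric about its chemical shift", {
  lw <- 0.004
  d <- seq(0, 0.2, length.out = 501)
  for (nm in list_models()) {
    m <- get_model(nm)
    J <- stats::setNames(c(0.06, 0.025)[seq_along(m$j_names)], m$j_names)
    v <- c(list(x0 = 2.0, I = 1, lw = lw, a = 0.6), as.list(J))
    expect_equal(simulate_signal(m, v, 2.0 + d),
                 simulate_signal(m, v, 2.0 - d), info = nm)
  }
})

test_that("peak_fwhm interpolates between Lorentzian and Gaussian widths", {
  lw <- 0.01
  expect_equal(peak_fwhm(lw, 0), 2 * lw, tolerance = 1e-9)
  expect_equal(peak_fwhm(lw, 1), 2 * sqrt(2 * log(2)) * lw, tolerance = 1e-9)
  mid <- peak_fwhm(lw, 0.5)
  expect_gt(mid, 2 * lw)
  expect_lt(mid, 2 * sqrt(2 * log(2)) * lw)
})
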