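test_that("text spectra round-trip losslessly at double precision", {
  tr <- singlet_truth(snr = 100, seed = 4)
  sp <- generate_spectrum(tr)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_text_spectrum(sp, f)
  sp2 <- read_text_spectrum(f)
  expect_identical(sp2$ppm, sp$ppm)
  expect_identical(sp2$intensity, sp$intensity)
  # write -> read -> write is byte-stable
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_text_spectrum(sp2, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("multi-column text input yields a series; dialects are detected", {
  ppm <- seq(0, 10, length.out = 64)
  mat <- rbind(sin(ppm), cos(ppm), sqrt(ppm))
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ppm,r1,r2,r3",
               apply(cbind(ppm, t(mat)), 1,
                     function(r) paste(format(r, digits = 12), collapse = ","))),
             f)
  s <- read_text_spectrum(f)
  expect_s3_class(s, "nmr_series")
  expect_equal(nrow(s$intensities), 3)
  expect_equal(s$intensities[2, ], cos(ppm), tolerance = 1e-10)

  # semicolon dialect, no header
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(paste(ppm, sin(ppm), sep = ";"), f2)
  s2 <- read_text_spectrum(f2)
  expect_s3_class(s2, "nmr_spectrum")
  expect_equal(s2$intensity, sin(ppm), tolerance = 1e-12)
})

test_that("descending-ppm text input is normalized to ascending", {
  ppm <- seq(10, 0, length.out = 32) # descending, Bruker-style
  y <- seq_len(32)
  f <- withr::local_tempfile()
  writeLines(paste(ppm, y, sep = "\t"), f)
  s <- read_text_spectrum(f)
  expect_true(all(diff(s$ppm) > 0))
  expect_equal(s$intensity, rev(y))
})

test_that("malformed text input produces located format errors", {
  f <- withr::local_tempfile()
  writeLines(c("1.0\t2.0", "1.1\tbroken", "1.2\t4.0"), f)
  expect_error(read_text_spectrum(f), "row 2, column 2")
  f2 <- withr::local_tempfile()
  writeLines(c("1.0", "2.0"), f2)
  expect_error(read_text_spectrum(f2), "at least 2 columns")
})

test_that("Bruker fixtures round-trip axis metadata exactly", {
  ppm <- seq(0, 10, length.out = 2048) # stored descending on disk
  y <- pseudo_voigt(ppm, 5, 1e6, 0.05, 0.5)
  sp <- spectrum1d(ppm, y, sf_mhz = 600.13)
  d <- withr::local_tempdir()
  write_bruker(sp, d, expno = 3, procno = 1)
  got <- read_bruker(d, expno = 3, procno = 1)
  expect_equal(length(got$ppm), 2048)
  expect_equal(min(got$ppm), 0, tolerance = 1e-9)
  expect_equal(max(got$ppm), 10, tolerance = 1e-9)
  expect_equal(got$meta$sf_mhz, 600.13)
  # int32 quantization: relative error ~2^-28 of the max
  expect_equal(got$intensity, y, tolerance = 1e-6)
})

test_that("pseudo-2D Bruker data returns labelled rows in order", {
  ppm <- seq(1, 3, length.out = 512)
  mat <- t(sapply(1:8, function(r) pseudo_voigt(ppm, 2, r * 10, 0.02, 0.3)))
  ser <- spectrum_series(ppm, mat, sf_mhz = 500)
  d <- withr::local_tempdir()
  write_bruker(ser, d)
  got <- read_bruker(d)
  expect_s3_class(got, "nmr_series")
  expect_equal(nrow(got$intensities), 8)
  expect_equal(got$labels, 1:8)
  for (r in c(1, 5, 8)) {
    expect_equal(got$intensities[r, ], mat[r, ], tolerance = 1e-5)
  }
})

test_that("truncated or incomplete Bruker files give format errors", {
  ppm <- seq(1, 3, length.out = 256)
  sp <- spectrum1d(ppm, pseudo_voigt(ppm, 2, 100, 0.02, 0.5), sf_mhz = 500)
  d <- withr::local_tempdir()
  pdir <- write_bruker(sp, d)
  # truncate the data file
  f1r <- file.path(pdir, "1r")
  raw <- readBin(f1r, "raw", file.size(f1r))
  writeBin(raw[seq_len(100)], f1r)
  expect_error(read_bruker(d), "truncated")
  # missing parameter file
  file.remove(file.path(pdir, "procs"))
  expect_error(read_bruker(d), "procs")
})

fit_one_singlet_session <- function() {
  tr <- singlet_truth(snr = 200, seed = 12)
  sp <- generate_spectrum(tr)
  reg <- region(1.8, 2.2)
  sig <- truth_signals(tr, reg)
  fit <- fit_signals(fit_problem(sp, reg, sig))
  add_fit(new_session(config = list(note = "io test")), fit, "spec_1")
}

test_that("export writes the parameter and curve schema", {
  s <- fit_one_singlet_session()
  d <- withr::local_tempdir()
  paths <- export_results(s, d)
  params <- read.csv(paths[["params"]])
  expect_setequal(params$parameter, c("x0", "I", "lw", "a", "area", "fwhm"))
  expect_true(all(c("value", "sd", "ci_lower", "ci_upper", "at_bound",
                    "converged") %in% names(params)))
  crv <- read.csv(paths[["curves"]])
  # fitted total equals the sum of per-signal columns at every grid point
  sig_cols <- grep("^signal_", names(crv), value = TRUE)
  expect_equal(crv$fitted, rowSums(crv[, sig_cols, drop = FALSE]),
               tolerance = 1e-12)
  expect_true(file.exists(paths[["log"]]))
})

test_that("session archives reload to byte-identical exports", {
  s <- fit_one_singlet_session()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  arch <- file.path(withr::local_tempdir(), "session.json")
  save_session(s, arch)
  p1 <- export_results(s, d1)
  s2 <- load_session(arch)
  expect_gt(length(s2$log), length(s$log)) # load appended a log entry
  p2 <- export_results(s2, d2)
  for (k in c("params", "curves")) {
    expect_identical(readBin(p1[[k]], "raw", file.size(p1[[k]])),
                     readBin(p2[[k]], "raw", file.size(p2[[k]])),
                     info = k)
  }
})

test_that("future schema versions and corrupt archives are rejected", {
  s <- fit_one_singlet_session()
  arch <- file.path(withr::local_tempdir(), "session.json")
  save_session(s, arch)
  obj <- jsonlite::fromJSON(arch)
  obj$schema_version <- 99L
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), arch)
  expect_error(load_session(arch), "schema version 99")
  writeLines("not json at all {", arch)
  expect_error(load_session(arch), "not a readable|not a multipletfit")
})
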