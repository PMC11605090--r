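# Spectrum I/O, scan accumulation, background subtraction, noise rules.

test_that("MSP write/read round-trips spectra losslessly", {
  sp <- toy_spectrum(c(184.0733, 489.3214, 760.5851), c(120, 45, 800),
                     pre = 760.5851)
  sp$metadata$Name <- "PC 16:0/18:1"
  path <- tempfile(fileext = ".msp")
  write_msp(sp, path)
  back <- read_msp(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$peaks$mz, sp$peaks$mz, tolerance = 1e-6)
  expect_equal(back[[1]]$peaks$intensity, sp$peaks$intensity, tolerance = 1e-6)
  expect_equal(back[[1]]$precursor_mz, 760.5851, tolerance = 1e-6)
  expect_identical(back[[1]]$metadata$Name, "PC 16:0/18:1")
})

test_that("malformed MSP blocks raise errors with a line reference", {
  path <- tempfile(fileext = ".msp")
  writeLines(c("Name: broken", "Num Peaks: 3",
               "100.1 10", "200.2 20"), path)
  expect_error(read_msp(path), "line")
})

test_that("MGF blocks parse with precursor and peaks", {
  path <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=spec1", "PEPMASS=760.5851",
               "184.0733 120", "489.3214 45", "END IONS"), path)
  sp <- read_mgf(path)
  expect_length(sp, 1)
  expect_equal(sp[[1]]$precursor_mz, 760.5851)
  expect_identical(nrow(sp[[1]]$peaks), 2L)
  writeLines(c("BEGIN IONS", "184.0733 120"), path)
  expect_error(read_mgf(path), "unterminated")
})

test_that("mzML import returns the centroided MS2 scans", {
  path <- tempfile(fileext = ".mzML")
  write_test_mzml(path, list(
    list(pre = 500.1, mz = c(150.1, 200.2, 300.3), intensity = c(10, 20, 30)),
    list(pre = 600.2, mz = c(180.5, 250.7), intensity = c(5, 15))))
  sp <- read_mzml(path)
  expect_length(sp, 2)
  expect_equal(sp[[1]]$precursor_mz, 500.1, tolerance = 1e-6)
  expect_equal(sp[[2]]$peaks$mz, c(180.5, 250.7), tolerance = 1e-6)
})

test_that("scan accumulation averages intensities per 0.05-Da bin", {
  s1 <- toy_spectrum(300.01, 10)
  s2 <- toy_spectrum(300.02, 30)
  acc <- accumulate_scans(list(s1, s2))
  expect_identical(nrow(acc$peaks), 1L)
  expect_equal(acc$peaks$intensity, 20)
  # single scan is unchanged up to binning
  one <- accumulate_scans(list(s1))
  expect_equal(one$peaks$intensity, 10)
  # peaks 0.06 Da apart land in distinct bins
  twobin <- accumulate_scans(list(toy_spectrum(c(300.01, 300.07), c(5, 7))))
  expect_identical(nrow(twobin$peaks), 2L)
  expect_error(accumulate_scans(list()), "no scans")
})

test_that("background subtraction clamps at zero and drops empty bins", {
  sp <- accumulate_scans(list(toy_spectrum(c(300.01, 400.01), c(100, 10))))
  bg <- accumulate_scans(list(toy_spectrum(c(300.01, 400.01), c(30, 30))))
  out <- subtract_background(sp, bg)
  expect_identical(nrow(out$peaks), 1L)
  expect_equal(out$peaks$intensity, 70)
  # empty background leaves the spectrum unchanged
  none <- centroid_spectrum(numeric(0), numeric(0))
  expect_equal(subtract_background(sp, none)$peaks, sp$peaks)
  # identical spectra cancel exactly
  expect_identical(nrow(subtract_background(sp, sp)$peaks), 0L)
})

test_that("barcode filtering removes strictly sub-threshold peaks", {
  sp <- toy_spectrum(c(100, 200, 300, 400), c(5, 10, 11, 50))
  flt <- apply_noise_model(sp)
  expect_equal(flt$spectrum$peaks$intensity, c(11, 50))
  expect_equal(flt$min_peak_intensity, 11)
  # threshold zero is the identity
  id <- apply_noise_model(sp, noise_model(barcode_threshold = 0))
  expect_identical(nrow(id$spectrum$peaks), 4L)
  expect_warning(apply_noise_model(toy_spectrum(100, 5)), "below")
})

test_that("filtering twice equals filtering once and is threshold-monotone", {
  sp <- toy_spectrum(seq(100, 500, by = 10), c(1:20, 100:120)[1:41])
  once <- apply_noise_model(sp)
  twice <- apply_noise_model(once$spectrum)
  expect_equal(once$spectrum$peaks, twice$spectrum$peaks)
  counts <- vapply(c(0, 5, 11, 50, 200), function(thr) {
    flt <- suppressWarnings(apply_noise_model(sp, noise_model(barcode_threshold = thr)))
    nrow(flt$spectrum$peaks)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the detection boundary is strictly twice the minimum intensity", {
  base <- toy_spectrum(c(100, 300), c(11, 500))
  flt <- apply_noise_model(base)
  # candidate ion at exactly 2 x 11 = 22 counts: undetected
  sp22 <- toy_spectrum(c(100, 200, 300), c(11, 22, 500))
  f22 <- apply_noise_model(sp22)
  expect_false(is_detected(200, f22$spectrum, f22$min_peak_intensity))
  sp23 <- toy_spectrum(c(100, 200, 300), c(11, 23, 500))
  f23 <- apply_noise_model(sp23)
  expect_true(is_detected(200, f23$spectrum, f23$min_peak_intensity))
  # no peak within tolerance
  expect_false(is_detected(250, f23$spectrum, f23$min_peak_intensity))
})
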