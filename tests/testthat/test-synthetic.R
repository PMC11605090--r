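# Synthetic spectrum / mixture / dilution / phantom generators.

test_that("noise-free synthesis is proportional to the in-silico model", {
  s <- "PC 16:0/18:1(9)"
  insil <- build_insilico_spectrum(s)
  syn <- synth_spectrum(s, config = noise_free_config())$spectrum
  expect_identical(nrow(syn$peaks), nrow(insil))
  ratio <- syn$peaks$intensity / insil$intensity
  expect_lt(diff(range(ratio)), 1e-9)
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- spectrum_noise_config(seed = 77)
  a <- synth_spectrum("PC 16:0/18:1(9)", config = cfg)$spectrum
  b <- synth_spectrum("PC 16:0/18:1(9)", config = cfg)$spectrum
  expect_identical(a$peaks, b$peaks)
  c2 <- synth_spectrum("PC 16:0/18:1(9)",
                       config = spectrum_noise_config(seed = 78))$spectrum
  expect_false(identical(a$peaks, c2$peaks))
})

test_that("full dropout leaves only the injected noise peaks", {
  cfg <- spectrum_noise_config(seed = 5, dropout = 1, n_noise_peaks = 12L,
                               intensity_jitter = 0, mz_jitter = 0)
  syn <- synth_spectrum("PC 16:0/18:1(9)", config = cfg)$spectrum
  expect_identical(nrow(syn$peaks), 12L)
  expect_true(all(syn$peaks$intensity == cfg$noise_level))
})

test_that("a 1:0-weighted mixture reduces to the pure component", {
  pure <- synth_spectrum("PC 16:0/18:1(9)", config = noise_free_config())$spectrum
  mix <- synth_mixture(list("PC 16:0/18:1(9)", "PC 16:0/18:1(11)"),
                       c(1, 1e-12), config = noise_free_config())$spectrum
  shared <- intersect(round(pure$peaks$mz, 4), round(mix$peaks$mz, 4))
  expect_identical(length(shared), nrow(pure$peaks))
})

test_that("isomer mixtures sum the shared valley/high peak at m/z 634.444", {
  nf <- noise_free_config()
  mix <- synth_mixture(list("PC 16:0/18:1(9)", "PC 16:0/18:1(11)"),
                       c(1, 1), config = nf)$spectrum
  s9 <- synth_spectrum("PC 16:0/18:1(9)", config = nf)$spectrum
  s11 <- synth_spectrum("PC 16:0/18:1(11)", config = nf)$spectrum
  at <- function(sp, mz) {
    i <- which(abs(sp$peaks$mz - mz) < 0.001)
    if (length(i)) sum(sp$peaks$intensity[i]) else 0
  }
  expect_equal(at(mix, 634.4442),
               at(s9, 634.4442) + at(s11, 634.4442), tolerance = 1e-6)
  expect_gt(at(s11, 634.4442), at(s9, 634.4442))  # high peak vs valley
})

test_that("mixtures are symmetric under component exchange", {
  nf <- noise_free_config(seed = 4)
  ab <- synth_mixture(list("PC 16:0/18:1(9)", "PC 16:0/18:1(11)"), c(3, 1),
                      config = nf)$spectrum
  ba <- synth_mixture(list("PC 16:0/18:1(11)", "PC 16:0/18:1(9)"), c(1, 3),
                      config = nf)$spectrum
  expect_equal(ab$peaks, ba$peaks, tolerance = 1e-12)
})

test_that("dilution series degrade monotonically through the intensity floor", {
  levels <- c(1, 0.3, 0.1, 0.03, 0.01, 0)
  series <- synth_dilution_series("PC 16:0/18:1(9)", levels,
                                  config = noise_free_config())
  counts <- vapply(series, function(s) nrow(s$peaks), integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[[1]], nrow(build_insilico_spectrum("PC 16:0/18:1(9)")))
  expect_identical(counts[[length(counts)]], 0L)
})

test_that("random resolved lipids stay inside the curated space", {
  cfg <- candidate_config()
  for (i in 1:20) {
    sc <- sample(supported_subclasses(), 1)
    trial <- random_resolved_lipid(sc, seed = 400 + i)
    expect_identical(trial$truth$subclass, sc)
    for (ch in trial$truth$chains) {
      if (ch$db == 1L && ch$kind != "sphingoid") {
        expect_true(ch$db_positions %in% mufa_positions(ch$carbons, cfg))
      }
      if (ch$kind == "sphingoid" && ch$db > 0L) {
        expect_true(all(ch$db_positions %in% c(4L, 8L, 14L)))
      }
    }
    # the query collapses the truth to molecular species
    q <- parse_lipid_name(trial$query)
    tq <- eadlipid:::.species_totals(q)
    tt <- eadlipid:::.species_totals(trial$truth)
    expect_identical(tq$carbons, tt$carbons)
    expect_identical(tq$db, tt$db)
  }
})

test_that("phantom truth tables carry enough to score matching automatically", {
  ref <- test_ccs_reference()
  ph <- synth_msi_phantom(ref, list(list(rows = 1:4, cols = 1:4, entries = 1)),
                          seed = 6)
  expect_identical(nrow(ph$truth), 1L)
  expect_identical(ph$truth$name, ref$name[1])
  expect_identical(nrow(ph$spots), 16L)
  ph2 <- synth_msi_phantom(ref, list(list(rows = 1:4, cols = 1:4, entries = 1)),
                           seed = 6)
  expect_identical(ph$spots, ph2$spots)
})
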