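# CRF fragment masses, abundance classes, diagnostic ions, intensity model.

dlpc <- parse_lipid_name("PC 18:2(9,12)/18:2(9,12)")
papc <- parse_lipid_name("PC 16:0/20:4(5,8,11,14)")

test_that("CRF fragment m/z reproduces the published reference values", {
  # DLPC 18:2(9,12) chain
  expect_equal(round(crf_fragment_mz(dlpc, chain = 1, k = 7, series = "H-loss"), 3), 630.413)
  expect_equal(round(crf_fragment_mz(dlpc, chain = 1, k = 10, series = "H-loss"), 3), 670.444)
  expect_equal(round(crf_fragment_mz(dlpc, chain = 1, k = 11, series = "radical"), 3), 685.468)
  expect_equal(round(crf_fragment_mz(dlpc, chain = 1, k = 14, series = "radical"), 3), 725.499)
  # PAPC 20:4(5,8,11,14) chain
  expect_equal(round(crf_fragment_mz(papc, chain = 2, k = 3, series = "H-loss"), 3), 550.350)
  expect_equal(round(crf_fragment_mz(papc, chain = 2, k = 6, series = "H-loss"), 3), 590.382)
  expect_equal(round(crf_fragment_mz(papc, chain = 2, k = 6, series = "H-gain"), 3), 592.397)
  expect_equal(round(crf_fragment_mz(papc, chain = 2, k = 9, series = "H-gain"), 3), 632.429)
  expect_equal(round(crf_fragment_mz(papc, chain = 2, k = 10, series = "radical"), 3), 645.436)
  # V-shape valley ions of the monounsaturated isomer pair
  expect_equal(round(crf_fragment_mz("PC 16:0/18:1(9)", chain = 2, k = 9,
                                     series = "H-loss"), 4), 634.4442)
  expect_equal(round(crf_fragment_mz("PC 16:0/18:1(11)", chain = 2, k = 11,
                                     series = "H-loss"), 4), 662.4755)
})

test_that("the three series are spaced by one hydrogen-atom mass", {
  for (k in c(3, 9, 14)) {
    r <- crf_fragment_mz(dlpc, chain = 1, k = k, series = "radical")
    expect_equal(crf_fragment_mz(dlpc, chain = 1, k = k, series = "H-gain") - r,
                 1.00783, tolerance = 1e-5)
    expect_equal(r - crf_fragment_mz(dlpc, chain = 1, k = k, series = "H-loss"),
                 1.00783, tolerance = 1e-5)
  }
})

test_that("CRF errors on out-of-range or unresolved positions", {
  expect_error(crf_fragment_mz(dlpc, chain = 1, k = 18, series = "radical"),
               "out of range")
  unresolved <- parse_lipid_name("PC 16:0/18:1")
  expect_error(crf_fragment_mz(unresolved, chain = 2, k = 9,
                               series = "radical"), "unresolved")
})

test_that("abundance classes form the V-shape around each double bond", {
  cl <- classify_abundance(acyl_chain(18, 1, db_positions = 9))
  get <- function(k, s) cl$class[cl$k == k & cl$series == s]
  expect_identical(get(7, "H-loss"), "cc_high_hloss")
  expect_identical(get(9, "H-loss"), "cc_low")
  expect_identical(get(9, "radical"), "cc_low")
  expect_identical(get(11, "radical"), "cc_high_radical")
  expect_identical(get(5, "H-loss"), "plain")
})

test_that("PUFA H-gain amplification sits on the methylene carbons", {
  cl <- classify_abundance(acyl_chain(20, 4, db_positions = c(5, 8, 11, 14)))
  pufa_k <- cl$k[cl$class == "cc_pufa_high"]
  expect_true(all(c(6, 9, 12) %in% pufa_k))
  expect_true(all(cl$series[cl$class == "cc_pufa_high"] == "H-gain"))
  # di-unsaturated chains never qualify
  cl2 <- classify_abundance(acyl_chain(18, 2, db_positions = c(9, 12)))
  expect_false(any(cl2$class == "cc_pufa_high"))
  # saturated chains are all plain
  cl3 <- classify_abundance(acyl_chain(16, 0))
  expect_true(all(cl3$class == "plain"))
})

test_that("diagnostic ions include the printed class and sn markers", {
  d <- diagnostic_ions(dlpc)
  expect_equal(round(d$mz[d$label == "head ion C5H15NO4P"], 3), 184.073)
  sn <- d[d$role == "position", ]
  expect_equal(round(sn$mz, 3), 489.321)
  dp <- diagnostic_ions(papc)
  expect_equal(round(dp$mz[dp$role == "position"], 3), 513.321)
})

test_that("betaine-lipid markers carry the isomer-resolving intensity ratio", {
  dgts <- diagnostic_ions(parse_lipid_name("DGTS 16:0/16:0"))
  dgta <- diagnostic_ions(parse_lipid_name("DGTA 16:0/16:0"))
  m204 <- function(d) d$intensity[d$label == "marker C9H18NO4"]
  m236 <- function(d) d$intensity[d$label == "marker C10H22NO5"]
  expect_equal(round(dgts$mz[dgts$label == "marker C9H18NO4"], 3), 204.123)
  expect_equal(round(dgts$mz[dgts$label == "marker C10H22NO5"], 3), 236.149)
  expect_gt(m236(dgts), m204(dgts))
  expect_gt(m204(dgta), m236(dgta))
})

test_that("unsupported subclasses fail loudly", {
  expect_error(diagnostic_ions(lipid_structure("PC", list(acyl_chain(16), acyl_chain(18, 1, 9)),
                                               sn_assigned = TRUE)), NA)
  expect_error(parse_lipid_name("GM3 34:1;O2"), "unsupported")
})

test_that("a chain of n carbons yields 3(n-1) CRF ions before merging", {
  s <- parse_lipid_name("LPC 18:1(9)")
  insil <- build_insilico_spectrum(s, min_mz = 0)
  crf <- insil[insil$series != "diagnostic", ]
  # merging can only reduce the count
  expect_lte(nrow(crf), 3 * 17)
  cl <- classify_abundance(s$chains[[1]])
  expect_identical(nrow(cl), 3L * 17L)
})

test_that("intensity model assigns the published factors", {
  insil <- build_insilico_spectrum(parse_lipid_name("LPC 16:0"), min_mz = 0)
  crf <- insil[insil$series != "diagnostic", ]
  expect_setequal(round(unique(crf$intensity[crf$series == "H-loss"]), 2), 0.5)
  expect_setequal(round(unique(crf$intensity[crf$series == "radical"]), 2), 1.0)
  insil2 <- build_insilico_spectrum(papc)
  expect_true(all(insil2$intensity[insil2$class == "cc_pufa_high"] >= 4.0))
  expect_true(all(insil2$intensity > 0))
  expect_false(is.unsorted(insil2$mz))
})

test_that("isomer spectra share the valley peak but differ in its class", {
  s9 <- build_insilico_spectrum("PC 16:0/18:1(9)")
  s11 <- build_insilico_spectrum("PC 16:0/18:1(11)")
  p9 <- s9[abs(s9$mz - 634.4442) < 0.001, ]
  p11 <- s11[abs(s11$mz - 634.4442) < 0.001, ]
  expect_identical(p9$class, "cc_low")
  expect_identical(p11$class, "cc_high_hloss")
})

test_that("fragment plus neutral loss reconstructs the precursor exactly", {
  pre <- precursor_mz(dlpc)
  for (k in c(2, 9, 13)) {
    loss <- eadlipid:::.crf_loss_mass(dlpc$chains[[1]], k)
    expect_equal(crf_fragment_mz(dlpc, chain = 1, k = k, series = "radical") +
                   loss, pre, tolerance = 1e-9)
  }
})
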