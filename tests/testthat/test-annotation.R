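# Decision-tree scoring and candidate ranking.

nf <- noise_free_config

test_that("reverse dot product is 1 for proportional and 0 for disjoint spectra", {
  lib <- data.frame(mz = c(300.1, 400.2, 500.3), intensity = c(4, 1, 2))
  prop <- toy_spectrum(lib$mz, lib$intensity * 37)
  expect_equal(reverse_dot_product(prop, lib), 1.0)
  none <- toy_spectrum(c(601, 602), c(5, 5))
  expect_equal(reverse_dot_product(none, lib), 0.0)
  expect_equal(reverse_dot_product(centroid_spectrum(numeric(0), numeric(0)),
                                   lib), 0)
})

test_that("reverse dot product matches the hand-evaluated weighted cosine", {
  lib <- data.frame(mz = c(300.1, 400.2), intensity = c(4, 1))
  ex <- toy_spectrum(c(300.1, 400.2), c(8, 1))
  # (sqrt(8*4) + sqrt(1*1))^2 / ((4+1) * (8+1)), evaluated independently
  expected <- (sqrt(32) + 1)^2 / (5 * 9)
  expect_equal(reverse_dot_product(ex, lib), expected, tolerance = 1e-12)
})

test_that("matched peaks percentage counts matched library ions", {
  lib <- data.frame(mz = c(300, 400, 500, 600), intensity = rep(1, 4))
  expect_equal(matched_peaks_percentage(toy_spectrum(c(300, 400, 500), 1:3), lib), 0.75)
  expect_equal(matched_peaks_percentage(toy_spectrum(lib$mz, 1:4), lib), 1.0)
  expect_equal(matched_peaks_percentage(toy_spectrum(700, 1), lib), 0.0)
})

test_that("V-shape bonus requires a strict 1.5-fold high/low contrast", {
  insil <- build_insilico_spectrum("PC 16:0/18:1(9)")
  high <- insil$mz[insil$class %in% c("cc_high_hloss", "cc_high_radical")]
  low <- insil$mz[insil$class == "cc_low"]
  mk <- function(hi, lo) toy_spectrum(c(high, low),
                                      c(rep(hi, length(high)), rep(lo, length(low))))
  expect_equal(vshape_bonus(mk(160, 100), insil), 0.5)
  expect_equal(vshape_bonus(mk(150, 100), insil), 0)   # strict inequality
  # no low peaks matched: no bonus
  expect_equal(vshape_bonus(toy_spectrum(high, rep(160, length(high))), insil), 0)
})

test_that("PUFA H-gain bonus requires a strict 3-fold excess and 3+ bonds", {
  insil <- build_insilico_spectrum("PC 16:0/20:4(5,8,11,14)")
  pufa <- insil$mz[insil$class == "cc_pufa_high"][1]
  other <- insil$mz[insil$series == "H-gain" & insil$class != "cc_pufa_high"]
  mk <- function(p) toy_spectrum(c(pufa, other),
                                 c(p, rep(100, length(other))))
  expect_equal(pufa_hgain_bonus(mk(400), insil), 0.5)
  expect_equal(pufa_hgain_bonus(mk(300), insil), 0)
  # a monounsaturated candidate never qualifies
  mono <- build_insilico_spectrum("PC 16:0/18:1(9)")
  expect_equal(pufa_hgain_bonus(mk(400), mono), 0)
})

test_that("class diagnostics gate the decision tree", {
  truth <- parse_lipid_name("PC 16:0/18:1(9)")
  syn <- synth_spectrum(truth, config = nf())$spectrum
  ctx <- noise_context(syn)
  d <- evaluate_diagnostics(truth, ctx)
  expect_identical(d$class_score, 1L)
  expect_identical(d$chain_score, 1L)
  expect_identical(d$position_score, 1L)
  # remove the 184.073 head ion: class fails
  keep <- abs(syn$peaks$mz - 184.0733) > 0.01
  gutted <- centroid_spectrum(syn$peaks$mz[keep], syn$peaks$intensity[keep],
                              precursor_mz = syn$precursor_mz)
  d2 <- evaluate_diagnostics(truth, noise_context(gutted))
  expect_identical(d2$class_score, 0L)
})

test_that("missing sn diagnostics cap the assigned level", {
  truth <- parse_lipid_name("PC 16:0/18:1(9)")
  syn <- synth_spectrum(truth, config = nf())$spectrum
  sn_mz <- diagnostic_ions(truth)$mz[diagnostic_ions(truth)$role == "position"]
  keep <- abs(syn$peaks$mz - sn_mz) > 0.01
  gutted <- centroid_spectrum(syn$peaks$mz[keep], syn$peaks$intensity[keep],
                              precursor_mz = syn$precursor_mz)
  res <- annotate_spectrum(gutted, "PC 16:0_18:1")
  top <- res$ranking[1, ]
  expect_identical(top$position_score, 0L)
  expect_identical(top$level, "db_resolved")
})

test_that("deleting an expected C=C high peak eliminates the candidate", {
  truth <- parse_lipid_name("PC 16:0/18:1(9)")
  syn <- synth_spectrum(truth, config = nf())$spectrum
  ctx <- noise_context(syn)
  expect_true(cc_presence_check(truth, ctx))
  # drop the H-loss high peak at C7
  c7 <- crf_fragment_mz(truth, chain = 2, k = 7, series = "H-loss")
  keep <- abs(syn$peaks$mz - c7) > 0.01
  gutted <- centroid_spectrum(syn$peaks$mz[keep], syn$peaks$intensity[keep],
                              precursor_mz = syn$precursor_mz)
  expect_false(cc_presence_check(truth, noise_context(gutted)))
  res <- annotate_spectrum(gutted, "PC 16:0_18:1")
  expect_false("PC 16:0/18:1(9)" %in% res$ranking$name)
})

test_that("hexa-unsaturated chains tolerate exactly one missing high peak", {
  truth <- parse_lipid_name("PC 16:0/22:6(4,7,10,13,16,19)")
  syn <- synth_spectrum(truth, config = nf())$spectrum
  ctx0 <- noise_context(syn)
  expect_true(cc_presence_check(truth, ctx0))
  insil <- build_insilico_spectrum(truth)
  high <- insil$mz[insil$class %in% c("cc_high_hloss", "cc_high_radical") &
                     insil$chain == 2]
  drop_n <- function(n) {
    bad <- high[seq_len(n)]
    keep <- !vapply(syn$peaks$mz, function(m) any(abs(m - bad) < 0.01),
                    logical(1))
    noise_context(centroid_spectrum(syn$peaks$mz[keep],
                                    syn$peaks$intensity[keep],
                                    precursor_mz = syn$precursor_mz))
  }
  expect_true(cc_presence_check(truth, drop_n(1)))
  expect_false(cc_presence_check(truth, drop_n(2)))
})

test_that("noise-free round trips score the ceiling and rank truth first", {
  cases <- list(
    list(truth = "PC 16:0/20:4(5,8,11,14)", query = "PC 16:0_20:4", full = TRUE),
    list(truth = "PC 16:0/18:1(9)", query = "PC 16:0_18:1", full = FALSE),
    list(truth = "SM 18:1(4);O2/16:0", query = "SM 18:1;O2/16:0", full = FALSE))
  for (cs in cases) {
    truth <- parse_lipid_name(cs$truth)
    if (truth$chains[[1]]$kind == "sphingoid") {
      truth$chains[[1]]$oh_positions <- c(1L, 3L)
    }
    syn <- synth_spectrum(truth, config = nf())$spectrum
    res <- annotate_spectrum(syn, cs$query)
    expect_identical(res$ranking$name[1], format_lipid_name(truth))
    if (cs$full) expect_equal(res$ranking$total[1], 6.0, tolerance = 1e-9)
    expect_true(res$ranking$high_confidence[1])
  }
})

test_that("score totals stay within the 0..6 bound on arbitrary spectra", {
  cand <- parse_lipid_name("PC 16:0/18:1(9)")
  insil <- build_insilico_spectrum(cand)
  set.seed(11)
  n_scored <- 0L
  for (i in 1:10) {
    # candidate peaks with randomized intensities plus random clutter, so
    # the presence check can pass while the score components vary freely
    sp <- toy_spectrum(c(insil$mz, sort(runif(40, 150, 760))),
                       c(insil$intensity * rexp(nrow(insil), 1 / 300) + 12,
                         rexp(40, 1 / 100) + 12),
                       pre = 760.5851)
    ctx <- noise_context(sp)
    br <- score_candidate(cand, ctx)
    if (!is.null(br)) {
      n_scored <- n_scored + 1L
      expect_gte(br$total, 0)
      expect_lte(br$total, 6)
      expect_lte(br$double_bond_score, 3)
    }
  }
  expect_gt(n_scored, 0L)
})

test_that("a head-ion-only spectrum falls back to a species-level call", {
  sp <- toy_spectrum(c(184.0733, 300), c(500, 11), pre = 760.5851)
  res <- annotate_spectrum(sp, "PC 16:0_18:1")
  expect_identical(nrow(res$ranking), 0L)
  expect_identical(res$fallback_level, "species")
  expect_identical(res$fallback_name, "PC 34:1")
  # and with nothing at all: unannotated
  empty <- toy_spectrum(c(300, 400), c(11, 11), pre = 760.5851)
  res2 <- annotate_spectrum(empty, "PC 16:0_18:1")
  expect_identical(res2$fallback_level, "unannotated")
})

test_that("co-eluting isomers are retained as ranked alternatives", {
  mix <- synth_mixture(list("PC 16:0/18:1(9)", "PC 16:0/18:1(11)"),
                       c(10, 1), config = nf())
  res <- annotate_spectrum(mix$spectrum, "PC 16:0_18:1")
  expect_identical(res$ranking$name[1], "PC 16:0/18:1(9)")
  expect_true("PC 16:0/18:1(11)" %in% res$ranking$name)
})

test_that("sn2 lysolipids resolve through the CH2OH neutral loss", {
  truth <- parse_lipid_name("LPC 0:0/18:1(9)")
  syn <- synth_spectrum(truth, config = nf())$spectrum
  res <- annotate_spectrum(syn, "LPC 18:1")
  expect_identical(res$ranking$name[1], "LPC 0:0/18:1(9)")
  top <- res$ranking[1, ]
  expect_identical(top$position_score, 1L)
})
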