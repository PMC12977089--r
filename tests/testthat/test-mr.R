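test_that("harmonization aligns swapped, flipped and palindromic alleles", {
  ex <- toySumStats(4, a1 = c("A", "A", "A", "A"),
                    a2 = c("G", "G", "T", "G"),
                    beta = c(0.1, 0.2, 0.3, 0.4))
  # SNP1 direct, SNP2 swapped, SNP3 palindromic (A/T), SNP4 strand-flipped
  ou <- toySumStats(4, a1 = c("A", "G", "A", "T"),
                    a2 = c("G", "A", "T", "C"),
                    beta = c(1, 2, 3, 4))
  h <- harmonize(ex, ou)
  tab <- instrumentTable(h)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$bOut, c(1, -2, 4))
  expect_identical(h@removedPalindromic, "1:3000")
  expect_identical(h@flipped, "1:2000")

  # identical tables pass through minus palindromes, nothing flipped
  h2 <- harmonize(ex, ex)
  expect_equal(nrow(instrumentTable(h2)), 3)
  expect_length(h2@flipped, 0)

  ouDisjoint <- toySumStats(2, snp = c("9:1", "9:2"))
  expect_error(harmonize(ex, ouDisjoint), "no shared")
})

test_that("exclusion regions drop SNPs by chr:pos identifier", {
  ex <- toySumStats(3, snp = c("17:43000000", "17:46000000", "2:500"))
  regions <- data.frame(chr = "17", start = 43e6, end = 45e6)
  h <- harmonize(ex, ex, excludeRegions = regions)
  expect_identical(instrumentTable(h)$snp, c("17:46000000", "2:500"))
  expect_identical(h@removedRegion, "17:43000000")

  exBad <- toySumStats(2, snp = c("rs123", "rs456"))
  expect_warning(harmonize(exBad, exBad, excludeRegions = regions),
                 "chr:pos")
})

test_that("instrument selection filters on the exposure p-value", {
  h <- toyHarmonized(bExp = c(0.1, 0.001, 0.2), seExp = c(0.01, 0.01, 0.01),
                     bOut = c(0.05, 0, 0.1), seOut = rep(0.01, 3))
  all3 <- selectInstruments(h, 0.999999)
  expect_equal(nInstruments(all3), 3)
  strict <- selectInstruments(h, 5e-8)
  expect_equal(nInstruments(strict), 2)   # the weak SNP drops out
  expect_warning(selectInstruments(toyHarmonized(0.001, 0.01, 0, 0.01),
                                   5e-8), "no SNP")
  expect_error(selectInstruments(h, 2), "pThreshold")
})

test_that("IVW reduces to the ratio estimate and is order/duplication invariant", {
  single <- toyHarmonized(0.2, 0.01, 0.06, 0.01)
  expect_equal(estimate(mrIvw(single)), 0.3, tolerance = 1e-12)

  set.seed(20)
  k <- 20
  bx <- runif(k, 0.05, 0.2); by <- 0.4 * bx + rnorm(k, 0, 0.01)
  h <- toyHarmonized(bx, rep(0.01, k), by, rep(0.01, k))
  est <- mrIvw(h)
  o <- sample(k)
  hPerm <- toyHarmonized(bx[o], rep(0.01, k), by[o], rep(0.01, k))
  expect_equal(estimate(mrIvw(hPerm)), estimate(est), tolerance = 1e-12)
  hDup <- toyHarmonized(rep(bx, 2), rep(0.01, 2 * k), rep(by, 2),
                        rep(0.01, 2 * k))
  expect_equal(estimate(mrIvw(hDup)), estimate(est), tolerance = 1e-12)

  null <- toyHarmonized(bx, rep(0.01, k), rep(0, k), rep(0.01, k))
  expect_equal(estimate(mrIvw(null)), 0)
  expect_warning(mrIvw(toyHarmonized(c(0, 0.1), c(0.01, 0.01),
                                     c(0, 0.03), c(0.01, 0.01))),
                 "zero exposure")
})

test_that("Egger recovers a directional pleiotropy intercept with unbiased slope", {
  set.seed(21)
  k <- 50
  bx <- runif(k, 0.05, 0.2)
  cIntercept <- 0.02
  by <- cIntercept + 0.3 * bx + rnorm(k, 0, 0.005)
  h <- toyHarmonized(bx, rep(0.005, k), by, rep(0.005, k))
  eg <- mrEgger(h)
  expect_lt(abs(estimate(eg) - 0.3), 0.05)
  expect_lt(abs(eg@details$intercept - cIntercept), 0.005)
  expect_lt(eg@details$interceptP, 0.01)

  # intercept-free data: Egger agrees with IVW
  by0 <- 0.3 * bx + rnorm(k, 0, 0.005)
  h0 <- toyHarmonized(bx, rep(0.005, k), by0, rep(0.005, k))
  expect_lt(abs(estimate(mrEgger(h0)) - estimate(mrIvw(h0))), 0.03)
  expect_error(mrEgger(toyHarmonized(c(0.1, 0.2), c(0.01, 0.01),
                                     c(0.03, 0.06), c(0.01, 0.01))),
               "at least 3")
})

test_that("the weighted median resists up to half invalid instruments", {
  # negligible exposure noise makes all five weights equal: the estimate
  # is the middle ratio
  eq <- toyHarmonized(rep(0.1, 5), rep(1e-8, 5),
                      0.1 * c(0.1, 0.2, 0.3, 0.4, 0.5), rep(0.01, 5))
  expect_equal(estimate(mrWeightedMedian(eq, nBoot = 50, seed = 1)), 0.3,
               tolerance = 1e-9)

  set.seed(22)
  k <- 40
  bx <- runif(k, 0.05, 0.2)
  by <- 0.3 * bx + rnorm(k, 0, 0.003)
  bad <- seq_len(k / 2 - 1)           # just under half invalid
  by[bad] <- by[bad] + 0.15
  h <- toyHarmonized(bx, rep(0.003, k), by, rep(0.003, k))
  wm <- mrWeightedMedian(h, nBoot = 200, seed = 2)
  ivw <- mrIvw(h)
  expect_lt(abs(estimate(wm) - 0.3), abs(estimate(ivw) - 0.3))
  expect_lt(abs(estimate(wm) - 0.3), 0.1)

  # duplicating every SNP leaves the weighted median essentially
  # unchanged (exactly, up to the interpolation grid of the estimator)
  hDup <- toyHarmonized(rep(bx, 2), rep(0.003, 2 * k), rep(by, 2),
                        rep(0.003, 2 * k))
  expect_equal(estimate(mrWeightedMedian(hDup, nBoot = 50, seed = 3)),
               estimate(mrWeightedMedian(h, nBoot = 50, seed = 3)),
               tolerance = 5e-3)
})

test_that("the weighted mode finds the majority ratio and ignores weight scale", {
  same <- toyHarmonized(c(0.1, 0.2, 0.4), rep(0.01, 3),
                        0.25 * c(0.1, 0.2, 0.4), rep(0.01, 3))
  expect_equal(estimate(mrWeightedMode(same, nBoot = 50, seed = 1)), 0.25,
               tolerance = 1e-9)

  set.seed(23)
  k <- 45
  bx <- runif(k, 0.05, 0.2)
  by <- 0.3 * bx + rnorm(k, 0, 0.002)
  by[1:15] <- by[1:15] + runif(15, 0.05, 0.3)   # minority invalid, spread out
  h <- toyHarmonized(bx, rep(0.002, k), by, rep(0.002, k))
  wm <- mrWeightedMode(h, nBoot = 100, seed = 2)
  expect_lt(abs(estimate(wm) - 0.3), 0.1)

  # scaling every outcome SE by a constant rescales all weights equally
  h2 <- toyHarmonized(bx, rep(0.002, k), by, rep(0.002 * 3, k))
  expect_equal(estimate(mrWeightedMode(h2, nBoot = 50, seed = 4)),
               estimate(mrWeightedMode(h, nBoot = 50, seed = 4)),
               tolerance = 1e-6)
})

test_that("the HEIDI filter removes spiked outliers and restores the estimate", {
  set.seed(24)
  k <- 30
  bx <- runif(k, 0.05, 0.2)
  # noise well below the nominal SE keeps every z-score deep inside the
  # HEIDI acceptance region: genuinely outlier-free data
  by <- 0.3 * bx + rnorm(k, 0, 0.001)
  h <- toyHarmonized(bx, rep(0.005, k), by, rep(0.005, k))
  clean <- mrGsmr(h)
  expect_length(removedSnps(clean), 0)
  expect_equal(estimate(clean), estimate(mrIvw(h)), tolerance = 1e-6)

  bySpike <- by
  bySpike[5] <- by[5] + 10 * 0.005 * 10    # gross pleiotropic outlier
  hS <- toyHarmonized(bx, rep(0.005, k), bySpike, rep(0.005, k))
  gs <- mrGsmr(hS)
  expect_true(instrumentTable(hS)$snp[5] %in% removedSnps(gs))
  expect_lt(abs(estimate(gs) - 0.3),
            abs(estimate(mrIvw(hS)) - 0.3))
  expect_lt(abs(estimate(gs) - 0.3), 0.05)

  # threshold zero disables removal entirely
  off <- mrGsmr(hS, heidiPThreshold = 0)
  expect_length(removedSnps(off), 0)
  expect_equal(estimate(off), estimate(mrIvw(hS)), tolerance = 1e-12)
})

test_that("sensitivity analysis reports Q, Egger intercept and leave-one-out", {
  set.seed(25)
  k <- 25
  bx <- runif(k, 0.05, 0.2)
  by <- 0.2 * bx + rnorm(k, 0, 0.004)
  by[k] <- by[k] + 0.2                 # dominant outlier
  h <- toyHarmonized(bx, rep(0.004, k), by, rep(0.004, k))
  sens <- mrSensitivity(h)
  expect_equal(nrow(sens$leaveOneOut), k)
  expect_identical(sens$maxDeviationSnp, instrumentTable(h)$snp[k])
  expect_lt(sens$QP, 1e-6)             # heterogeneity detected

  byHom <- 0.2 * bx + rnorm(k, 0, 0.004)
  hHom <- toyHarmonized(bx, rep(0.004, k), byHom, rep(0.004, k))
  expect_gt(mrSensitivity(hHom)$QP, 1e-3)
})

test_that("all five estimators agree on clean simulations", {
  gp <- simulateGwasPair(nSnps = 60, nInstruments = 40, bxy = 0.25,
                         seed = 26)
  h <- suppressWarnings(selectInstruments(harmonize(gp$exposure,
                                                    gp$outcome)))
  ests <- list(mrIvw(h), mrEgger(h),
               mrWeightedMedian(h, nBoot = 200, seed = 1),
               mrWeightedMode(h, nBoot = 200, seed = 1), mrGsmr(h))
  for (e in ests)
    expect_lt(abs(estimate(e) - 0.25), 2 * max(stdError(e), 0.02))
  expect_setequal(vapply(ests, mrMethod, ""),
                  c("IVW", "Egger", "weighted_median", "weighted_mode",
                    "GSMR"))
  # OR transform consistency
  expect_equal(log(oddsRatio(ests[[1]])), estimate(ests[[1]]))
  ci <- oddsRatioCI(ests[[1]])
  expect_true(ci[1] < oddsRatio(ests[[1]]) && oddsRatio(ests[[1]]) < ci[2])
})

test_that("bidirectional MR finds forward-only causality with tiered annotation", {
  traits <- c("total_surface_area", "ADHD")
  cm <- matrix(0, 2, 2, dimnames = list(traits, traits))
  cm["total_surface_area", "ADHD"] <- 0.3
  panel <- simulateGwasPanel(traits, nInstrumentsPerTrait = 40,
                             causalMatrix = cm, sampleSizes = 200000,
                             seed = 27)
  res <- runBidirectionalMr(panel["total_surface_area"], panel["ADHD"],
                            methods = c("IVW", "GSMR"), nDiseases = 13,
                            seed = 28)
  expect_equal(nrow(res), 4)    # 1 pair x 2 directions x 2 methods
  fwd <- res[res$direction == "forward" & res$method == "IVW", ]
  rev <- res[res$direction == "reverse" & res$method == "IVW", ]
  expect_lt(abs(fwd$beta - 0.3), 2 * fwd$se)
  expect_lt(fwd$p, 0.05 / 3 / 13)
  expect_identical(fwd$tier, "study_wise")
  expect_gt(rev$p, 0.05)
  expect_identical(rev$tier, "none")
  # threshold annotation arithmetic of the three-tier scheme
  thr <- attr(res, "thresholds")
  expect_equal(unname(thr["disease_wise"]), 0.05 / 1, tolerance = 1e-12)

  res3 <- runBidirectionalMr(
    setNames(rep(panel["total_surface_area"], 3),
             c("total_surface_area", "mean_thickness", "ICV")),
    panel["ADHD"], methods = "IVW", nDiseases = 13, seed = 29)
  thr3 <- attr(res3, "thresholds")
  expect_equal(signif(unname(thr3["disease_wise"]), 2), 1.7e-2)
  expect_lt(abs(thr3[["disease_wise"]] - 1.6e-2), 1e-3)
  expect_lt(abs(thr3[["study_wise"]] - 1.2e-3), 1e-4)
  expect_lte(nrow(res3), 39 * 2)
})
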