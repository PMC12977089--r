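test_that("cohort generation is bit-reproducible under a fixed seed", {
  a <- simulateCohort(nParticipants = 100, seed = 11)
  b <- simulateCohort(nParticipants = 100, seed = 11)
  expect_identical(brainMeasures(a), brainMeasures(b))
  expect_identical(prsScores(a), prsScores(b))
  c <- simulateCohort(nParticipants = 100, seed = 12)
  expect_false(identical(brainMeasures(a), brainMeasures(c)))

  m1 <- simulateEffectMap(letters[1:5], "random", seed = 3)
  m2 <- simulateEffectMap(letters[1:5], "random", seed = 3)
  expect_identical(effectSizes(m1), effectSizes(m2))

  g1 <- simulateGwasPair(nSnps = 50, nInstruments = 10, seed = 5)
  g2 <- simulateGwasPair(nSnps = 50, nInstruments = 10, seed = 5)
  expect_identical(sumstats(g1$exposure), sumstats(g2$exposure))
  expect_identical(sumstats(g1$outcome), sumstats(g2$outcome))
})

test_that("a null cohort carries no PRS-brain correlation beyond noise", {
  bc <- simulateCohort(nParticipants = 5000, regions = smallRegions(3),
                       diseases = c("ADHD", "SZ"), seed = 21)
  pm <- prepareMeasures(bc)
  prs <- prsScores(bc)
  lim <- 3 / sqrt(5000)
  for (d in colnames(prs))
    for (j in seq_len(ncol(pm)))
      expect_lt(abs(cor(prs[, d], pm[, j])), lim)
})

test_that("planted regional effects are recovered by the association scan", {
  regions <- smallRegions(3)
  eff <- matrix(0, 2, 3, dimnames = list(c("ADHD", "SZ"),
                                         paste0("SA_", regions$SA)))
  eff["ADHD", "SA_bankssts"] <- -0.05
  bc <- simulateCohort(nParticipants = 20000, regions = regions,
                       diseases = c("ADHD", "SZ"), prsEffect = eff,
                       seed = 31)
  res <- associationScan(bc)
  hit <- res[res$disease == "ADHD" & res$region == "bankssts", ]
  expect_gt(hit$beta, -0.07)
  expect_lt(hit$beta, -0.03)
  # null cell stays null
  null <- res[res$disease == "SZ" & res$region == "bankssts", ]
  expect_gt(null$p, 1e-4)
})

test_that("invalid generator configurations are rejected with the field named", {
  expect_error(simulateCohort(nParticipants = 1), "nParticipants")
  expect_error(simulateCohort(100, regions = list(SA = character())),
               "regions")
  expect_error(simulateCohort(100, diseases = c("A", "B"),
                              prsEffect = matrix(0, 3, 2)), "prsEffect")
  expect_error(simulateCohort(100, noiseSd = 0), "noiseSd")
  expect_error(simulateGwasPair(nSnps = 5, nInstruments = 10),
               "nInstruments")
  expect_warning(simulateGwasPair(nSnps = 10, nInstruments = 2, seed = 1),
                 "fewer than 3")
})

test_that("liability-threshold diagnoses behave at the boundary cases", {
  bc <- simulateCohort(nParticipants = 400, regions = smallRegions(2),
                       diseases = "SZ", seed = 41)
  suppressWarnings({
    allFalse <- simulateDiagnoses(bc, threshold = Inf, seed = 1)
  })
  expect_false(any(diagnoses(allFalse)))
  expect_warning(simulateDiagnoses(bc, threshold = Inf, seed = 1),
                 "no cases")

  # no signal, threshold 0: prevalence near one half
  half <- simulateDiagnoses(bc, wPrs = 0, wBrain = 0, threshold = 0,
                            seed = 2)
  prev <- mean(diagnoses(half))
  expect_gt(prev, 0.40)
  expect_lt(prev, 0.60)
})

test_that("diagnosed individuals carry elevated PRS under the liability model", {
  # truncated-normal expectation: cases selected on liability containing
  # the PRS must have mean PRS above the population mean of 0
  bc <- simulateCohort(nParticipants = 33861, regions = smallRegions(2),
                       diseases = "BPD", prsGlobalEffect = c(BPD = -0.1),
                       seed = 51)
  bc <- simulateDiagnoses(bc, wPrs = 1, wBrain = 0.5, prevalence = 0.002,
                          seed = 52)
  dx <- diagnoses(bc)[, "BPD"]
  expect_gt(sum(dx), 10)
  prs <- prsScores(bc)[, "BPD"]
  expect_gt(mean(prs[dx]), mean(prs) + 0.5)
})

test_that("simulated GWAS pairs have significant instruments and calibrated IVW", {
  gp <- simulateGwasPair(nSnps = 300, nInstruments = 50, bxy = 0.3,
                         nExposure = 200000, seed = 61)
  ex <- sumstats(gp$exposure)
  instr <- ex$snp %in% gp$instruments
  expect_gte(sum(ex$p[instr] < 5e-8), 45)      # near-complete power
  expect_lt(max(ex$p[instr]), 0.05)
  # non-instrument SNPs are null
  expect_gt(min(ex$p[!instr]), 1e-6)

  h <- suppressWarnings(selectInstruments(harmonize(gp$exposure,
                                                    gp$outcome)))
  est <- mrIvw(h)
  expect_lt(abs(estimate(est) - 0.3), 1.96 * stdError(est))
})

test_that("effect map patterns honor the sign request and the magnitude cap", {
  m <- simulateEffectMap(dkCorticalRegions(), "all-negative", seed = 71)
  expect_length(regions(m), 34)
  expect_true(all(effectSizes(m) < 0))
  expect_lte(max(abs(effectSizes(m))), 0.45)
  p <- simulateEffectMap(letters[1:6], "all-positive", seed = 72)
  expect_true(all(effectSizes(p) > 0))
  # identical sign pattern implies full concordance
  sc <- signConcordance(m, simulateEffectMap(dkCorticalRegions(),
                                             "all-negative", seed = 99))
  expect_identical(sc$k, sc$n)
})
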