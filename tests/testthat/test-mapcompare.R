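test_that("Cohen's d conversions follow their defining formulas", {
  expect_equal(cohenDFromT(0, 50, 60), 0)
  expect_equal(cohenDFromT(2, 100, 100), 2 * sqrt(0.02), tolerance = 1e-12)
  ts <- c(-3, -0.5, 0.7, 4)
  expect_identical(sign(cohenDFromT(ts, 30, 40)), sign(ts))
  expect_error(cohenDFromT(1, 1, 10), ">= 2")

  expect_equal(cohenD(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohenD(c(1, 2, 3), c(4, 5, 7)),
               -cohenD(c(4, 5, 7), c(1, 2, 3)))
  # hand check against pooled-SD formula
  x <- c(2, 4, 6); y <- c(1, 2)
  sp <- sqrt((2 * var(x) + 1 * var(y)) / 3)
  expect_equal(cohenD(x, y), (4 - 1.5) / sp, tolerance = 1e-12)
  expect_error(cohenD(c(1, 1), c(1, 1)), "zero pooled")
})

test_that("the median split puts strictly-above-median values in the high group", {
  g <- medianSplit(1:10)
  expect_equal(sum(g == "high"), 5)
  g2 <- medianSplit(c(1, 2, 2, 3))
  expect_identical(as.character(g2), c("low", "low", "low", "high"))
  expect_error(medianSplit(rep(2, 10)), "constant")
  set.seed(6)
  g3 <- medianSplit(rnorm(33861))
  expect_lte(abs(sum(g3 == "high") - sum(g3 == "low")), 1)
})

test_that("a planted PRS effect appears in the median-split genetic-risk map", {
  # theory: splitting a standard-normal PRS at its median shifts the mean
  # PRS between groups by 2*sqrt(2/pi); a linear effect beta transfers a
  # mean difference 2*beta*sqrt(2/pi) to the measure (up to the measure SD)
  regions <- smallRegions(2)
  eff <- matrix(c(0.05, 0), 1, 2,
                dimnames = list("SZ", paste0("SA_", regions$SA)))
  bc <- simulateCohort(nParticipants = 30000, regions = regions,
                       diseases = "SZ", prsEffect = eff,
                       globalFactorSd = 0.3, seed = 91)
  em <- prsEffectMap(bc, "SZ", "SA")
  expect_identical(contrastType(em), "prs_split")
  d <- effectSizes(em)
  theory <- 2 * 0.05 * sqrt(2 / pi)
  expect_lt(abs(d[["bankssts"]] - theory), 0.035)
  expect_lt(abs(d[["caudalanteriorcingulate"]]), 0.035)
})

test_that("atlas crosswalk averages with the stated weights", {
  m <- toyMap(c(0.2, 0.4), c("a", "b"))
  w <- data.frame(target = c("t", "t"), source = c("a", "b"),
                  weight = c(0.5, 0.5))
  expect_equal(unname(effectSizes(crosswalkMap(m, w))), 0.3)

  idw <- data.frame(target = c("a", "b"), source = c("a", "b"),
                    weight = c(1, 1))
  expect_equal(effectSizes(crosswalkMap(m, idw)), effectSizes(m))

  # permuting rows with matching weights changes nothing
  wPerm <- w[c(2, 1), ]
  expect_equal(effectSizes(crosswalkMap(m, wPerm)),
               effectSizes(crosswalkMap(m, w)))
  expect_error(crosswalkMap(m, data.frame(target = "t", source = "a",
                                          weight = 0.8)), "sum")
  expect_error(crosswalkMap(m, data.frame(target = "t", source = "zz",
                                          weight = 1)), "zz")
})

test_that("sign concordance equals the exact binomial tail and 2^n enumeration", {
  set.seed(10)
  for (n in c(4, 7, 10, 12)) {
    a <- toyMap(rnorm(n))
    b <- toyMap(rnorm(n))
    sc <- signConcordance(a, b)
    # brute force: tail probability from all 2^n equally likely sign vectors
    signs <- as.matrix(expand.grid(rep(list(0:1), n)))
    pBrute <- mean(rowSums(signs) >= sc$k)
    expect_equal(sc$pSign, pBrute, tolerance = 1e-12)
  }

  allneg <- toyMap(rep(-0.2, 34))
  sc <- signConcordance(allneg, toyMap(-runif(34)))
  expect_equal(sc$pSign, 0.5^34, tolerance = 1e-12)

  # negation flips k to n - k; both-negation leaves k unchanged
  a <- toyMap(c(-1, 2, 3, -4, 5, 6))
  b <- toyMap(c(-2, 1, 3, 4, -5, 6))
  sc1 <- signConcordance(a, b)
  scNeg <- signConcordance(a, toyMap(-effectSizes(b)))
  expect_equal(scNeg$k, sc1$n - sc1$k)
  scBoth <- signConcordance(toyMap(-effectSizes(a)),
                            toyMap(-effectSizes(b)))
  expect_equal(scBoth$k, sc1$k)

  neg <- signConcordance(a, toyMap(-effectSizes(a)))
  expect_equal(neg$k, 0)
  expect_equal(neg$pSign, 1)
})

test_that("zero and absent effects are excluded from the concordance count", {
  a <- toyMap(c(0.5, 0, -0.3, NA, 0.2), paste0("r", 1:5))
  b <- toyMap(c(0.4, 0.9, -0.1, 0.3, 0.6), paste0("r", 1:5))
  sc <- signConcordance(a, b)
  expect_equal(sc$n, 3)   # r2 zero, r4 absent
  expect_equal(sc$k, 3)
  # the 1-of-6 subcortical configuration gives the printed 0.984 tail
  sub <- signConcordance(toyMap(c(1, -1, -1, -1, -1, -1)),
                         toyMap(rep(1, 6)))
  expect_equal(sub$proportion, 1 / 6, tolerance = 1e-12)
  expect_equal(sub$pSign, binomTailOracle(1, 6), tolerance = 1e-12)
  expect_equal(round(sub$pSign, 3), 0.984)
})

test_that("the permutation correlation p is exact for small maps", {
  set.seed(12)
  for (n in c(4, 5, 6)) {
    a <- toyMap(rnorm(n)); b <- toyMap(rnorm(n))
    pc <- spatialCorrelation(a, b)
    expect_true(pc$exact)
    # oracle: enumerate every permutation with Heap's algorithm
    perms <- heapPermutations(n)
    da <- unname(effectSizes(a)); db <- unname(effectSizes(b))
    rStar <- apply(perms, 1, function(p) cor(da, db[p]))
    expect_equal(pc$pPerm, mean(abs(rStar) >= abs(pc$r) - 1e-12),
                 tolerance = 1e-12)
    expect_equal(pc$halfwidth, 1.96 * sqrt((1 - pc$r^2) / (n - 2)),
                 tolerance = 1e-12)
  }
})

test_that("sampled permutation p-values are seed-stable within binomial error", {
  set.seed(13)
  a <- toyMap(rnorm(20)); b <- toyMap(0.5 * effectSizes(a) + rnorm(20))
  nPerm <- 2000
  p1 <- spatialCorrelation(a, b, nPerm = nPerm, seed = 1)$pPerm
  p2 <- spatialCorrelation(a, b, nPerm = nPerm, seed = 2)$pPerm
  pbar <- (p1 + p2) / 2
  expect_lt(abs(p1 - p2), 3 * sqrt(pbar * (1 - pbar) / nPerm) + 1e-9)
  expect_identical(p1,
                   spatialCorrelation(a, b, nPerm = nPerm, seed = 1)$pPerm)

  ident <- spatialCorrelation(a, a, nPerm = nPerm, seed = 3)
  expect_equal(ident$r, 1)
  expect_equal(ident$pPerm, 1 / (nPerm + 1))  # minimum attainable

  # negating one map negates r
  neg <- spatialCorrelation(a, toyMap(-effectSizes(b)), nPerm = 0)
  base <- spatialCorrelation(a, b, nPerm = 0)
  expect_equal(neg$r, -base$r, tolerance = 1e-12)
})

test_that("independent random maps give calibrated concordance", {
  set.seed(14)
  props <- numeric(300); pv <- numeric(300)
  for (i in seq_len(300)) {
    sc <- signConcordance(toyMap(rnorm(34)), toyMap(rnorm(34)))
    props[i] <- sc$proportion; pv[i] <- sc$pSign
  }
  expect_lt(abs(mean(props) - 0.5), 0.02)
  # discrete p is stochastically >= uniform
  expect_lte(mean(pv < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("map comparison tables carry BH-adjusted permutation p-values", {
  set.seed(15)
  atlas <- paste0("r", 1:20)
  risk <- lapply(1:4, function(i) toyMap(rnorm(20), atlas))
  names(risk) <- c("ADHD", "ASD", "BPD", "SZ")
  diag <- lapply(risk, function(m)
    toyMap(effectSizes(m) + rnorm(20, sd = 0.5), atlas))
  tab <- compareMaps(risk, diag, nPerm = 500, seed = 9)
  expect_identical(tab$disorder, names(risk))
  expect_equal(tab$qFdr, p.adjust(tab$pPerm, "BH"))
  expect_equal(tab$halfwidth, 1.96 * sqrt((1 - tab$r^2) / (tab$n - 2)),
               tolerance = 1e-12)
  # hand BH step-up on a known vector
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
})
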