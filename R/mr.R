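# Two-sample Mendelian randomization: harmonization, instrument
# selection, five estimators, sensitivity analyses, bidirectional driver.

flipAllele <- function(a) c(A = "T", T = "A", C = "G", G = "C")[a]

isPalindromic <- function(a1, a2) flipAllele(a1) == a2

newMREstimate <- function(method, beta, se, p, nIv, removed = character(),
                          details = list())
  new("MREstimate", method = method, beta = beta, se = se, p = p,
      nIv = as.integer(nIv), removed = removed, details = details)

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the two studies to a common effect allele per SNP: direct
#' matches pass through, allele swaps negate the outcome effect, strand
#' flips are resolved by complementing, and SNPs whose alleles cannot be
#' reconciled are dropped. Palindromic SNPs (A/T, C/G) are removed
#' because their strand is ambiguous. Optionally removes SNPs falling in
#' excluded genomic regions (e.g. long-range LD blocks such as 17q21.31)
#' given a BED-like table; SNP identifiers must then parse as
#' `chr:pos`.
#'
#' @param exposure,outcome [GwasSumStats-class] objects with overlapping
#'   SNPs.
#' @param excludeRegions optional data.frame with columns `chr`,
#'   `start`, `end` (see [readRegionFile()]).
#' @return a [HarmonizedSet-class].
#' @export
harmonize <- function(exposure, outcome, excludeRegions = NULL) {
  stopifnot(is(exposure, "GwasSumStats"), is(outcome, "GwasSumStats"))
  ex <- sumstats(exposure)
  ou <- sumstats(outcome)
  shared <- intersect(ex$snp, ou$snp)
  if (!length(shared)) stop("no shared SNPs between studies", call. = FALSE)
  ex <- ex[match(shared, ex$snp), ]
  ou <- ou[match(shared, ou$snp), ]

  pal <- isPalindromic(ex$a1, ex$a2) | isPalindromic(ou$a1, ou$a2)
  removedPal <- shared[pal]

  direct <- ou$a1 == ex$a1 & ou$a2 == ex$a2
  swapped <- ou$a1 == ex$a2 & ou$a2 == ex$a1
  strand <- flipAllele(ou$a1) == ex$a1 & flipAllele(ou$a2) == ex$a2
  strandSwap <- flipAllele(ou$a1) == ex$a2 & flipAllele(ou$a2) == ex$a1
  resolvable <- direct | swapped | strand | strandSwap
  removedMis <- shared[!pal & !resolvable]

  keep <- !pal & resolvable
  sign <- ifelse(swapped | strandSwap, -1, 1)
  flipped <- shared[keep & sign < 0]

  removedRegion <- character()
  if (!is.null(excludeRegions) && nrow(excludeRegions)) {
    parts <- strsplit(shared, ":", fixed = TRUE)
    ok <- lengths(parts) == 2L
    chr <- rep(NA_character_, length(shared))
    pos <- rep(NA_real_, length(shared))
    chr[ok] <- vapply(parts[ok], `[`, "", 1L)
    pos[ok] <- suppressWarnings(as.numeric(vapply(parts[ok], `[`, "", 2L)))
    if (any(!ok | is.na(pos)))
      warning("some SNP ids do not parse as chr:pos; kept unchecked",
              call. = FALSE)
    inRegion <- rep(FALSE, length(shared))
    for (i in seq_len(nrow(excludeRegions))) {
      rg <- excludeRegions[i, ]
      inRegion <- inRegion | (!is.na(pos) & chr == as.character(rg$chr) &
                                pos >= rg$start & pos <= rg$end)
    }
    removedRegion <- shared[keep & inRegion]
    keep <- keep & !inRegion
  }

  tab <- data.frame(snp = shared[keep],
                    bExp = ex$beta[keep], seExp = ex$se[keep],
                    pExp = ex$p[keep],
                    bOut = sign[keep] * ou$beta[keep],
                    seOut = ou$se[keep], pOut = ou$p[keep],
                    stringsAsFactors = FALSE)
  new("HarmonizedSet", table = tab, flipped = flipped,
      removedPalindromic = removedPal, removedRegion = removedRegion,
      removedMismatch = removedMis)
}

#' Select genome-wide-significant instruments
#'
#' Retains SNPs whose exposure p-value is below the threshold (default
#' the genome-wide 5e-8).
#'
#' @param harmonized a [HarmonizedSet-class].
#' @param pThreshold exposure p-value cutoff in (0, 1).
#' @return the filtered [HarmonizedSet-class].
#' @export
selectInstruments <- function(harmonized, pThreshold = 5e-8) {
  stopifnot(is(harmonized, "HarmonizedSet"))
  if (pThreshold <= 0 || pThreshold >= 1)
    stop("'pThreshold' must lie in (0, 1)", call. = FALSE)
  keep <- harmonized@table$pExp < pThreshold
  if (!any(keep))
    warning("no SNP passes the instrument p-value threshold",
            call. = FALSE)
  harmonized@table <- harmonized@table[keep, , drop = FALSE]
  harmonized
}

ivTable <- function(harmonized, minIv = 1L, method = "this method") {
  stopifnot(is(harmonized, "HarmonizedSet"))
  tab <- harmonized@table
  zero <- tab$bExp == 0
  if (any(zero)) {
    warning(sprintf("dropping %d SNP(s) with zero exposure effect",
                    sum(zero)), call. = FALSE)
    tab <- tab[!zero, , drop = FALSE]
  }
  if (nrow(tab) < minIv)
    stop(sprintf("%s needs at least %d instrument(s), got %d", method,
                 minIv, nrow(tab)), call. = FALSE)
  tab
}

#' Inverse-variance-weighted MR estimate
#'
#' Fixed-effect IVW: the weighted mean of per-SNP ratio estimates
#' `bOut/bExp` with weights `bExp^2 / seOut^2`, equivalently the
#' weighted regression of outcome on exposure effects through the
#' origin. `se = 1/sqrt(sum(w))`.
#'
#' @param harmonized a [HarmonizedSet-class] of selected instruments.
#' @return an [MREstimate-class].
#' @export
mrIvw <- function(harmonized) {
  tab <- ivTable(harmonized, 1L, "IVW")
  w <- tab$bExp^2 / tab$seOut^2
  ratio <- tab$bOut / tab$bExp
  beta <- sum(w * ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  newMREstimate("IVW", beta, se, 2 * pnorm(-abs(beta / se)), nrow(tab))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with a free
#' intercept (weights `1/seOut^2`), exposure effects oriented positive.
#' The slope estimates the causal effect under InSIDE; the intercept
#' tests directional pleiotropy. Standard errors use the t distribution
#' with k - 2 df and multiplicative overdispersion bounded below by 1.
#'
#' @param harmonized a [HarmonizedSet-class] with >= 3 instruments.
#' @return an [MREstimate-class]; `details` holds `intercept`,
#'   `interceptSe`, `interceptP`.
#' @export
mrEgger <- function(harmonized) {
  tab <- ivTable(harmonized, 3L, "Egger regression")
  s <- sign(tab$bExp)
  x <- abs(tab$bExp)
  y <- s * tab$bOut
  fit <- lm(y ~ x, weights = 1 / tab$seOut^2)
  sm <- summary(fit)
  infl <- max(1, sm$sigma)
  co <- sm$coefficients
  k <- nrow(tab)
  beta <- co["x", "Estimate"]
  se <- co["x", "Std. Error"] / sm$sigma * infl
  int <- co["(Intercept)", "Estimate"]
  intSe <- co["(Intercept)", "Std. Error"] / sm$sigma * infl
  newMREstimate("Egger", beta, se, 2 * pt(-abs(beta / se), k - 2), k,
                details = list(intercept = int, interceptSe = intSe,
                               interceptP = 2 * pt(-abs(int / intSe),
                                                   k - 2)))
}

weightedMedianCore <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- (cumsum(w) - w / 2) / sum(w)
  if (cw[1] >= 0.5) return(x[1])
  if (cw[length(cw)] <= 0.5) return(x[length(x)])
  approx(cw, x, xout = 0.5, ties = "ordered")$y
}

bootstrapSe <- function(tab, estimator, nBoot, seed) {
  withSeed(seed, {
    reps <- vapply(seq_len(nBoot), function(i) {
      bx <- rnorm(nrow(tab), tab$bExp, tab$seExp)
      by <- rnorm(nrow(tab), tab$bOut, tab$seOut)
      estimator(bx, by, tab)
    }, numeric(1))
    sd(reps)
  })
}

#' Weighted-median MR estimate
#'
#' The inverse-variance-weighted median of per-SNP ratio estimates:
#' consistent when instruments carrying at least half the weight are
#' valid. SE by parametric bootstrap of the summary statistics.
#'
#' @param harmonized a [HarmonizedSet-class] with >= 3 instruments.
#' @param nBoot bootstrap resamples for the SE.
#' @param seed integer seed or `NULL`.
#' @return an [MREstimate-class].
#' @export
mrWeightedMedian <- function(harmonized, nBoot = 1000, seed = NULL) {
  tab <- ivTable(harmonized, 3L, "weighted median")
  est <- function(bx, by, tb) {
    ratio <- by / bx
    seRatio <- sqrt(tb$seOut^2 / bx^2 + by^2 * tb$seExp^2 / bx^4)
    weightedMedianCore(ratio, 1 / seRatio^2)
  }
  beta <- est(tab$bExp, tab$bOut, tab)
  se <- bootstrapSe(tab, est, nBoot, seed)
  newMREstimate("weighted_median", beta, se, 2 * pnorm(-abs(beta / se)),
                nrow(tab), details = list(nBoot = nBoot))
}

#' Weighted-mode MR estimate
#'
#' The mode of the smoothed, inverse-variance-weighted empirical density
#' of per-SNP ratio estimates (normal kernel): consistent when the
#' largest group of instruments sharing a ratio value is valid. SE by
#' parametric bootstrap.
#'
#' @param harmonized a [HarmonizedSet-class] with >= 3 instruments.
#' @param bandwidth multiplicative bandwidth factor (default 1) applied
#'   to the modified-Silverman rule `0.9 min(sd, mad) k^(-1/5)`.
#' @param nBoot bootstrap resamples.
#' @param seed integer seed or `NULL`.
#' @return an [MREstimate-class].
#' @export
mrWeightedMode <- function(harmonized, bandwidth = 1, nBoot = 1000,
                           seed = NULL) {
  tab <- ivTable(harmonized, 3L, "weighted mode")
  assertScalarNumeric(bandwidth, "bandwidth", positive = TRUE)
  est <- function(bx, by, tb) {
    ratio <- by / bx
    seRatio <- tb$seOut / abs(bx)
    w <- 1 / seRatio^2
    spread <- min(sd(ratio), mad(ratio))
    if (spread == 0) return(ratio[1])
    h <- bandwidth * 0.9 * spread * length(ratio)^(-1 / 5)
    de <- density(ratio, weights = w / sum(w), bw = h, n = 512)
    de$x[which.max(de$y)]
  }
  beta <- est(tab$bExp, tab$bOut, tab)
  se <- bootstrapSe(tab, est, nBoot, seed)
  newMREstimate("weighted_mode", beta, se, 2 * pnorm(-abs(beta / se)),
                nrow(tab), details = list(nBoot = nBoot,
                                          bandwidth = bandwidth))
}

#' GSMR-style estimate with iterative HEIDI outlier removal
#'
#' Under identity LD the pooled estimate is IVW. Each iteration scores
#' every SNP by `z_j = (ratio_j - betaHat) / sqrt(var_j)` with the
#' delta-method variance `var_j = (seOut_j^2 + ratio_j^2 seExp_j^2) /
#' bExp_j^2`, removes the single worst SNP among those with two-sided
#' `p(z_j) < heidiPThreshold`, and re-estimates until no SNP falls
#' below the threshold. One removal per iteration matters: a gross
#' outlier biases the pooled estimate enough to push valid instruments
#' past the threshold, so removing all flagged SNPs at once cascades
#' into mass deletion. `heidiPThreshold = 0` disables removal (result
#' equals IVW).
#'
#' @param harmonized a [HarmonizedSet-class]; fewer than 10 instruments
#'   triggers a warning.
#' @param heidiPThreshold HEIDI outlier p-value cutoff (default 0.01).
#' @return an [MREstimate-class]; removed SNPs listed in
#'   `removedSnps()`.
#' @export
mrGsmr <- function(harmonized, heidiPThreshold = 0.01) {
  tab <- ivTable(harmonized, 1L, "GSMR")
  if (nrow(tab) < 10)
    warning("fewer than 10 instruments: GSMR estimate may be unstable",
            call. = FALSE)
  removed <- character()
  repeat {
    w <- tab$bExp^2 / tab$seOut^2
    ratio <- tab$bOut / tab$bExp
    beta <- sum(w * ratio) / sum(w)
    if (heidiPThreshold <= 0) break
    vj <- (tab$seOut^2 + ratio^2 * tab$seExp^2) / tab$bExp^2
    z <- (ratio - beta) / sqrt(vj)
    pz <- 2 * pnorm(-abs(z))
    if (!any(pz < heidiPThreshold)) break
    worst <- which.max(abs(z))
    removed <- c(removed, tab$snp[worst])
    tab <- tab[-worst, , drop = FALSE]
    if (!nrow(tab))
      stop("HEIDI filter removed every instrument", call. = FALSE)
  }
  w <- tab$bExp^2 / tab$seOut^2
  ratio <- tab$bOut / tab$bExp
  beta <- sum(w * ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  newMREstimate("GSMR", beta, se, 2 * pnorm(-abs(beta / se)), nrow(tab),
                removed = removed,
                details = list(heidiPThreshold = heidiPThreshold))
}

#' MR sensitivity analyses
#'
#' Cochran's Q heterogeneity test of the per-SNP ratio estimates around
#' their pooled value (chi-square with k - 1 df), the Egger intercept
#' test of directional pleiotropy, and a leave-one-out IVW series with
#' the maximally deviating SNP flagged. Q uses the delta-method per-SNP
#' ratio variances `(seOut^2 + ratio^2 seExp^2) / bExp^2` (the same
#' variance the HEIDI filter uses): first-order IVW weights ignore the
#' exposure noise and over-reject under the null.
#'
#' @param harmonized a [HarmonizedSet-class] with >= 3 instruments.
#' @return list of class `"mrSensitivity"`: `Q`, `QDf`, `QP`,
#'   `eggerIntercept`, `eggerInterceptP`, `leaveOneOut` (data.frame
#'   `snp`, `beta`, `deviation`), `maxDeviationSnp`.
#' @export
mrSensitivity <- function(harmonized) {
  tab <- ivTable(harmonized, 3L, "sensitivity analysis")
  full <- mrIvw(harmonized)
  w <- tab$bExp^2 / tab$seOut^2
  ratio <- tab$bOut / tab$bExp
  wQ <- tab$bExp^2 / (tab$seOut^2 + ratio^2 * tab$seExp^2)
  betaQ <- sum(wQ * ratio) / sum(wQ)
  Q <- sum(wQ * (ratio - betaQ)^2)
  k <- nrow(tab)
  eg <- mrEgger(harmonized)
  loo <- vapply(seq_len(k), function(i) {
    wi <- w[-i]; ri <- ratio[-i]
    sum(wi * ri) / sum(wi)
  }, numeric(1))
  looDf <- data.frame(snp = tab$snp, beta = loo,
                      deviation = abs(loo - estimate(full)))
  out <- list(Q = Q, QDf = k - 1, QP = pchisq(Q, k - 1, lower.tail = FALSE),
              eggerIntercept = eg@details$intercept,
              eggerInterceptP = eg@details$interceptP,
              leaveOneOut = looDf,
              maxDeviationSnp = tab$snp[which.max(looDf$deviation)])
  class(out) <- "mrSensitivity"
  out
}

#' @export
print.mrSensitivity <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.2f (df %d), p = %.3g\n", x$Q, x$QDf, x$QP))
  cat(sprintf("Egger intercept = %.4f, p = %.3g\n", x$eggerIntercept,
              x$eggerInterceptP))
  cat(sprintf("Leave-one-out: max |deviation| at %s\n", x$maxDeviationSnp))
  invisible(x)
}

mrEstimatorByName <- function(name, harmonized, nBoot, seed,
                              heidiPThreshold) {
  switch(name,
         IVW = mrIvw(harmonized),
         Egger = mrEgger(harmonized),
         weighted_median = mrWeightedMedian(harmonized, nBoot, seed),
         weighted_mode = mrWeightedMode(harmonized, nBoot = nBoot,
                                        seed = seed),
         GSMR = mrGsmr(harmonized, heidiPThreshold),
         stop(sprintf("unknown MR method '%s'", name), call. = FALSE))
}

#' Bidirectional MR between brain measures and disorders
#'
#' For every (brain measure, disorder) pair runs two-sample MR in the
#' forward direction (brain as exposure, disorder as outcome; OR scale)
#' and the reverse direction (disorder as exposure; beta scale), with a
#' three-tier Bonferroni annotation: nominal p < alpha, disease-wise
#' p < alpha / nBrain (0.05/3 = 1.6e-2), study-wise p < alpha /
#' (nBrain * nDiseases) (0.05/39 = 1.2e-3 for 13 disorders). Pairs with
#' a missing direction yield an `unavailable` row.
#'
#' @param brainGwas named list of [GwasSumStats-class], one per global
#'   brain measure.
#' @param disorderGwas named list of [GwasSumStats-class], one per
#'   disorder.
#' @param methods MR estimators to run per cell.
#' @param pThreshold instrument exposure p-value cutoff.
#' @param heidiPThreshold HEIDI cutoff for GSMR.
#' @param nBoot bootstrap resamples for median/mode SEs.
#' @param excludeRegions optional region exclusion table (see
#'   [harmonize()]).
#' @param nDiseases disease count for the study-wise threshold.
#' @param alpha base level.
#' @param seed integer seed or `NULL`.
#' @return data.frame: `exposure`, `outcome`, `direction`, `method`,
#'   `beta`, `se`, `p`, `or`, `ciLow`, `ciHigh`, `nIv`, `nRemoved`,
#'   `tier` (`unavailable` when estimation failed).
#' @export
runBidirectionalMr <- function(brainGwas, disorderGwas,
                               methods = c("IVW", "Egger",
                                           "weighted_median",
                                           "weighted_mode", "GSMR"),
                               pThreshold = 5e-8, heidiPThreshold = 0.01,
                               nBoot = 200, excludeRegions = NULL,
                               nDiseases = length(disorderGwas),
                               alpha = 0.05, seed = NULL) {
  nBrain <- length(brainGwas)
  thr <- c(nominal = alpha, disease_wise = alpha / nBrain,
           study_wise = alpha / (nBrain * nDiseases))
  cell <- function(expo, outc, expoName, outcName, direction, k) {
    res <- lapply(methods, function(mth) {
      est <- tryCatch({
        h <- harmonize(expo, outc, excludeRegions)
        h <- selectInstruments(h, pThreshold)
        mrEstimatorByName(mth, h, nBoot, childSeed(seed, k), heidiPThreshold)
      }, error = function(e) NULL, warning = function(w) {
        tryCatch(suppressWarnings({
          h <- selectInstruments(harmonize(expo, outc, excludeRegions),
                                 pThreshold)
          mrEstimatorByName(mth, h, nBoot, childSeed(seed, k),
                            heidiPThreshold)
        }), error = function(e) NULL)
      })
      if (is.null(est))
        return(data.frame(exposure = expoName, outcome = outcName,
                          direction = direction, method = mth,
                          beta = NA_real_, se = NA_real_, p = NA_real_,
                          or = NA_real_, ciLow = NA_real_,
                          ciHigh = NA_real_, nIv = NA_integer_,
                          nRemoved = NA_integer_, tier = "unavailable"))
      ci <- oddsRatioCI(est)
      p <- pValue(est)
      tier <- if (!is.finite(p)) "unavailable"
      else if (p < thr["study_wise"]) "study_wise"
      else if (p < thr["disease_wise"]) "disease_wise"
      else if (p < thr["nominal"]) "nominal"
      else "none"
      data.frame(exposure = expoName, outcome = outcName,
                 direction = direction, method = mth,
                 beta = estimate(est), se = stdError(est), p = p,
                 or = oddsRatio(est), ciLow = ci[1], ciHigh = ci[2],
                 nIv = nInstruments(est),
                 nRemoved = length(removedSnps(est)), tier = tier)
    })
    do.call(rbind, res)
  }
  rows <- list(); k <- 0L
  for (b in names(brainGwas)) for (d in names(disorderGwas)) {
    k <- k + 1L
    rows[[length(rows) + 1L]] <-
      cell(brainGwas[[b]], disorderGwas[[d]], b, d, "forward", k)
    rows[[length(rows) + 1L]] <-
      cell(disorderGwas[[d]], brainGwas[[b]], d, b, "reverse", k + 10000L)
  }
  out <- do.call(rbind, rows)
  attr(out, "thresholds") <- thr
  out
}
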