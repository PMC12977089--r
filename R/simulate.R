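#' Construct an effect-size map
#'
#' @param regions character region labels (canonical atlas order).
#' @param d numeric Cohen's d per region; `NA` marks an absent region.
#' @param modality `"SA"`, `"CT"`, `"subcortical"` or `"global"`.
#' @param contrast `"diagnosis"` (case-control) or `"prs_split"`
#'   (high- vs low-PRS median split).
#' @param nPair optional integer group sizes (n1, n2).
#' @return an [EffectSizeMap-class] object.
#' @export
effectSizeMap <- function(regions, d, modality = "SA",
                          contrast = "diagnosis", nPair = integer()) {
  new("EffectSizeMap", regions = as.character(regions), d = as.numeric(d),
      modality = modality, contrast = contrast, nPair = as.integer(nPair))
}

#' Simulate a participant cohort with known PRS-brain effects
#'
#' Generates an individual-level cohort emulating a UK-Biobank-style
#' imaging-genetics sample: independent covariates (age uniform on
#' 45.13-81.83 y, sex Bernoulli with male-female ratio 0.9, three scanner
#' sites, a scan-quality proxy, 10 genetic PCs), standard-normal PRS per
#' disease, and brain measures built additively from covariate effects, a
#' shared latent global-size factor, planted standardized PRS effects and
#' Gaussian noise. Measures are on a standardized latent scale; the
#' rank-based inverse normal transformation applied downstream makes all
#' association results scale-invariant.
#'
#' The latent global factor for participant i is
#' `g_i = sum_d prsGlobalEffect[d] * prs_{i,d} + N(0, globalFactorSd)`,
#' and the measure for regional feature r is
#' `covariate terms + g_i + sum_d prsEffect[d, r] * prs_{i,d} +
#' N(0, noiseSd)`. Each global measure is `covariate terms + g_i +
#' N(0, globalNoiseSd)`.
#'
#' @param nParticipants number of participants (>= 2).
#' @param diseases disease labels; one standard-normal PRS column each.
#' @param regions named list of region labels per regional modality
#'   (names among `"SA"`, `"CT"`, `"subcortical"`).
#' @param prsEffect matrix of standardized effects, diseases x regional
#'   features (feature ids `<modality>_<region>`); `NULL` = all zero.
#' @param prsGlobalEffect named numeric, per-disease effect of PRS on the
#'   latent global-size factor; `NULL` = all zero.
#' @param globalFactorSd SD of the latent global-size factor noise.
#' @param covariateEffects named numeric with entries `age` (per year,
#'   centered), `sex`, `euler` (per SD), `site`, `pc`.
#' @param noiseSd residual SD of regional measures (> 0).
#' @param globalNoiseSd residual SD of global measures (> 0).
#' @param seed integer for bit-reproducible output; `NULL` uses the
#'   current RNG stream.
#' @return a [BrainCohort-class].
#' @examples
#' bc <- simulateCohort(nParticipants = 200, seed = 1)
#' dim(brainMeasures(bc))
#' @export
simulateCohort <- function(nParticipants = 1000,
                           diseases = disorderPanel(),
                           regions = list(SA = dkCorticalRegions(),
                                          CT = dkCorticalRegions(),
                                          subcortical = asegSubcorticalRegions()),
                           prsEffect = NULL,
                           prsGlobalEffect = NULL,
                           globalFactorSd = 0.3,
                           covariateEffects = c(age = -0.01, sex = 0.2,
                                                euler = 0.05, site = 0.1,
                                                pc = 0.02),
                           noiseSd = 1,
                           globalNoiseSd = 0.2,
                           seed = NULL) {
  if (!is.numeric(nParticipants) || nParticipants < 2)
    stop("'nParticipants' must be >= 2", call. = FALSE)
  n <- as.integer(nParticipants)
  if (!length(diseases)) stop("'diseases' must be non-empty", call. = FALSE)
  if (!is.list(regions) || !length(regions) ||
      !all(names(regions) %in% c("SA", "CT", "subcortical")))
    stop("'regions' must be a named list over SA/CT/subcortical",
         call. = FALSE)
  if (any(!lengths(regions)))
    stop("'regions' contains an empty region list", call. = FALSE)
  assertScalarNumeric(noiseSd, "noiseSd", positive = TRUE)
  assertScalarNumeric(globalNoiseSd, "globalNoiseSd", positive = TRUE)
  assertScalarNumeric(globalFactorSd, "globalFactorSd", positive = TRUE)

  mods <- rep(names(regions), lengths(regions))
  regNames <- unlist(regions, use.names = FALSE)
  featIds <- paste(mods, regNames, sep = "_")
  nFeat <- length(featIds)
  nDis <- length(diseases)

  if (is.null(prsEffect)) {
    prsEffect <- matrix(0, nDis, nFeat, dimnames = list(diseases, featIds))
  } else {
    prsEffect <- as.matrix(prsEffect)
    if (nrow(prsEffect) != nDis || ncol(prsEffect) != nFeat)
      stop(sprintf(paste0("'prsEffect' must be %d diseases x %d regional",
                          " features, got %d x %d"),
                   nDis, nFeat, nrow(prsEffect), ncol(prsEffect)),
           call. = FALSE)
    if (!is.null(rownames(prsEffect)))
      prsEffect <- prsEffect[diseases, , drop = FALSE]
    if (!is.null(colnames(prsEffect)))
      prsEffect <- prsEffect[, featIds, drop = FALSE]
  }
  if (is.null(prsGlobalEffect)) {
    prsGlobalEffect <- setNames(numeric(nDis), diseases)
  } else {
    if (is.null(names(prsGlobalEffect))) {
      if (length(prsGlobalEffect) != nDis)
        stop("'prsGlobalEffect' must have one entry per disease",
             call. = FALSE)
      names(prsGlobalEffect) <- diseases
    }
    full <- setNames(numeric(nDis), diseases)
    bad <- setdiff(names(prsGlobalEffect), diseases)
    if (length(bad))
      stop(sprintf("'prsGlobalEffect' names unknown diseases: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    full[names(prsGlobalEffect)] <- prsGlobalEffect
    prsGlobalEffect <- full
  }
  ce <- c(age = 0, sex = 0, euler = 0, site = 0, pc = 0)
  ce[names(covariateEffects)] <- covariateEffects

  withSeed(seed, {
    age <- runif(n, 45.13, 81.83)
    sex <- rbinom(n, 1L, 0.9 / 1.9)          # male-female ratio 0.9
    site <- sample.int(3L, n, replace = TRUE)
    euler <- rnorm(n, -120, 40)
    pcs <- matrix(rnorm(n * 10L), n, 10L,
                  dimnames = list(NULL, paste0("pc", 1:10)))
    prs <- matrix(rnorm(n * nDis), n, nDis, dimnames = list(NULL, diseases))

    gFactor <- drop(prs %*% prsGlobalEffect) + rnorm(n, 0, globalFactorSd)
    covTerm <- ce["age"] * (age - 63.48) + ce["sex"] * sex +
      ce["euler"] * (euler + 120) / 40 +
      c(0, ce["site"], -ce["site"])[site] +
      ce["pc"] * rowSums(pcs)

    regional <- covTerm + gFactor + prs %*% prsEffect +
      matrix(rnorm(n * nFeat, 0, noiseSd), n, nFeat)
    globals <- sapply(globalMeasureNames(), function(gm)
      covTerm + gFactor + rnorm(n, 0, globalNoiseSd))

    measure <- t(cbind(regional, globals))
    rownames(measure) <- c(featIds, paste0("global_", globalMeasureNames()))
    ids <- sprintf("P%06d", seq_len(n))
    colnames(measure) <- ids

    cd <- S4Vectors::DataFrame(
      id = ids, age = age, sex = sex, site = factor(site), euler = euler,
      pcs, row.names = ids)
    for (d in diseases) cd[[paste0("prs_", d)]] <- prs[, d]
    rd <- S4Vectors::DataFrame(
      modality = c(mods, rep("global", length(globalMeasureNames()))),
      region = c(regNames, globalMeasureNames()),
      row.names = rownames(measure))

    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(measure = measure), rowData = rd, colData = cd)
    new("BrainCohort", se)
  })
}

#' Liability threshold attaining a target prevalence
#'
#' Under the liability model `L_d = wPrs * PRS_d - wBrain * globalZ +
#' N(0, 1)` with approximately independent standard-normal components,
#' `L_d` has SD `sqrt(wPrs^2 + wBrain^2 + 1)` and the threshold giving
#' case prevalence `prev` is `qnorm(1 - prev) * SD`. The independence
#' approximation is slightly off when the PRS also drives the global
#' factor.
#'
#' @param prevalence target case fraction in (0, 0.5).
#' @param wPrs,wBrain liability weights of PRS and global brain z-score.
#' @return threshold in liability units.
#' @export
liabilityThreshold <- function(prevalence, wPrs = 1, wBrain = 0.5) {
  if (prevalence <= 0 || prevalence >= 0.5)
    stop("'prevalence' must lie in (0, 0.5)", call. = FALSE)
  qnorm(1 - prevalence) * sqrt(wPrs^2 + wBrain^2 + 1)
}

#' Simulate diagnoses from a liability-threshold model
#'
#' Adds one boolean `dx_<disease>` column per disease:
#' `dx = (wPrs * PRS_d - wBrain * globalZ + N(0,1)) > threshold`, where
#' `globalZ` is the standardized mean of the three standardized global
#' measures. Diseases are generated independently of each other.
#'
#' @param cohort a [BrainCohort-class].
#' @param wPrs,wBrain liability weights (both finite; positive values make
#'   high PRS and small brains risk factors).
#' @param threshold liability cutoff in z-units; alternatively give
#'   `prevalence` and the threshold is derived via [liabilityThreshold()].
#' @param prevalence optional target prevalence in (0, 0.5).
#' @param seed integer seed or `NULL`.
#' @return the cohort with diagnosis columns (replacing any existing ones).
#' @export
simulateDiagnoses <- function(cohort, wPrs = 1, wBrain = 0.5,
                              threshold = NULL, prevalence = NULL,
                              seed = NULL) {
  stopifnot(is(cohort, "BrainCohort"))
  if (!is.finite(wPrs) || !is.finite(wBrain))
    stop("liability weights must be finite", call. = FALSE)
  if (is.null(threshold)) {
    if (is.null(prevalence))
      stop("give either 'threshold' or 'prevalence'", call. = FALSE)
    threshold <- liabilityThreshold(prevalence, wPrs, wBrain)
  }
  if (is.nan(threshold)) stop("'threshold' must not be NaN", call. = FALSE)

  glob <- brainMeasures(cohort, modality = "global")
  globalZ <- drop(scale(rowMeans(scale(glob))))
  prs <- prsScores(cohort)
  n <- nrow(prs)

  withSeed(seed, {
    for (d in colnames(prs)) {
      liab <- wPrs * prs[, d] - wBrain * globalZ + rnorm(n)
      dx <- liab > threshold
      if (!any(dx))
        warning(sprintf("no cases generated for '%s' at this threshold", d),
                call. = FALSE)
      SummarizedExperiment::colData(cohort)[[paste0("dx_", d)]] <- dx
    }
    cohort
  })
}

#' Simulate a paired exposure/outcome GWAS for two-sample MR
#'
#' Generates per-SNP summary statistics for an exposure trait and an
#' outcome trait with a known causal effect `bxy` and optional horizontal
#' pleiotropy. SNPs are mutually independent (identity LD). Instrument
#' SNPs receive true exposure effects with non-centrality uniform on
#' 7-12, so essentially all reach genome-wide significance (p < 5e-8) at
#' the stated exposure sample size; remaining SNPs are null. Standard
#' errors follow `1/sqrt(2 f (1-f) N)` for allele frequency `f`. Outcome
#' effects are `bxy * bExp_true + pleiotropy + noise`, pleiotropy drawn
#' as `N(pleiotropyMean, pleiotropySd)` for a `pleiotropyFraction` of the
#' instruments. SNP identifiers are `chr:pos`, alleles non-palindromic.
#'
#' @param nSnps total SNP count.
#' @param nInstruments SNPs given true exposure effects (<= nSnps; a
#'   warning notes that fewer than 3 makes Egger/median methods
#'   unreliable).
#' @param bxy causal effect of exposure on outcome.
#' @param pleiotropyFraction fraction of instruments with a direct
#'   outcome effect, in `[0, 1]`.
#' @param pleiotropyMean,pleiotropySd pleiotropy distribution; a nonzero
#'   mean is directional (violates the IVW/median assumptions but is
#'   absorbed by the Egger intercept).
#' @param nExposure,nOutcome GWAS sample sizes.
#' @param seed integer seed or `NULL`.
#' @return list with [GwasSumStats-class] elements `exposure`, `outcome`,
#'   plus `instruments` (true instrument SNP ids) and `bxy`.
#' @examples
#' gp <- simulateGwasPair(nSnps = 200, nInstruments = 30, bxy = 0.3,
#'                        seed = 7)
#' estimate(mrIvw(selectInstruments(harmonize(gp$exposure, gp$outcome))))
#' @export
simulateGwasPair <- function(nSnps = 1000, nInstruments = 50, bxy = 0,
                             pleiotropyFraction = 0, pleiotropyMean = 0,
                             pleiotropySd = 0.02, nExposure = 200000,
                             nOutcome = 100000, seed = NULL) {
  if (nInstruments > nSnps)
    stop("'nInstruments' must not exceed 'nSnps'", call. = FALSE)
  if (pleiotropyFraction < 0 || pleiotropyFraction > 1)
    stop("'pleiotropyFraction' must lie in [0, 1]", call. = FALSE)
  if (nInstruments < 3)
    warning("fewer than 3 instruments: Egger and median/mode methods are unreliable",
            call. = FALSE)
  withSeed(seed, {
    chr <- sample.int(22L, nSnps, replace = TRUE)
    pos <- sample.int(99000000L, nSnps)    # unique positions
    snp <- paste0(chr, ":", pos)
    pairPool <- matrix(c("A", "C", "A", "G", "C", "A", "G", "A",
                         "C", "T", "T", "C", "G", "T", "T", "G"),
                       ncol = 2, byrow = TRUE)
    pick <- sample.int(nrow(pairPool), nSnps, replace = TRUE)
    a1 <- pairPool[pick, 1]; a2 <- pairPool[pick, 2]
    freq <- runif(nSnps, 0.05, 0.95)
    seX <- 1 / sqrt(2 * freq * (1 - freq) * nExposure)
    seY <- 1 / sqrt(2 * freq * (1 - freq) * nOutcome)

    instrIdx <- seq_len(nInstruments)
    bTrueX <- numeric(nSnps)
    bTrueX[instrIdx] <- sample(c(-1, 1), nInstruments, replace = TRUE) *
      runif(nInstruments, 7, 12) * seX[instrIdx]

    pleio <- numeric(nSnps)
    nPleio <- round(pleiotropyFraction * nInstruments)
    if (nPleio > 0) {
      sel <- if (nPleio == nInstruments) instrIdx else
        sample(instrIdx, nPleio)
      pleio[sel] <- rnorm(nPleio, pleiotropyMean, pleiotropySd)
    }
    bTrueY <- bxy * bTrueX + pleio

    bX <- bTrueX + rnorm(nSnps, 0, seX)
    bY <- bTrueY + rnorm(nSnps, 0, seY)
    pX <- pmax(2 * pnorm(-abs(bX / seX)), 1e-300)
    pY <- pmax(2 * pnorm(-abs(bY / seY)), 1e-300)

    mk <- function(b, se, p, n, trait)
      new("GwasSumStats",
          data = data.frame(snp = snp, a1 = a1, a2 = a2, freq = freq,
                            beta = b, se = se, p = p, n = rep(n, nSnps),
                            stringsAsFactors = FALSE),
          trait = trait)
    list(exposure = mk(bX, seX, pX, nExposure, "exposure"),
         outcome = mk(bY, seY, pY, nOutcome, "outcome"),
         instruments = snp[instrIdx], bxy = bxy)
  })
}

#' Simulate a regional effect-size map
#'
#' Fixture generator for ENIGMA-style case-control maps: draws a Cohen's d
#' per region with a configurable sign pattern and magnitudes bounded by
#' `maxD` (default 0.45, the scale of published case-control cortical
#' maps).
#'
#' @param regions region labels (non-empty).
#' @param pattern `"random"` (uniform on `(-maxD, maxD)`),
#'   `"all-negative"` or `"all-positive"`.
#' @param maxD magnitude bound (> 0).
#' @param modality,contrast stored as map metadata.
#' @param seed integer seed or `NULL`.
#' @return an [EffectSizeMap-class].
#' @export
simulateEffectMap <- function(regions, pattern = c("random", "all-negative",
                                                   "all-positive"),
                              maxD = 0.45, modality = "SA",
                              contrast = "diagnosis", seed = NULL) {
  if (!length(regions)) stop("'regions' must be non-empty", call. = FALSE)
  pattern <- match.arg(pattern)
  assertScalarNumeric(maxD, "maxD", positive = TRUE)
  withSeed(seed, {
    n <- length(regions)
    d <- switch(pattern,
                random = runif(n, -maxD, maxD),
                `all-negative` = -runif(n, maxD / 100, maxD),
                `all-positive` = runif(n, maxD / 100, maxD))
    effectSizeMap(regions, d, modality = modality, contrast = contrast)
  })
}
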