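#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats approx coef cor density lm mad median p.adjust pbinom
#'   pchisq pnorm pt qnorm quantile rbinom rnorm runif sd setNames var
#'   complete.cases
#' @importFrom utils read.delim read.csv write.table head packageVersion
NULL

#' Cohort container for PRS-brain association analysis
#'
#' `BrainCohort` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single `"measure"` assay holding brain morphometric measures (rows =
#' regional and global features, columns = participants). `rowData` carries
#' the feature `modality` (`"SA"`, `"CT"`, `"subcortical"` or `"global"`)
#' and the bare `region` label; `colData` carries the participant
#' covariates (`age`, `sex`, `site`, `euler`, `pc1`..`pc10`), one
#' standardized PRS column per disease (`prs_<disease>`) and optionally one
#' diagnosis flag per disease (`dx_<disease>`).
#'
#' @seealso [simulateCohort()], [prsScores()], [brainMeasures()],
#'   [diagnoses()], [cohortCovariates()]
#' @export
setClass("BrainCohort", contains = "SummarizedExperiment")

setValidity("BrainCohort", function(object) {
  msg <- character()
  if (!"measure" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'measure' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("modality", "region") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'modality' and 'region'")
  else if (!all(rd$modality %in% c("SA", "CT", "subcortical", "global")))
    msg <- c(msg, "modality must be one of SA, CT, subcortical, global")
  if ("measure" %in% SummarizedExperiment::assayNames(object) &&
      anyNA(SummarizedExperiment::assay(object, "measure")))
    msg <- c(msg, "measure assay must not contain missing values")
  cd <- SummarizedExperiment::colData(object)
  prs <- grep("^prs_", colnames(cd), value = TRUE)
  for (p in prs) {
    v <- cd[[p]]
    if (anyNA(v) || !all(is.finite(v)))
      msg <- c(msg, sprintf("PRS column '%s' contains non-finite values", p))
    else if (length(v) > 1L && var(v) == 0)
      msg <- c(msg, sprintf("PRS column '%s' has zero variance", p))
  }
  if (length(msg)) msg else TRUE
})

#' Regional effect-size (Cohen's d) brain map
#'
#' An ordered mapping from atlas region labels to Cohen's d effect sizes
#' for one modality and one contrast (case-control diagnosis or high- vs
#' low-PRS median split). Regions explicitly absent from a source table
#' (e.g. a 6-of-7 subcortical map) are carried as `NA` so that downstream
#' comparisons drop them region-wise.
#'
#' @slot regions character, canonical atlas order.
#' @slot d numeric Cohen's d per region (`NA` = region absent).
#' @slot modality one of `"SA"`, `"CT"`, `"subcortical"`, `"global"`.
#' @slot contrast `"diagnosis"` or `"prs_split"`.
#' @slot nPair integer group sizes (n1, n2) when known, else empty.
#' @export
setClass("EffectSizeMap",
  representation(regions = "character", d = "numeric", modality = "character",
                 contrast = "character", nPair = "integer"),
  prototype(modality = "SA", contrast = "diagnosis", nPair = integer()))

setValidity("EffectSizeMap", function(object) {
  msg <- character()
  if (length(object@regions) == 0L) msg <- c(msg, "regions must be non-empty")
  if (length(object@regions) != length(object@d))
    msg <- c(msg, "regions and d must have equal length")
  if (anyDuplicated(object@regions))
    msg <- c(msg, "duplicate region labels")
  if (!object@contrast %in% c("diagnosis", "prs_split"))
    msg <- c(msg, "contrast must be 'diagnosis' or 'prs_split'")
  if (any(is.infinite(object@d)))
    msg <- c(msg, "effect sizes must be finite or NA")
  if (length(msg)) msg else TRUE
})

#' GWAS summary statistics for one trait
#'
#' Per-SNP allele metadata and marginal effects in the common summary-stat
#' dialect (SNP, A1, A2, freq, b, se, p, N). A1 is the effect allele.
#'
#' @slot data data.frame with columns `snp`, `a1`, `a2`, `freq`, `beta`,
#'   `se`, `p`, `n`.
#' @slot trait trait label.
#' @export
setClass("GwasSumStats",
  representation(data = "data.frame", trait = "character"),
  prototype(trait = NA_character_))

setValidity("GwasSumStats", function(object) {
  d <- object@data
  need <- c("snp", "a1", "a2", "freq", "beta", "se", "p", "n")
  miss <- setdiff(need, colnames(d))
  if (length(miss))
    return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  msg <- character()
  if (nrow(d)) {
    if (!all(d$a1 %in% c("A", "C", "G", "T")) ||
        !all(d$a2 %in% c("A", "C", "G", "T")))
      msg <- c(msg, "alleles must be A, C, G or T")
    if (any(d$a1 == d$a2)) msg <- c(msg, "a1 must differ from a2")
    if (any(d$se <= 0)) msg <- c(msg, "se must be positive")
    if (any(d$p <= 0 | d$p > 1)) msg <- c(msg, "p must lie in (0, 1]")
    if (any(d$freq <= 0 | d$freq >= 1)) msg <- c(msg, "freq must lie in (0, 1)")
    if (anyDuplicated(d$snp)) msg <- c(msg, "duplicate SNP identifiers")
  }
  if (length(msg)) msg else TRUE
})

#' Allele-harmonized exposure/outcome instrument set
#'
#' SNP effects aligned to a common effect allele across the exposure and
#' outcome studies, with palindromic and excluded-region SNPs removed.
#'
#' @slot table data.frame with columns `snp`, `bExp`, `seExp`, `pExp`,
#'   `bOut`, `seOut`, `pOut`.
#' @slot flipped SNPs whose outcome effect was negated during alignment.
#' @slot removedPalindromic removed A/T and C/G SNPs.
#' @slot removedRegion SNPs removed by the exclusion-region filter.
#' @slot removedMismatch SNPs whose alleles could not be reconciled.
#' @export
setClass("HarmonizedSet",
  representation(table = "data.frame", flipped = "character",
                 removedPalindromic = "character",
                 removedRegion = "character",
                 removedMismatch = "character"))

setValidity("HarmonizedSet", function(object) {
  need <- c("snp", "bExp", "seExp", "pExp", "bOut", "seOut", "pOut")
  miss <- setdiff(need, colnames(object@table))
  if (length(miss))
    return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  if (nrow(object@table) &&
      (any(object@table$seExp <= 0) || any(object@table$seOut <= 0)))
    return("standard errors must be positive")
  TRUE
})

#' A two-sample Mendelian randomization causal estimate
#'
#' @slot method one of `"IVW"`, `"Egger"`, `"weighted_median"`,
#'   `"weighted_mode"`, `"GSMR"`.
#' @slot beta causal effect estimate (log-OR scale for binary outcomes).
#' @slot se standard error of `beta`.
#' @slot p two-sided p-value.
#' @slot nIv number of instruments used.
#' @slot removed SNPs removed during estimation (e.g. HEIDI outliers).
#' @slot details method-specific extras (Egger intercept, bootstrap count).
#' @export
setClass("MREstimate",
  representation(method = "character", beta = "numeric", se = "numeric",
                 p = "numeric", nIv = "integer", removed = "character",
                 details = "list"),
  prototype(removed = character(), details = list()))

setValidity("MREstimate", function(object) {
  msg <- character()
  if (!object@method %in% c("IVW", "Egger", "weighted_median",
                            "weighted_mode", "GSMR"))
    msg <- c(msg, "unknown method label")
  if (length(object@nIv) != 1L || object@nIv < 1L)
    msg <- c(msg, "nIv must be a single count >= 1")
  if (length(object@se) == 1L && is.finite(object@se) && object@se <= 0)
    msg <- c(msg, "se must be positive")
  if (length(msg)) msg else TRUE
})
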