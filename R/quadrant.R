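#' Standardize to z-scores over the full sample
#'
#' @param values numeric vector (length >= 2, nonzero variance).
#' @return `(x - mean) / sd`.
#' @export
standardizeZ <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  s <- sd(values)
  if (s == 0) stop("zero variance", call. = FALSE)
  (values - mean(values)) / s
}

#' Cross-classify diagnosed cases by PRS and brain-measure sign
#'
#' Counts cases in the four quadrants of standardized (PRS, brain
#' measure) space. Values exactly 0 go to the "low" side. The target
#' quadrant for enrichment is high PRS (z > 0) with low brain measure
#' (z <= 0).
#'
#' @param prsZ,brainZ standardized vectors over the full sample.
#' @param caseFlags logical vector (>= 1 case).
#' @return 2x2 matrix of case counts, rows = PRS (high/low), columns =
#'   brain (low/high); attribute `kTarget` = cases at (PRS high, brain
#'   low).
#' @export
quadrantCounts <- function(prsZ, brainZ, caseFlags) {
  n <- length(prsZ)
  if (length(brainZ) != n || length(caseFlags) != n)
    stop("input lengths differ", call. = FALSE)
  caseFlags <- as.logical(caseFlags)
  if (!any(caseFlags)) stop("no cases", call. = FALSE)
  pHigh <- prsZ[caseFlags] > 0
  bLow <- brainZ[caseFlags] <= 0
  tab <- matrix(c(sum(pHigh & bLow), sum(!pHigh & bLow),
                  sum(pHigh & !bLow), sum(!pHigh & !bLow)),
                nrow = 2,
                dimnames = list(prs = c("high", "low"),
                                brain = c("low", "high")))
  attr(tab, "kTarget") <- tab["high", "low"]
  tab
}

#' Exact binomial quadrant enrichment test
#'
#' One-sided upper-tail test of the case count in the high-PRS /
#' low-brain quadrant against the chance rate `p0 = 0.25`:
#' `p = P(X >= k), X ~ Binomial(n, p0)`, computed exactly.
#'
#' @param kTarget cases observed in the target quadrant.
#' @param nCases total diagnosed cases.
#' @param p0 null quadrant probability.
#' @return exact one-sided p-value.
#' @examples
#' quadrantEnrichment(10, 19)
#' @export
quadrantEnrichment <- function(kTarget, nCases, p0 = 0.25) {
  if (kTarget < 0 || kTarget > nCases)
    stop("'kTarget' must lie in [0, nCases]", call. = FALSE)
  pbinom(kTarget - 1, nCases, p0, lower.tail = FALSE)
}

#' Quadrant enrichment scan over diseases and global measures
#'
#' For each disease with diagnosis flags and each global brain measure,
#' standardizes PRS and measure over the full sample, cross-classifies
#' the diagnosed cases by quadrant and applies the exact binomial
#' enrichment test.
#'
#' @param cohort a [BrainCohort-class] with `dx_` columns (see
#'   [simulateDiagnoses()]).
#' @param diseasesUsed diseases to test (default: all with diagnosis
#'   flags); diseases with zero cases are skipped with a warning.
#' @param measures global measures to test.
#' @return data.frame: `disease`, `measure`, `nCases`, `kTarget`,
#'   `proportion`, `p`.
#' @export
quadrantScan <- function(cohort, diseasesUsed = NULL,
                         measures = globalMeasureNames()) {
  stopifnot(is(cohort, "BrainCohort"))
  dx <- diagnoses(cohort)
  if (!ncol(dx)) stop("cohort has no diagnosis columns", call. = FALSE)
  diseasesUsed <- diseasesUsed %||% colnames(dx)
  glob <- brainMeasures(cohort, modality = "global")
  colnames(glob) <- sub("^global_", "", colnames(glob))
  bad <- setdiff(measures, colnames(glob))
  if (length(bad))
    stop(sprintf("unknown global measure(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  prs <- prsScores(cohort)
  rows <- list()
  for (d in diseasesUsed) {
    if (!any(dx[, d])) {
      warning(sprintf("no diagnosed cases for '%s'; skipped", d),
              call. = FALSE)
      next
    }
    pz <- standardizeZ(prs[, d])
    for (m in measures) {
      bz <- standardizeZ(glob[, m])
      tab <- quadrantCounts(pz, bz, dx[, d])
      k <- attr(tab, "kTarget")
      n <- sum(tab)
      rows[[length(rows) + 1L]] <-
        data.frame(disease = d, measure = m, nCases = n, kTarget = k,
                   proportion = k / n, p = quadrantEnrichment(k, n))
    }
  }
  do.call(rbind, rows)
}
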