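#' Simple linear association of one PRS with one prepared measure
#'
#' Ordinary least squares of the prepared measure on the standardized
#' PRS (intercept included); the two-sided p-value comes from the t
#' distribution with n - 2 degrees of freedom.
#'
#' @param prs numeric PRS vector (standardized internally).
#' @param measure numeric prepared measure, same length (>= 10).
#' @return one-row data.frame with `beta`, `se`, `t`, `p`, `n`.
#' @export
fitPrsBrain <- function(prs, measure) {
  n <- length(prs)
  if (n != length(measure)) stop("length mismatch", call. = FALSE)
  if (n < 10L) stop("need at least 10 observations", call. = FALSE)
  if (!all(is.finite(prs)) || !all(is.finite(measure)))
    stop("inputs must be finite", call. = FALSE)
  if (sd(prs) == 0) stop("zero-variance PRS", call. = FALSE)
  x <- (prs - mean(prs)) / sd(prs)
  y <- measure
  sxx <- sum(x^2) - n * mean(x)^2
  beta <- (sum(x * y) - n * mean(x) * mean(y)) / sxx
  rss <- sum((y - mean(y) - beta * (x - mean(x)))^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- beta / se
  data.frame(beta = beta, se = se, t = tval,
             p = 2 * pt(-abs(tval), df = n - 2), n = n)
}

# Vectorized slope of every column of Y on standardized x.
fitScanColumn <- function(x, Y) {
  n <- length(x)
  x <- (x - mean(x)) / sd(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  Yc <- sweep(Y, 2L, colMeans(Y))
  beta <- drop(crossprod(xc, Yc)) / sxx
  rss <- colSums(Yc^2) - beta^2 * sxx
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- beta / se
  data.frame(beta = beta, se = se, t = tval,
             p = 2 * pt(-abs(tval), df = n - 2))
}

#' Disease x region PRS association scan
#'
#' Fits, for every disease PRS and every prepared brain feature
#' (regional features plus the three global measures), the simple linear
#' association of [fitPrsBrain()]. Covariates are handled beforehand by
#' [prepareMeasures()] (two-stage residualization).
#'
#' @param cohort a [BrainCohort-class].
#' @param relative use relative (global-size-adjusted) measures?
#' @param prepared optional precomputed [prepareMeasures()] output.
#' @param diseasesUsed subset of diseases (default all).
#' @return long data.frame: `disease`, `region`, `modality`, `beta`,
#'   `se`, `t`, `p`.
#' @export
associationScan <- function(cohort, relative = FALSE, prepared = NULL,
                            diseasesUsed = NULL) {
  stopifnot(is(cohort, "BrainCohort"))
  if (is.null(prepared)) prepared <- prepareMeasures(cohort, relative)
  mods <- attr(prepared, "modality")
  prs <- prsScores(cohort)
  diseasesUsed <- diseasesUsed %||% colnames(prs)
  rd <- SummarizedExperiment::rowData(cohort)
  regionOf <- setNames(as.character(rd$region), rownames(rd))

  out <- do.call(rbind, lapply(diseasesUsed, function(d) {
    fits <- fitScanColumn(prs[, d], prepared)
    data.frame(disease = d, region = unname(regionOf[colnames(prepared)]),
               modality = unname(mods[colnames(prepared)]), fits,
               row.names = NULL)
  }))
  attr(out, "relative") <- attr(prepared, "relative")
  out
}

#' Annotate association results with nested significance tiers
#'
#' Three-tier Bonferroni annotation against the effective number of
#' independent phenotypes: `nominal` iff p < 0.05; `disease_wise` iff
#' p < 0.05 / t_e; `study_wise` iff p < 0.05 / (t_e * nDiseases). Tiers
#' are nested; the strongest attained tier is reported. With t_e = 22
#' cortical and 7 subcortical effective phenotypes and 13 diseases the
#' study-wise thresholds are 1.7e-4 and 5.5e-4.
#'
#' @param results data.frame from [associationScan()] (needs `p`, and
#'   `modality` when `tE` is a named per-modality vector).
#' @param tE effective test count (scalar, or named vector by modality;
#'   >= 1).
#' @param nDiseases number of diseases in the scan family (>= 1).
#' @param alpha base significance level.
#' @return `results` with an ordered factor column `tier` (levels
#'   `none < nominal < disease_wise < study_wise`).
#' @export
significanceTiers <- function(results, tE, nDiseases = 13, alpha = 0.05) {
  if (any(tE < 1)) stop("'tE' must be >= 1", call. = FALSE)
  if (nDiseases < 1) stop("'nDiseases' must be >= 1", call. = FALSE)
  teVec <- if (length(tE) == 1L && is.null(names(tE))) {
    rep(unname(tE), nrow(results))
  } else {
    if (!"modality" %in% colnames(results))
      stop("per-modality 'tE' needs a 'modality' column", call. = FALSE)
    miss <- setdiff(unique(results$modality), names(tE))
    if (length(miss))
      stop(sprintf("'tE' missing modalities: %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    unname(tE[results$modality])
  }
  p <- results$p
  tier <- rep("none", length(p))
  tier[p < alpha] <- "nominal"
  tier[p < alpha / teVec] <- "disease_wise"
  tier[p < alpha / (teVec * nDiseases)] <- "study_wise"
  results$tier <- factor(tier, levels = c("none", "nominal", "disease_wise",
                                          "study_wise"), ordered = TRUE)
  results
}

#' Bonferroni thresholds for the three annotation tiers
#'
#' @param tE effective number of independent phenotypes.
#' @param nDiseases diseases in the family.
#' @param alpha base level.
#' @return named numeric: `nominal`, `disease_wise`, `study_wise`.
#' @examples
#' tierThresholds(22, 13)["study_wise"]  # 0.05/286 = 1.7e-4
#' @export
tierThresholds <- function(tE, nDiseases = 13, alpha = 0.05) {
  c(nominal = alpha, disease_wise = alpha / tE,
    study_wise = alpha / (tE * nDiseases))
}
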