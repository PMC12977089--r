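#' Cohen's d from a two-sample t statistic
#'
#' `d = t * sqrt(1/n1 + 1/n2)`, the standard conversion for a pooled-SD
#' two-sample comparison.
#'
#' @param t t statistic for the group difference.
#' @param n1,n2 group sizes (>= 2).
#' @return Cohen's d (vectorized over `t`).
#' @export
cohenDFromT <- function(t, n1, n2) {
  if (any(n1 < 2) || any(n2 < 2)) stop("group sizes must be >= 2",
                                       call. = FALSE)
  t * sqrt(1 / n1 + 1 / n2)
}

#' Median split of PRS into high- and low-risk groups
#'
#' High risk = strictly above the sample median; values at or below the
#' median (including ties at the median) go to the low group.
#'
#' @param prs numeric vector (length >= 4, non-constant).
#' @return factor with levels `low`, `high`.
#' @export
medianSplit <- function(prs) {
  if (length(prs) < 4L) stop("need at least 4 values", call. = FALSE)
  if (max(prs) == min(prs)) stop("constant PRS cannot be split",
                                 call. = FALSE)
  factor(ifelse(prs > median(prs), "high", "low"),
         levels = c("low", "high"))
}

#' Cohen's d between two groups (pooled SD)
#'
#' `d = (mean(xHigh) - mean(xLow)) / sPooled` with
#' `sPooled^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`.
#'
#' @param xHigh,xLow numeric vectors, each length >= 2.
#' @return Cohen's d.
#' @export
cohenD <- function(xHigh, xLow) {
  n1 <- length(xHigh); n2 <- length(xLow)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 values",
                               call. = FALSE)
  sp2 <- ((n1 - 1) * var(xHigh) + (n2 - 1) * var(xLow)) / (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled SD", call. = FALSE)
  (mean(xHigh) - mean(xLow)) / sqrt(sp2)
}

#' Genetic-risk effect-size map from a median split on PRS
#'
#' Dichotomizes one disease PRS at the median and computes the pooled
#' Cohen's d (high minus low) of every prepared regional measure in the
#' requested modality, producing a genetic-risk analogue of a
#' case-control brain map.
#'
#' @param cohort a [BrainCohort-class].
#' @param disease disease label (must have a PRS column).
#' @param modality regional modality (`"SA"`, `"CT"` or `"subcortical"`).
#' @param prepared optional [prepareMeasures()] output to reuse.
#' @param relative use global-size-adjusted measures when `prepared` is
#'   not supplied?
#' @return an [EffectSizeMap-class] with contrast `"prs_split"`.
#' @export
prsEffectMap <- function(cohort, disease, modality, prepared = NULL,
                         relative = FALSE) {
  stopifnot(is(cohort, "BrainCohort"))
  if (!disease %in% diseases(cohort))
    stop(sprintf("no PRS column for disease '%s'", disease), call. = FALSE)
  if (is.null(prepared)) prepared <- prepareMeasures(cohort, relative)
  mods <- attr(prepared, "modality")
  cols <- names(mods)[mods == modality]
  if (!length(cols))
    stop(sprintf("no features of modality '%s'", modality), call. = FALSE)
  grp <- medianSplit(prsScores(cohort)[, disease])
  hi <- grp == "high"
  d <- vapply(cols, function(cl)
    cohenD(prepared[hi, cl], prepared[!hi, cl]), numeric(1))
  rd <- SummarizedExperiment::rowData(cohort)
  regionOf <- setNames(as.character(rd$region), rownames(rd))
  effectSizeMap(unname(regionOf[cols]), unname(d), modality = modality,
                contrast = "prs_split",
                nPair = c(sum(hi), sum(!hi)))
}

#' Crosswalk an effect-size map into a target atlas
#'
#' Converts a map between parcellations by weighted averaging: each
#' target region's d is the weighted mean of its source regions' d, the
#' weights of each target region summing to 1.
#'
#' @param map an [EffectSizeMap-class] in the source atlas.
#' @param weights data.frame with columns `target`, `source`, `weight`.
#' @return an [EffectSizeMap-class] over the target regions.
#' @export
crosswalkMap <- function(map, weights) {
  stopifnot(is(map, "EffectSizeMap"))
  need <- c("target", "source", "weight")
  if (!all(need %in% colnames(weights)))
    stop("'weights' needs columns target, source, weight", call. = FALSE)
  badSrc <- setdiff(unique(weights$source), regions(map))
  if (length(badSrc))
    stop(sprintf("unknown source region(s): %s",
                 paste(badSrc, collapse = ", ")), call. = FALSE)
  d <- effectSizes(map)
  targets <- unique(weights$target)
  dOut <- vapply(targets, function(tr) {
    w <- weights[weights$target == tr, ]
    tot <- sum(w$weight)
    if (tot == 0) stop(sprintf("target region '%s' has zero total weight",
                               tr), call. = FALSE)
    if (abs(tot - 1) > 1e-6)
      stop(sprintf("weights for target '%s' sum to %.4f, not 1", tr, tot),
           call. = FALSE)
    sum(w$weight * d[w$source])
  }, numeric(1))
  effectSizeMap(targets, unname(dOut), modality = modality(map),
                contrast = contrastType(map))
}

# Align two maps on shared, non-absent regions.
alignMaps <- function(mapA, mapB) {
  shared <- intersect(regions(mapA), regions(mapB))
  if (!length(shared)) stop("maps share no regions", call. = FALSE)
  da <- effectSizes(mapA)[shared]
  db <- effectSizes(mapB)[shared]
  keep <- !is.na(da) & !is.na(db)
  list(da = da[keep], db = db[keep], regions = shared[keep])
}

#' Sign concordance of two effect-size maps
#'
#' Counts regions where the two maps agree in effect direction and tests
#' the count against Binomial(n, 1/2) with the exact one-sided upper
#' tail `P(X >= k)`. Regions with an exactly zero d in either map are
#' excluded from n.
#'
#' @param mapA,mapB [EffectSizeMap-class] objects sharing regions.
#' @return list: `k`, `n`, `proportion`, `pSign`.
#' @examples
#' m <- effectSizeMap(letters[1:6], c(-1, -2, 1, 2, 3, -4))
#' signConcordance(m, m)  # k = n = 6, p = 0.5^6
#' @export
signConcordance <- function(mapA, mapB) {
  al <- alignMaps(mapA, mapB)
  nz <- al$da != 0 & al$db != 0
  da <- al$da[nz]; db <- al$db[nz]
  n <- length(da)
  if (n == 0L) stop("no comparable regions with nonzero effects",
                    call. = FALSE)
  k <- sum(da * db > 0)
  list(k = k, n = n, proportion = k / n,
       pSign = pbinom(k - 1L, n, 0.5, lower.tail = FALSE))
}

#' Large-sample 95% interval half-width for a correlation
#'
#' `1.96 * sqrt((1 - r^2) / (n - 2))`, the half-width printed alongside
#' spatial correlations of regional maps.
#'
#' @param r Pearson correlation.
#' @param n number of regions (> 2).
#' @return half-width (vectorized).
#' @examples
#' correlationHalfwidth(0.67, 34)  # 0.26
#' @export
correlationHalfwidth <- function(r, n) {
  if (any(n <= 2)) stop("'n' must exceed 2", call. = FALSE)
  1.96 * sqrt((1 - r^2) / (n - 2))
}

# All permutations of seq_len(n) as a matrix (n! rows); n <= 8 in use.
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Spatial correlation of two maps with a permutation null
#'
#' Pearson correlation of the shared-region d vectors, the large-sample
#' 95% interval half-width `1.96 * sqrt((1 - r^2) / (n - 2))`, and a
#' two-sided permutation p-value from uniformly random region-label
#' permutations of one map. For n <= 8 all n! permutations are
#' enumerated exactly; otherwise `pPerm = (#{|r*| >= |r|} + 1) /
#' (nPerm + 1)`.
#'
#' @param mapA,mapB [EffectSizeMap-class] objects with >= 3 shared
#'   regions.
#' @param nPerm permutation count (default 10000); 0 gives `pPerm = NA`.
#' @param seed integer seed or `NULL`.
#' @return list: `r`, `halfwidth`, `pPerm`, `n`, `exact` (enumerated?).
#' @export
spatialCorrelation <- function(mapA, mapB, nPerm = 10000, seed = NULL) {
  al <- alignMaps(mapA, mapB)
  n <- length(al$da)
  if (n < 3L) stop("need at least 3 shared regions", call. = FALSE)
  if (sd(al$da) == 0 || sd(al$db) == 0)
    stop("zero variance in a map", call. = FALSE)
  r <- cor(al$da, al$db)
  halfwidth <- correlationHalfwidth(r, n)
  if (n <= 8L) {
    perms <- allPermutations(n)
    rStar <- apply(perms, 1L, function(pp) cor(al$da, al$db[pp]))
    pPerm <- mean(abs(rStar) >= abs(r) - 1e-12)
    exact <- TRUE
  } else if (nPerm > 0) {
    pPerm <- withSeed(seed, {
      hits <- sum(vapply(seq_len(nPerm), function(i)
        abs(cor(al$da, sample(al$db))) >= abs(r) - 1e-12, logical(1)))
      (hits + 1) / (nPerm + 1)
    })
    exact <- FALSE
  } else {
    pPerm <- NA_real_
    exact <- FALSE
  }
  list(r = r, halfwidth = halfwidth, pPerm = pPerm, n = n, exact = exact)
}

#' Compare genetic-risk maps against case-control maps
#'
#' Table-style comparison across disorders within one modality: sign
#' concordance with exact binomial p, spatial correlation with
#' permutation p, and Benjamini-Hochberg adjustment of the permutation
#' p-values across the disorders of the modality family.
#'
#' @param riskMaps named list of [EffectSizeMap-class] (genetic risk),
#'   keyed by disorder.
#' @param diagMaps named list of [EffectSizeMap-class] (case-control),
#'   same names.
#' @param nPerm permutations for the correlation null.
#' @param seed integer seed or `NULL`.
#' @return data.frame: `disorder`, `k`, `n`, `proportion`, `pSign`, `r`,
#'   `halfwidth`, `pPerm`, `qFdr`.
#' @export
compareMaps <- function(riskMaps, diagMaps, nPerm = 10000, seed = NULL) {
  common <- intersect(names(riskMaps), names(diagMaps))
  if (!length(common)) stop("no shared disorders", call. = FALSE)
  rows <- lapply(seq_along(common), function(i) {
    dis <- common[i]
    sc <- signConcordance(riskMaps[[dis]], diagMaps[[dis]])
    pc <- spatialCorrelation(riskMaps[[dis]], diagMaps[[dis]],
                             nPerm = nPerm, seed = childSeed(seed, i))
    data.frame(disorder = dis, k = sc$k, n = sc$n,
               proportion = sc$proportion, pSign = sc$pSign, r = pc$r,
               halfwidth = pc$halfwidth, pPerm = pc$pPerm)
  })
  out <- do.call(rbind, rows)
  out$qFdr <- p.adjust(out$pPerm, method = "BH")
  out
}
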