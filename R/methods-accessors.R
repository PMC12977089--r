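# Accessor and show methods for the S4 containers.

#' @rdname prsbrainmap-accessors
#' @export
setMethod("regions", "EffectSizeMap", function(x) x@regions)

#' @rdname prsbrainmap-accessors
#' @export
setMethod("effectSizes", "EffectSizeMap", function(x)
  setNames(x@d, x@regions))

#' @rdname prsbrainmap-accessors
#' @export
setMethod("modality", "EffectSizeMap", function(x) x@modality)

#' @rdname prsbrainmap-accessors
#' @export
setMethod("contrastType", "EffectSizeMap", function(x) x@contrast)

#' @export
setMethod("length", "EffectSizeMap", function(x) length(x@regions))

setMethod("show", "EffectSizeMap", function(object) {
  d <- object@d
  cat(sprintf("EffectSizeMap: %d region(s), modality %s, contrast %s\n",
              length(d), object@modality, object@contrast))
  cat(sprintf("  d range [%.3f, %.3f], %d absent\n",
              suppressWarnings(min(d, na.rm = TRUE)),
              suppressWarnings(max(d, na.rm = TRUE)), sum(is.na(d))))
})

#' @rdname prsbrainmap-accessors
#' @export
setMethod("sumstats", "GwasSumStats", function(x) x@data)

#' @rdname prsbrainmap-accessors
#' @export
setMethod("traitName", "GwasSumStats", function(x) x@trait)

#' @export
setMethod("nrow", "GwasSumStats", function(x) nrow(x@data))

setMethod("show", "GwasSumStats", function(object) {
  cat(sprintf("GwasSumStats: %d SNP(s), trait %s\n", nrow(object@data),
              object@trait))
  if (nrow(object@data))
    cat(sprintf("  min p = %.3g, median N = %.0f\n", min(object@data$p),
                median(object@data$n)))
})

#' @rdname prsbrainmap-accessors
#' @export
setMethod("instrumentTable", "HarmonizedSet", function(x) x@table)

#' @rdname prsbrainmap-accessors
#' @export
setMethod("nInstruments", "HarmonizedSet", function(x) nrow(x@table))

#' @rdname prsbrainmap-accessors
#' @export
setMethod("removedSnps", "HarmonizedSet", function(x)
  c(x@removedPalindromic, x@removedRegion, x@removedMismatch))

setMethod("show", "HarmonizedSet", function(object) {
  cat(sprintf(paste0("HarmonizedSet: %d SNP(s) aligned ",
                     "(%d flipped; removed: %d palindromic, %d in excluded",
                     " regions, %d allele mismatch)\n"),
              nrow(object@table), length(object@flipped),
              length(object@removedPalindromic), length(object@removedRegion),
              length(object@removedMismatch)))
})

#' @rdname prsbrainmap-accessors
#' @export
setMethod("estimate", "MREstimate", function(x) x@beta)

#' @rdname prsbrainmap-accessors
#' @export
setMethod("stdError", "MREstimate", function(x) x@se)

#' @rdname prsbrainmap-accessors
#' @export
setMethod("pValue", "MREstimate", function(x) x@p)

#' @rdname prsbrainmap-accessors
#' @export
setMethod("oddsRatio", "MREstimate", function(x) exp(x@beta))

#' @rdname prsbrainmap-accessors
#' @export
setMethod("oddsRatioCI", "MREstimate", function(x)
  exp(x@beta + c(-1, 1) * 1.96 * x@se))

#' @rdname prsbrainmap-accessors
#' @export
setMethod("nInstruments", "MREstimate", function(x) x@nIv)

#' @rdname prsbrainmap-accessors
#' @export
setMethod("removedSnps", "MREstimate", function(x) x@removed)

#' @rdname prsbrainmap-accessors
#' @export
setMethod("mrMethod", "MREstimate", function(x) x@method)

setMethod("show", "MREstimate", function(object) {
  ci <- oddsRatioCI(object)
  cat(sprintf("MREstimate [%s]: beta = %.4f (se %.4f), p = %.3g\n",
              object@method, object@beta, object@se, object@p))
  cat(sprintf("  OR = %.3f, 95%% CI [%.3f, %.3f]; %d IV(s) used, %d removed\n",
              oddsRatio(object), ci[1], ci[2], object@nIv,
              length(object@removed)))
})

#' @rdname prsbrainmap-accessors
#' @export
setMethod("prsScores", "BrainCohort", function(x) {
  cd <- SummarizedExperiment::colData(x)
  cols <- grep("^prs_", colnames(cd), value = TRUE)
  m <- as.matrix(as.data.frame(cd[, cols, drop = FALSE]))
  colnames(m) <- sub("^prs_", "", cols)
  rownames(m) <- rownames(cd)
  m
})

#' @rdname prsbrainmap-accessors
#' @export
setMethod("diagnoses", "BrainCohort", function(x) {
  cd <- SummarizedExperiment::colData(x)
  cols <- grep("^dx_", colnames(cd), value = TRUE)
  m <- as.matrix(as.data.frame(cd[, cols, drop = FALSE]))
  colnames(m) <- sub("^dx_", "", cols)
  rownames(m) <- rownames(cd)
  m
})

#' @rdname prsbrainmap-accessors
#' @export
setMethod("cohortCovariates", "BrainCohort", function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  keep <- c("age", "sex", "site", "euler", grep("^pc", colnames(cd),
                                                value = TRUE))
  cd[, intersect(keep, colnames(cd)), drop = FALSE]
})

#' @rdname prsbrainmap-accessors
#' @param modality optional modality filter (`"SA"`, `"CT"`,
#'   `"subcortical"`, `"global"`).
#' @export
setMethod("brainMeasures", "BrainCohort", function(x, modality = NULL) {
  m <- SummarizedExperiment::assay(x, "measure")
  if (!is.null(modality)) {
    keep <- SummarizedExperiment::rowData(x)$modality %in% modality
    m <- m[keep, , drop = FALSE]
  }
  t(m)
})

#' @rdname prsbrainmap-accessors
#' @export
setMethod("diseases", "BrainCohort", function(x)
  sub("^prs_", "", grep("^prs_",
      colnames(SummarizedExperiment::colData(x)), value = TRUE)))

setMethod("show", "BrainCohort", function(object) {
  callNextMethod()
  cat(sprintf("diseases(%d): %s\n", length(diseases(object)),
              paste(head(diseases(object), 6), collapse = " ")))
})
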