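#' Residualize brain measures on covariates
#'
#' Regresses every measure column on the covariates (intercept added;
#' factors dummy-coded) and returns the residual matrix. Covariates must
#' be full rank after coding; collinear columns are named in the error.
#'
#' @param measures numeric matrix, participants x measures (no missing
#'   values).
#' @param covariates data.frame of covariates, or `NULL` for
#'   intercept-only (mean-centering).
#' @return residual matrix with attributes `covariates` (design column
#'   names) and `relative` (`FALSE`).
#' @export
residualize <- function(measures, covariates = NULL) {
  measures <- as.matrix(measures)
  if (anyNA(measures)) stop("'measures' contains missing values",
                            call. = FALSE)
  n <- nrow(measures)
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n)
      stop("'covariates' and 'measures' disagree on participant count",
           call. = FALSE)
    if (anyNA(covariates)) stop("'covariates' contains missing values",
                                call. = FALSE)
    X <- stats::model.matrix(~ ., data = covariates)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf("covariates are rank deficient; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  res <- qr.resid(qrX, measures)
  dimnames(res) <- dimnames(measures)
  attr(res, "covariates") <- colnames(X)
  attr(res, "relative") <- FALSE
  res
}

#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles of Blom-offset ranks,
#' `qnorm((rank - 3/8) / (n + 1/4))`, ties receiving average ranks. The
#' transform is order-preserving and its output is an exact monotone
#' function of the ranks.
#'
#' @param values numeric vector (length >= 3) or matrix (applied
#'   column-wise).
#' @return transformed values, same shape.
#' @examples
#' inverseNormal(c(5, 1, 3))  # middle value maps to 0
#' @export
inverseNormal <- function(values) {
  if (is.matrix(values)) {
    out <- apply(values, 2L, inverseNormal)
    dimnames(out) <- dimnames(values)
    return(out)
  }
  n <- length(values)
  if (n < 3L) stop("need at least 3 values", call. = FALSE)
  if (anyNA(values)) stop("missing values not allowed", call. = FALSE)
  if (max(values) == min(values))
    stop("constant input: ranks undefined", call. = FALSE)
  r <- rank(values, ties.method = "average")
  qnorm((r - 3 / 8) / (n + 1 / 4))
}

#' Adjust regional measures for a matching global measure
#'
#' Residualizes each (already covariate-residualized) regional column
#' additionally on the matching global measure, producing "relative"
#' measures in which a shared global-size driver is removed.
#'
#' @param measures residual matrix, participants x regions.
#' @param globalMeasure numeric vector, the matching covariate-adjusted
#'   global measure (total SA for SA regions, mean CT for CT, ICV for
#'   subcortical volumes).
#' @return residual matrix with attribute `relative = TRUE`.
#' @export
makeRelative <- function(measures, globalMeasure) {
  measures <- as.matrix(measures)
  globalMeasure <- as.numeric(globalMeasure)
  if (length(globalMeasure) != nrow(measures))
    stop("'globalMeasure' length must equal the participant count",
         call. = FALSE)
  if (sd(globalMeasure) == 0)
    stop("'globalMeasure' is constant", call. = FALSE)
  out <- residualize(measures, data.frame(global = globalMeasure))
  attr(out, "relative") <- TRUE
  out
}

#' Prepare cohort brain measures for association scans
#'
#' Two-stage preparation mirroring standard imaging-genetics practice:
#' (1) residualize every measure on age, sex, scanner site, the
#' scan-quality proxy and the 10 genetic PCs; (2) optionally residualize
#' each regional measure on its covariate-adjusted matching global
#' measure (`relative = TRUE`); (3) apply the rank-based inverse normal
#' transformation column-wise.
#'
#' @param cohort a [BrainCohort-class].
#' @param relative adjust regional measures for the matching global
#'   measure?
#' @param int apply the inverse normal transformation (default `TRUE`)?
#' @return matrix participants x features (regional features first, then
#'   the three global measures), z-units, with attributes `modality`
#'   (per-column modality), `covariates` and `relative`.
#' @export
prepareMeasures <- function(cohort, relative = FALSE, int = TRUE) {
  stopifnot(is(cohort, "BrainCohort"))
  meas <- brainMeasures(cohort)
  rd <- SummarizedExperiment::rowData(cohort)
  covs <- cohortCovariates(cohort)
  res <- residualize(meas, covs)
  mods <- as.character(rd$modality)

  if (relative) {
    for (m in intersect(c("SA", "CT", "subcortical"), unique(mods))) {
      gName <- paste0("global_", matchingGlobal(m))
      if (!gName %in% colnames(res))
        stop(sprintf("global measure '%s' absent; cannot form relative %s",
                     gName, m), call. = FALSE)
      idx <- which(mods == m)
      res[, idx] <- makeRelative(res[, idx, drop = FALSE], res[, gName])
    }
  }
  out <- if (int) inverseNormal(res) else res
  attr(out, "modality") <- setNames(mods, colnames(meas))
  attr(out, "covariates") <- attr(res, "covariates")
  attr(out, "relative") <- relative
  out
}

#' Effective number of independent phenotypes
#'
#' Eigenvalue-based effective-test count for a phenotype correlation
#' matrix, in the matSpD tradition. The Li-Ji estimate is
#' `sum_i [ 1(lambda_i >= 1) + (lambda_i - floor(lambda_i)) ]`; the
#' Nyholt estimate is `1 + (M - 1) (1 - Var(lambda) / M)`. Both are
#' reported; Li-Ji is the default `te`.
#'
#' @param corrMatrix symmetric correlation matrix (unit diagonal,
#'   positive semidefinite within tolerance 1e-6).
#' @param method which estimate populates `te`.
#' @return an object of class `"EffectiveTests"`: list with `te`,
#'   `teLiJi`, `teNyholt`, `eigenvalues`, `m`, `method`.
#' @examples
#' effectiveTests(diag(10))$te  # 10
#' @export
effectiveTests <- function(corrMatrix, method = c("liJi", "nyholt")) {
  method <- match.arg(method)
  corrMatrix <- as.matrix(corrMatrix)
  m <- nrow(corrMatrix)
  if (m != ncol(corrMatrix) || !isSymmetric(unname(corrMatrix),
                                            tol = 1e-8))
    stop("'corrMatrix' must be symmetric", call. = FALSE)
  if (any(abs(diag(corrMatrix) - 1) > 1e-6))
    stop("'corrMatrix' must have unit diagonal", call. = FALSE)
  lam <- eigen(corrMatrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(lam) < -1e-6)
    stop("'corrMatrix' is not positive semidefinite", call. = FALSE)
  lam <- pmax(lam, 0)
  # guard the floor against eigenvalues a few ulp below an integer
  lamR <- round(lam, 10)
  teLiJi <- sum((lamR >= 1) + pmax(lamR - floor(lamR), 0))
  teNyholt <- if (m == 1L) 1 else 1 + (m - 1) * (1 - var(lam) / m)
  out <- list(te = if (method == "liJi") teLiJi else teNyholt,
              teLiJi = teLiJi, teNyholt = teNyholt,
              eigenvalues = lam, m = m, method = method)
  class(out) <- "EffectiveTests"
  out
}

#' @export
print.EffectiveTests <- function(x, ...) {
  cat(sprintf("Effective number of independent phenotypes (M = %d)\n", x$m))
  cat(sprintf("  Li-Ji: %.3f   Nyholt: %.3f   (default: %s)\n",
              x$teLiJi, x$teNyholt, x$method))
  invisible(x)
}
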