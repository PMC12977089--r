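#' Pipeline configuration
#'
#' Builds and validates the configuration consumed by [runPipeline()].
#' Unknown keys are rejected. With all paths `NULL` the pipeline runs on
#' synthetic data with known ground truth: a cohort with planted
#' negative PRS effects for the disorders carrying published
#' case-control maps, all-negative diagnosis maps, a multi-trait GWAS
#' panel with forward brain-to-disorder causal effects, and
#' liability-model diagnoses.
#'
#' @param cohortPath optional cohort TSV ([readCohort()]).
#' @param effectMapDir optional directory of `<disorder>.csv` diagnosis
#'   maps ([readEffectMap()]).
#' @param gwasDir optional directory of `<trait>.tsv` GWAS summary
#'   statistics for the MR stage (brain measures and disorders).
#' @param crosswalkPath optional crosswalk CSV applied to loaded
#'   diagnosis maps.
#' @param excludeRegionsPath optional BED-like exclusion file for MR.
#' @param nParticipants synthetic cohort size.
#' @param diseases PRS disease panel.
#' @param mapped disorders compared against case-control maps.
#' @param mrDisorders disorders entering the MR stage.
#' @param mapModality modality of the compared maps.
#' @param relative use global-size-adjusted measures in the scan?
#' @param prsEffectSize planted standardized regional effect for mapped
#'   disorders (negative = risk reduces the measure).
#' @param prsGlobalEffectSize planted PRS effect on the global factor.
#' @param dxPrevalence synthetic diagnosis prevalence.
#' @param nPerm permutations for the correlation null (0 = report `NA`).
#' @param mrMethods MR estimators per cell.
#' @param instrumentP,heidiP,nBoot MR stage tuning.
#' @param seed master seed; every stochastic stage derives its stream
#'   from it.
#' @param outDir output directory.
#' @return a validated list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(cohortPath = NULL, effectMapDir = NULL,
                           gwasDir = NULL, crosswalkPath = NULL,
                           excludeRegionsPath = NULL,
                           nParticipants = 2000,
                           diseases = disorderPanel(),
                           mapped = mappedDisorders(),
                           mrDisorders = c("ADHD", "SZ", "PD"),
                           mapModality = "SA", relative = FALSE,
                           prsEffectSize = -0.03,
                           prsGlobalEffectSize = -0.05,
                           dxPrevalence = 0.02, nPerm = 1000,
                           mrMethods = c("IVW", "GSMR"),
                           instrumentP = 5e-8, heidiP = 0.01,
                           nBoot = 200, seed = 1, outDir = "results") {
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys mirror the arguments of [pipelineConfig()]; unknown keys are an
#' error.
#'
#' @param path YAML (or JSON) file.
#' @return a `"PipelineConfig"` list.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  do.call(pipelineConfig, raw)
}

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Chains all stages on synthetic or user-supplied tables: cohort
#' preparation and PRS association scan with effective-test tiers,
#' genetic-risk vs diagnosis map comparison (sign concordance,
#' permutation correlation, FDR), bidirectional MR across global
#' measures and disorders, and the quadrant enrichment scan. Writes
#' `association.tsv`, `concordance.tsv`, `mr.tsv`, `quadrant.tsv` and a
#' machine-readable `manifest.json` (seed, thresholds, effective test
#' counts, package version) into `config$outDir`. Statistical outputs
#' are byte-identical across reruns with the same configuration.
#'
#' @param config a `"PipelineConfig"` from [pipelineConfig()] /
#'   [readPipelineConfig()].
#' @return invisibly, a list with the four result data.frames and the
#'   manifest.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (!inherits(config, "PipelineConfig"))
    stop("'config' must come from pipelineConfig()", call. = FALSE)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  cohort <- stageTry("cohort", {
    if (!is.null(config$cohortPath)) {
      readCohort(config$cohortPath)
    } else {
      regionsList <- list(SA = dkCorticalRegions(),
                          CT = dkCorticalRegions(),
                          subcortical = asegSubcorticalRegions())
      featIds <- paste(rep(names(regionsList), lengths(regionsList)),
                       unlist(regionsList, use.names = FALSE), sep = "_")
      eff <- matrix(0, length(config$diseases), length(featIds),
                    dimnames = list(config$diseases, featIds))
      planted <- intersect(config$mapped, config$diseases)
      eff[planted, grep(paste0("^", config$mapModality, "_"), featIds)] <-
        config$prsEffectSize
      gl <- setNames(rep(0, length(config$diseases)), config$diseases)
      gl[planted] <- config$prsGlobalEffectSize
      bc <- simulateCohort(nParticipants = config$nParticipants,
                           diseases = config$diseases,
                           regions = regionsList, prsEffect = eff,
                           prsGlobalEffect = gl,
                           seed = childSeed(seed, 1))
      simulateDiagnoses(bc, prevalence = config$dxPrevalence,
                        seed = childSeed(seed, 2))
    }
  })

  scan <- stageTry("association", {
    prepared <- prepareMeasures(cohort, relative = config$relative)
    mods <- attr(prepared, "modality")
    tE <- vapply(unique(mods), function(m) {
      cols <- names(mods)[mods == m]
      if (length(cols) == 1L) return(1)
      effectiveTests(cor(prepared[, cols, drop = FALSE]))$te
    }, numeric(1))
    res <- associationScan(cohort, prepared = prepared)
    res <- significanceTiers(res, tE = tE,
                             nDiseases = length(config$diseases))
    attr(res, "tE") <- tE
    attr(res, "prepared") <- prepared
    res
  })
  prepared <- attr(scan, "prepared")
  tE <- attr(scan, "tE")

  concordance <- stageTry("map comparison", {
    mapped <- config$mapped
    riskMaps <- lapply(mapped, function(d)
      prsEffectMap(cohort, d, config$mapModality, prepared = prepared))
    names(riskMaps) <- mapped
    atlas <- regions(riskMaps[[1]])
    diagMaps <- if (!is.null(config$effectMapDir)) {
      cw <- if (!is.null(config$crosswalkPath))
        readCrosswalk(config$crosswalkPath) else NULL
      ms <- lapply(mapped, function(d) {
        m <- readEffectMap(file.path(config$effectMapDir,
                                     paste0(d, ".csv")),
                           atlas = if (is.null(cw)) atlas else NULL,
                           modality = config$mapModality)
        if (is.null(cw)) m else crosswalkMap(m, cw)
      })
      names(ms) <- mapped
      ms
    } else {
      ms <- lapply(seq_along(mapped), function(i)
        simulateEffectMap(atlas, pattern = "all-negative",
                          modality = config$mapModality,
                          seed = childSeed(seed, 100 + i)))
      names(ms) <- mapped
      ms
    }
    compareMaps(riskMaps, diagMaps, nPerm = config$nPerm,
                seed = childSeed(seed, 3))
  })

  mr <- stageTry("mendelian randomization", {
    brainTraits <- globalMeasureNames()
    if (!is.null(config$gwasDir)) {
      readTrait <- function(t)
        readGwasSumstats(file.path(config$gwasDir, paste0(t, ".tsv")),
                         trait = t)
      brainGwas <- setNames(lapply(brainTraits, readTrait), brainTraits)
      disorderGwas <- setNames(lapply(config$mrDisorders, readTrait),
                               config$mrDisorders)
    } else {
      traits <- c(brainTraits, config$mrDisorders)
      cm <- matrix(0, length(traits), length(traits),
                   dimnames = list(traits, traits))
      cm[brainTraits, config$mrDisorders] <- 0.15   # forward-only
      panel <- simulateGwasPanel(traits, nInstrumentsPerTrait = 30,
                                 causalMatrix = cm,
                                 sampleSizes = 100000,
                                 seed = childSeed(seed, 4))
      brainGwas <- panel[brainTraits]
      disorderGwas <- panel[config$mrDisorders]
    }
    excl <- if (!is.null(config$excludeRegionsPath))
      readRegionFile(config$excludeRegionsPath) else NULL
    runBidirectionalMr(brainGwas, disorderGwas,
                       methods = config$mrMethods,
                       pThreshold = config$instrumentP,
                       heidiPThreshold = config$heidiP,
                       nBoot = config$nBoot, excludeRegions = excl,
                       nDiseases = length(config$diseases),
                       seed = childSeed(seed, 5))
  })

  quadrant <- stageTry("quadrant", {
    if (ncol(diagnoses(cohort)) == 0L) {
      data.frame()
    } else {
      suppressWarnings(quadrantScan(cohort,
                                    diseasesUsed = config$mrDisorders))
    }
  })

  manifest <- list(
    package = "prsbrainmap",
    version = as.character(packageVersion("prsbrainmap")),
    seed = seed,
    nParticipants = if (is.null(config$cohortPath))
      config$nParticipants else ncol(cohort),
    relative = config$relative,
    nPerm = config$nPerm,
    effectiveTests = as.list(round(tE, 4)),
    tierThresholds = lapply(as.list(round(tE, 4)), function(t)
      as.list(tierThresholds(t, length(config$diseases)))),
    mr = list(methods = config$mrMethods, instrumentP = config$instrumentP,
              heidiP = config$heidiP),
    outputs = c("association.tsv", "concordance.tsv", "mr.tsv",
                "quadrant.tsv"))

  scanOut <- scan
  attr(scanOut, "prepared") <- NULL
  writeTsv(scanOut, file.path(config$outDir, "association.tsv"))
  writeTsv(concordance, file.path(config$outDir, "concordance.tsv"))
  writeTsv(mr, file.path(config$outDir, "mr.tsv"))
  writeTsv(quadrant, file.path(config$outDir, "quadrant.tsv"))
  jsonlite::write_json(manifest,
                       file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(association = scanOut, concordance = concordance,
                 mr = mr, quadrant = quadrant, manifest = manifest))
}
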