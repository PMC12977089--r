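# Readers and writers for the plain-text exchange formats: cohort TSV,
# GWAS summary-stat TSV, effect-size map CSV, crosswalk CSV, BED-like
# region exclusion files.

#' Write / read a cohort as tab-delimited text
#'
#' One row per participant: `id`, covariates, `prs_*`, `dx_*`, then one
#' column per brain feature (named `<modality>_<region>`, globals
#' `global_<name>`). Write-then-read is the identity on the data model.
#'
#' @param cohort a [BrainCohort-class].
#' @param path file path.
#' @return `readCohort` returns a [BrainCohort-class];
#'   `writeCohort` returns `path` invisibly.
#' @export
writeCohort <- function(cohort, path) {
  stopifnot(is(cohort, "BrainCohort"))
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  meas <- brainMeasures(cohort)
  df <- cbind(cd, as.data.frame(meas))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% colnames(df)) stop("cohort file lacks an 'id' column",
                                    call. = FALSE)
  measCols <- grep("^(SA|CT|subcortical|global)_", colnames(df),
                   value = TRUE)
  if (!length(measCols)) stop("cohort file has no brain measure columns",
                              call. = FALSE)
  metaCols <- setdiff(colnames(df), measCols)
  measure <- t(as.matrix(df[, measCols, drop = FALSE]))
  colnames(measure) <- df$id
  mods <- sub("_.*$", "", measCols)
  regs <- sub("^[^_]+_", "", measCols)
  cd <- S4Vectors::DataFrame(df[, metaCols, drop = FALSE],
                             row.names = df$id)
  if ("site" %in% colnames(cd)) cd$site <- factor(cd$site)
  dxCols <- grep("^dx_", colnames(cd), value = TRUE)
  for (cl in dxCols) cd[[cl]] <- as.logical(cd[[cl]])
  rd <- S4Vectors::DataFrame(modality = mods, region = regs,
                             row.names = measCols)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(measure = measure), rowData = rd, colData = cd)
  new("BrainCohort", se)
}

#' Read / write GWAS summary statistics TSV
#'
#' Expects columns SNP, A1, A2, freq, b, se, p, N (case-insensitive;
#' common synonyms such as `beta`/`b`, `pval`/`p`, `effect_allele`/`a1`
#' accepted). Rows violating the invariants (non-positive se, p outside
#' (0,1], freq outside (0,1), non-ACGT alleles, a1 == a2) are dropped
#' with a message giving counts.
#'
#' @param path file path.
#' @param trait trait label stored on the object.
#' @return a [GwasSumStats-class].
#' @export
readGwasSumstats <- function(path, trait = NA_character_) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  syn <- list(snp = c("snp", "rsid", "markername", "id"),
              a1 = c("a1", "effect_allele", "allele1", "ea"),
              a2 = c("a2", "other_allele", "allele2", "oa", "nea"),
              freq = c("freq", "eaf", "af", "frq", "maf"),
              beta = c("b", "beta", "effect", "est"),
              se = c("se", "stderr", "standard_error"),
              p = c("p", "pval", "p_value", "pvalue"),
              n = c("n", "samplesize", "n_total", "ntotal"))
  lowered <- tolower(colnames(df))
  out <- list()
  for (std in names(syn)) {
    hit <- which(lowered %in% syn[[std]])
    if (!length(hit))
      stop(sprintf("missing required column '%s' (accepted: %s)", std,
                   paste(syn[[std]], collapse = "/")), call. = FALSE)
    out[[std]] <- df[[hit[1]]]
  }
  d <- data.frame(out, stringsAsFactors = FALSE)
  d$snp <- as.character(d$snp)
  d$a1 <- toupper(as.character(d$a1))
  d$a2 <- toupper(as.character(d$a2))
  ok <- d$a1 %in% c("A", "C", "G", "T") & d$a2 %in% c("A", "C", "G", "T") &
    d$a1 != d$a2 & is.finite(d$beta) & d$se > 0 &
    d$p > 0 & d$p <= 1 & d$freq > 0 & d$freq < 1 & d$n > 0 &
    !duplicated(d$snp)
  ok[is.na(ok)] <- FALSE
  if (any(!ok))
    message(sprintf("readGwasSumstats: dropped %d of %d row(s) failing validation",
                    sum(!ok), nrow(d)))
  new("GwasSumStats", data = d[ok, , drop = FALSE], trait = trait)
}

#' @rdname readGwasSumstats
#' @param x a [GwasSumStats-class].
#' @export
writeGwasSumstats <- function(x, path) {
  stopifnot(is(x, "GwasSumStats"))
  d <- sumstats(x)
  out <- data.frame(SNP = d$snp, A1 = d$a1, A2 = d$a2, freq = d$freq,
                    b = d$beta, se = d$se, p = d$p, N = d$n)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an effect-size map CSV
#'
#' Two-column CSV `region,d` with header. When an atlas label set is
#' given, unknown regions are an error and the map is canonicalized to
#' atlas order with `NA` for regions absent from the file (explicit
#' absence, e.g. a 6-of-7 subcortical map).
#'
#' @param path file path.
#' @param atlas optional character vector of valid region labels in
#'   canonical order.
#' @param modality,contrast map metadata.
#' @return an [EffectSizeMap-class].
#' @export
readEffectMap <- function(path, atlas = NULL, modality = "SA",
                          contrast = "diagnosis") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("region", "d") %in% colnames(df)))
    stop("effect map file needs columns 'region' and 'd'", call. = FALSE)
  if (anyDuplicated(df$region))
    stop(sprintf("duplicate region(s): %s",
                 paste(unique(df$region[duplicated(df$region)]),
                       collapse = ", ")), call. = FALSE)
  if (!is.null(atlas)) {
    unknown <- setdiff(df$region, atlas)
    if (length(unknown))
      stop(sprintf("unknown region label(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    d <- setNames(rep(NA_real_, length(atlas)), atlas)
    d[df$region] <- df$d
    effectSizeMap(atlas, unname(d), modality = modality,
                  contrast = contrast)
  } else {
    effectSizeMap(df$region, df$d, modality = modality,
                  contrast = contrast)
  }
}

#' @rdname readEffectMap
#' @param x an [EffectSizeMap-class].
#' @param keepAbsent write `NA` rows for absent regions?
#' @export
writeEffectMap <- function(x, path, keepAbsent = FALSE) {
  stopifnot(is(x, "EffectSizeMap"))
  df <- data.frame(region = regions(x), d = x@d)
  if (!keepAbsent) df <- df[!is.na(df$d), ]
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an atlas crosswalk weight table
#'
#' CSV with columns `target_region`, `source_region`, `weight` (weights
#' of source regions contributing to each target region).
#'
#' @param path file path.
#' @return data.frame with columns `target`, `source`, `weight` for
#'   [crosswalkMap()].
#' @export
readCrosswalk <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("target_region", "source_region", "weight")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop(sprintf("crosswalk file missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  data.frame(target = df$target_region, source = df$source_region,
             weight = df$weight, stringsAsFactors = FALSE)
}

#' Read a BED-like region exclusion file
#'
#' Three tab-separated columns `chr`, `start`, `end` (no header; an
#' optional fourth column is kept as `label`). Used to drop SNPs in
#' long-range LD blocks during harmonization.
#'
#' @param path file path.
#' @return data.frame with columns `chr`, `start`, `end` (and `label`).
#' @export
readRegionFile <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("region file needs at least 3 columns (chr, start, end)",
         call. = FALSE)
  names(df)[1:3] <- c("chr", "start", "end")
  if (ncol(df) >= 4L) names(df)[4] <- "label"
  df$chr <- sub("^chr", "", as.character(df$chr))
  df[, seq_len(min(4L, ncol(df))), drop = FALSE]
}
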