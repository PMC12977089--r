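#' Simulate GWAS summary statistics for a panel of traits on one SNP set
#'
#' Multi-trait extension of [simulateGwasPair()] for bidirectional MR:
#' every trait shares the same SNP panel, receives its own disjoint
#' block of instrument SNPs (non-centrality uniform on 7-12 at its
#' sample size), and inherits one-hop causal contributions from other
#' traits through `causalMatrix` (entry [s, t] is the causal effect of
#' trait s on trait t; feedback loops are not propagated).
#'
#' @param traits trait labels.
#' @param nInstrumentsPerTrait instrument SNPs per trait.
#' @param causalMatrix square matrix over `traits` (zero diagonal);
#'   `NULL` = no causal effects.
#' @param sampleSizes named (or recycled) GWAS sample sizes per trait.
#' @param nSnps total SNPs (>= traits x instruments; default exactly
#'   that plus 20% null SNPs).
#' @param seed integer seed or `NULL`.
#' @return named list of [GwasSumStats-class], one per trait, with
#'   attribute `instruments` (named list of instrument SNP ids).
#' @export
simulateGwasPanel <- function(traits, nInstrumentsPerTrait = 30,
                              causalMatrix = NULL, sampleSizes = 100000,
                              nSnps = NULL, seed = NULL) {
  nT <- length(traits)
  if (nT < 1L) stop("'traits' must be non-empty", call. = FALSE)
  need <- nT * nInstrumentsPerTrait
  nSnps <- nSnps %||% ceiling(need * 1.2)
  if (nSnps < need)
    stop(sprintf("'nSnps' must be >= %d (traits x instruments)", need),
         call. = FALSE)
  if (is.null(causalMatrix))
    causalMatrix <- matrix(0, nT, nT, dimnames = list(traits, traits))
  causalMatrix <- as.matrix(causalMatrix)
  if (!all(dim(causalMatrix) == nT))
    stop("'causalMatrix' must be square over the traits", call. = FALSE)
  if (is.null(rownames(causalMatrix)))
    dimnames(causalMatrix) <- list(traits, traits)
  if (any(diag(causalMatrix) != 0))
    stop("'causalMatrix' diagonal must be zero", call. = FALSE)
  if (length(sampleSizes) == 1L)
    sampleSizes <- setNames(rep(sampleSizes, nT), traits)
  if (is.null(names(sampleSizes))) names(sampleSizes) <- traits

  withSeed(seed, {
    chr <- sample.int(22L, nSnps, replace = TRUE)
    pos <- sample.int(99000000L, nSnps)
    snp <- paste0(chr, ":", pos)
    pairPool <- matrix(c("A", "C", "A", "G", "C", "A", "G", "A",
                         "C", "T", "T", "C", "G", "T", "T", "G"),
                       ncol = 2, byrow = TRUE)
    pick <- sample.int(nrow(pairPool), nSnps, replace = TRUE)
    freq <- runif(nSnps, 0.05, 0.95)

    seMat <- sapply(traits, function(t)
      1 / sqrt(2 * freq * (1 - freq) * sampleSizes[[t]]))
    base <- matrix(0, nSnps, nT, dimnames = list(snp, traits))
    instruments <- list()
    for (i in seq_len(nT)) {
      idx <- ((i - 1L) * nInstrumentsPerTrait + 1L):(i * nInstrumentsPerTrait)
      base[idx, i] <- sample(c(-1, 1), length(idx), replace = TRUE) *
        runif(length(idx), 7, 12) * seMat[idx, i]
      instruments[[traits[i]]] <- snp[idx]
    }
    total <- base + base %*% causalMatrix

    out <- lapply(seq_len(nT), function(i) {
      se <- seMat[, i]
      b <- total[, i] + rnorm(nSnps, 0, se)
      p <- pmax(2 * pnorm(-abs(b / se)), 1e-300)
      new("GwasSumStats",
          data = data.frame(snp = snp, a1 = pairPool[pick, 1],
                            a2 = pairPool[pick, 2], freq = freq,
                            beta = b, se = se, p = p,
                            n = rep(sampleSizes[[i]], nSnps),
                            stringsAsFactors = FALSE),
          trait = traits[i])
    })
    names(out) <- traits
    attr(out, "instruments") <- instruments
    out
  })
}
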