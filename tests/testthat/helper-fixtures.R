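# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

toyMap <- function(d, regions = NULL, modality = "SA",
                   contrast = "diagnosis") {
  regions <- regions %||% paste0("r", seq_along(d))
  effectSizeMap(regions, d, modality = modality, contrast = contrast)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal valid summary-stat table; override columns as needed.
toySumStats <- function(n = 5, trait = "t", snp = NULL, a1 = NULL,
                        a2 = NULL, beta = NULL, se = NULL, p = NULL,
                        freq = NULL, N = 10000) {
  df <- data.frame(
    snp = snp %||% paste0("1:", seq_len(n) * 1000),
    a1 = a1 %||% rep("A", n),
    a2 = a2 %||% rep("G", n),
    freq = freq %||% rep(0.3, n),
    beta = beta %||% seq(0.1, by = 0.01, length.out = n),
    se = se %||% rep(0.01, n),
    p = p %||% rep(1e-10, n),
    n = rep(N, n), stringsAsFactors = FALSE)
  new("GwasSumStats", data = df, trait = trait)
}

# Directly build a harmonized instrument set (bypasses allele logic) for
# estimator unit tests.
toyHarmonized <- function(bExp, seExp, bOut, seOut, snp = NULL) {
  k <- length(bExp)
  new("HarmonizedSet",
      table = data.frame(snp = snp %||% paste0("1:", seq_len(k) * 100),
                         bExp = bExp, seExp = seExp,
                         pExp = 2 * pnorm(-abs(bExp / seExp)),
                         bOut = bOut, seOut = seOut,
                         pOut = 2 * pnorm(-abs(bOut / seOut)),
                         stringsAsFactors = FALSE),
      flipped = character(), removedPalindromic = character(),
      removedRegion = character(), removedMismatch = character())
}

# Exact one-sided binomial upper tail by direct summation of the mass
# function built from choose(); oracle independent of stats::pbinom.
binomTailOracle <- function(k, n, p = 0.5)
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))

# All permutations of 1..n by Heap's algorithm (iterative, independent of
# the package's recursive generator).
heapPermutations <- function(n) {
  a <- seq_len(n)
  c0 <- rep(1L, n)
  out <- matrix(0L, factorial(n), n)
  out[1, ] <- a
  row <- 1L
  i <- 1L
  while (i <= n) {
    if (c0[i] < i) {
      if (i %% 2L == 1L) a[c(1L, i)] <- a[c(i, 1L)]
      else a[c(c0[i], i)] <- a[c(i, c0[i])]
      row <- row + 1L
      out[row, ] <- a
      c0[i] <- c0[i] + 1L
      i <- 1L
    } else {
      c0[i] <- 1L
      i <- i + 1L
    }
  }
  out
}

smallRegions <- function(k = 3) list(SA = dkCorticalRegions()[seq_len(k)])
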