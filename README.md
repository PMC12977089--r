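# prsbrainmap

Cross-disorder analysis of how polygenic risk for neuropsychiatric
disorders relates to regional brain morphology. The package is aimed at
imaging-genetics analysts who have (a) an individual-level cohort with
per-participant brain measures, covariates and per-disease polygenic
risk scores (PRS), (b) published case–control effect-size brain maps
(Cohen's *d* per Desikan–Killiany region, ENIGMA-style CSV), and (c)
GWAS summary statistics — or who have none of these, since a synthetic
module generates all three with known ground truth.

## What it computes

* **PRS association scans.** Brain measures are residualized on age,
  sex, scanner site, a scan-quality proxy and 10 genetic PCs, inverse
  normal transformed (Blom ranks), optionally adjusted for the matching
  global measure, and regressed on each standardized PRS. Results carry
  a three-tier Bonferroni annotation built from the effective number of
  independent phenotypes *t*ₑ (eigenvalue-based, Li–Ji
  `sum[1(λ≥1) + (λ−⌊λ⌋)]` by default, Nyholt also reported): nominal
  `p < 0.05`, disease-wise `p < 0.05/tₑ`, study-wise
  `p < 0.05/(tₑ·n_diseases)` — e.g. 0.05/(22·13) = 1.7e-4 for cortical
  measures.
* **Brain-map concordance.** Genetic-risk maps (median split on PRS,
  pooled-SD Cohen's *d* per region) against case–control maps: sign
  concordance `k/n` with the exact tail `P(X ≥ k), X ~ Bin(n, ½)`,
  Pearson correlation with half-width `1.96·√((1−r²)/(n−2))` and a
  permutation null (exhaustive `n!` enumeration for n ≤ 8, else 10,000
  label permutations with `(hits+1)/(nPerm+1)`), BH-FDR across
  disorders.
* **Bidirectional two-sample Mendelian randomization** between the
  three global measures (total SA, mean CT, ICV) and the disorders:
  allele harmonization with palindromic-SNP and long-range-LD-region
  removal, instrument selection at 5e-8, then IVW, MR-Egger, weighted
  median, weighted mode and a GSMR-style estimator with iterative HEIDI
  outlier removal, plus Cochran's Q / Egger-intercept / leave-one-out
  sensitivity analyses.
* **Quadrant enrichment.** Exact one-sided binomial test of whether
  diagnosed individuals exceed the 25% chance rate of falling in the
  high-PRS / low-brain quadrant of standardized axes.

## Worked example

```r
library(prsbrainmap)

## cohort with negative PRS effects on surface area, strongest posteriorly
eff <- matrix(0, 1, 34,
              dimnames = list("SZ", paste0("SA_", dkCorticalRegions())))
eff[1, ] <- -seq(0.01, 0.05, length.out = 34)
bc <- simulateCohort(nParticipants = 8000,
                     regions = list(SA = dkCorticalRegions()),
                     diseases = "SZ", prsEffect = eff,
                     prsGlobalEffect = c(SZ = -0.05), seed = 1)

## association scan with tier annotation
scan <- associationScan(bc)
scan <- significanceTiers(scan, tE = c(SA = 22, global = 1), nDiseases = 13)
head(scan[order(scan$p), c("region", "beta", "se", "p", "tier")], 3)
#>                region   beta     se        p       tier
#> 37                ICV -0.145 0.0111 5.14e-39 study_wise
#> 36     mean_thickness -0.140 0.0111 3.66e-36 study_wise
#> 35 total_surface_area -0.140 0.0111 3.66e-36 study_wise

## genetic-risk map vs a case-control map sharing the spatial profile
risk <- prsEffectMap(bc, "SZ", "SA")
diagMap <- effectSizeMap(dkCorticalRegions(),
                         -(seq(0.01, 0.05, length.out = 34) + 0.05) * 1.6)
sc <- signConcordance(risk, diagMap)
#> concordance 34/34 (100.0%), exact binomial p = 5.82e-11
pc <- spatialCorrelation(risk, diagMap, nPerm = 10000, seed = 2)
#> spatial r = 0.59 +/- 0.28, permutation p = 0.0003

## two-sample MR with a known causal effect of 0.3
gp <- simulateGwasPair(nSnps = 300, nInstruments = 50, bxy = 0.3, seed = 3)
h <- selectInstruments(harmonize(gp$exposure, gp$outcome))
mrIvw(h)
#> MREstimate [IVW]: beta = 0.2976 (se 0.0200), p = 6.14e-50
#>   OR = 1.347, 95% CI [1.295, 1.401]; 49 IV(s) used, 0 removed
```

The scan found the planted global pathway (all three global measures
study-wise significant with negative betas), the map comparison
recovered perfect sign concordance at the analytic minimum p for 34
regions and a permutation p at its attainable floor, and IVW recovered
the causal effect within one standard error. The full chain —
association, map comparison, MR, quadrant — runs end to end via
`runPipeline(pipelineConfig(...))` or
`Rscript scripts/run_pipeline.R --seed 1 --out results`, writing four
TSV result tables and a reproducibility manifest.

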