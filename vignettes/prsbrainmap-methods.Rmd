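---
title: "Methods: linking polygenic risk to regional brain morphology"
author: "prsbrainmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking polygenic risk to regional brain morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsbrainmap)
```

# Overview

`prsbrainmap` implements a cross-disorder analysis chain connecting
polygenic risk scores (PRS) for neuropsychiatric disorders to regional
brain morphology, of the kind run on large imaging-genetics cohorts
(UK-Biobank-scale individual-level data, ENIGMA-style case-control
summary maps, public GWAS summary statistics). Individual-level and
consortium data of that kind are access-restricted, so the package ships
a first-class synthetic-data module that generates every input with
known ground truth; all statistical machinery is agnostic to whether its
inputs are synthetic or real.

The stages, each usable on its own:

1. **Phenotype preparation** — residualize each brain measure on
   age, sex, scanner site, a scan-quality proxy (Euler number) and 10
   genetic PCs, then apply a rank-based inverse normal transformation
   (INT); optionally adjust regional measures for the matching global
   measure ("relative" measures).
2. **Association scan** — per disease x region ordinary least squares of
   the prepared measure on the standardized PRS, annotated with a
   three-tier Bonferroni scheme based on the effective number of
   independent phenotypes.
3. **Map comparison** — build genetic-risk Cohen's *d* maps by median
   split on the PRS, compare them against case-control *d* maps region
   by region: exact binomial sign concordance, Pearson correlation with
   a permutation null, Benjamini-Hochberg adjustment across disorders.
4. **Mendelian randomization** — bidirectional two-sample MR between the
   three global brain measures and the disorders: harmonization,
   instrument selection, IVW, Egger, weighted median, weighted mode and
   a GSMR-style estimator with iterative HEIDI outlier removal, plus
   sensitivity analyses.
5. **Quadrant enrichment** — exact binomial test of whether diagnosed
   individuals are over-represented in the high-PRS / low-brain-measure
   quadrant of standardized axes.

# The synthetic cohort generator

`simulateCohort()` draws, for each participant, independent covariates
matched to the marginals of a large middle-aged community imaging
cohort: age uniform on 45.13–81.83 years, sex Bernoulli with a
male-female ratio of 0.9, three scanner sites, a Gaussian Euler-number
proxy, and ten standard-normal genetic PCs. Each disease PRS is standard
normal. Brain measures follow an additive model

$$y_{ir} = c_i + g_i + \sum_d \beta_{dr}\,\mathrm{PRS}_{id} +
\varepsilon_{ir},\qquad
g_i = \sum_d \gamma_d\,\mathrm{PRS}_{id} + \eta_i,$$

where $c_i$ collects covariate effects, $g_i$ is a shared latent
global-size factor ($\eta_i \sim N(0, 0.3^2)$ by default), $\beta_{dr}$
are the planted standardized regional effects (the realistic range is
$|\beta| \approx 0.01$–$0.05$), $\gamma_d$ an optional PRS effect on
global size, and $\varepsilon_{ir} \sim N(0, 1)$. The shared factor
induces the inter-regional correlation that motivates both the
effective-test correction and the absolute/relative distinction: with a
pure global pathway ($\beta = 0$, $\gamma < 0$) every absolute regional
association is real while every relative association is null, which the
tests verify. Global measures are $g_i$ plus covariate effects and a
smaller noise term ($\sigma = 0.2$).

Measures are produced on a standardized latent scale rather than native
units (mm^2^, mm, mm^3^): the INT applied during preparation makes every
downstream statistic invariant to monotone rescaling, so native-unit
intercepts would be decorative. The generator does **not** emulate
spatial autocorrelation between neighboring regions beyond the single
shared factor, distance-dependent covariance, site-by-age interactions,
or non-Gaussian measure distributions — passing tests therefore show
correctness of the statistical machinery under the stated generative
model, not robustness to every feature of real imaging data.

Diagnoses come from a liability-threshold model,
$L_{id} = w_g\,\mathrm{PRS}_{id} - w_b\,\bar g_i + N(0,1)$ with
$\bar g_i$ the standardized mean of the standardized global measures;
`dx = L > threshold`. `liabilityThreshold()` converts a target
prevalence to a threshold using
$\sigma_L = \sqrt{w_g^2 + w_b^2 + 1}$, an independence approximation
that is slightly off when the PRS also drives $g$ (realized prevalence
then deviates by a few percent of itself — immaterial for the tests,
which target case counts of roughly 20–60). Diseases are generated
independently; comorbidity structure is not modeled because the
source analyses treat disorders one at a time.

The GWAS simulator (`simulateGwasPair()`, and `simulateGwasPanel()` for
many traits on one SNP panel) gives instrument SNPs true exposure
effects with non-centrality uniform on 7–12 at the stated sample size,
so essentially all pass the genome-wide threshold $5\times10^{-8}$ while
remaining realistically weak; standard errors follow
$1/\sqrt{2f(1-f)N}$. Outcome effects are
$b_{xy} b^{exp}_j + \text{pleiotropy}_j + \text{noise}$. Instruments are
mutually independent (identity LD): the package consumes
clumped/simulated instruments, and LD-aware simulation is out of scope.
SNP identifiers are `chr:pos`, which is what the optional exclusion of
long-range-LD regions (e.g. 17q21.31) keys on.

# Phenotype preparation

Residualization is two-stage by design: covariates are removed first and
the association model then contains only the PRS, reproducing the
standard order of operations in imaging-genetics scans (rather than a
joint fit). Residualization is exact linear projection, so it is
idempotent and leaves columns orthogonal to the design.

The INT uses Blom offsets, $\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$,
with average ranks for ties — the conventional default among the
rank-based INT variants. Relative measures are formed by residualizing
each covariate-adjusted regional measure on its covariate-adjusted
matching global measure (total surface area for SA, mean thickness for
CT, ICV for subcortical volumes) before the INT. Adjustment by
residualization was chosen over ratio scaling or joint modeling; it
keeps the operation linear and exactly removes the shared component.

`effectiveTests()` reports both eigenvalue-based estimates of the
effective number of independent phenotypes for a correlation matrix of
$M$ measures:

* Li–Ji: $t_e = \sum_i \big[\mathbf 1(\lambda_i \ge 1) + (\lambda_i -
  \lfloor\lambda_i\rfloor)\big]$ (default),
* Nyholt: $t_e = 1 + (M-1)\big(1 - \mathrm{Var}(\lambda)/M\big)$.

Li–Ji is the default because the integer effective counts quoted for
cortical (22) and subcortical (7) measures in this literature are
consistent with its near-integer behavior on strongly structured
matrices. Eigenvalues are rounded to 10 decimals before the floor:
`eigen()` returns values a few ulp below an integer for exactly
exchangeable matrices, and the Li–Ji summand is discontinuous there.

The three significance tiers are nominal ($p < 0.05$), disease-wise
($p < 0.05/t_e$) and study-wise ($p < 0.05/(t_e \cdot
n_{\text{diseases}})$); with $t_e = 22$, 13 diseases this gives the
cortical study-wise threshold $1.7\times10^{-4}$ and with $t_e = 7$ the
subcortical $5.5\times10^{-4}$. The disease count defaults to 13 but is
configurable.

# Map comparison

Genetic-risk maps dichotomize the PRS at the sample median (strictly
above = high risk; ties at the median go low) and take the pooled-SD
Cohen's *d* per region. For a standard-normal PRS with a linear effect
$\beta$ on a unit-variance measure, the expected median-split *d* is
$2\beta\sqrt{2/\pi}$ to first order, which the tests use as an oracle.
Case-control maps arrive as two-column CSVs, optionally crosswalked into
the target atlas by weighted averaging (weights per target region sum
to 1).

Sign concordance counts regions with $d_A d_B > 0$ and tests $k$ of $n$
against $\mathrm{Binomial}(n, 1/2)$ with the exact upper tail. Regions
with an exactly zero effect in either map are excluded from $n$ rather
than counted as half-concordant: the test stays exact and the choice is
auditable because both $k/n$ and the proportion are reported. Absent
regions (e.g. a 6-of-7 subcortical map) are `NA` and likewise drop out.

The spatial correlation reports Pearson's $r$, the large-sample 95%
half-width $1.96\sqrt{(1-r^2)/(n-2)}$, and a permutation $p$: for
$n \le 8$ all $n!$ region-label permutations are enumerated exactly;
otherwise `nPerm` (default 10,000) uniform permutations with the
bias-corrected estimate $(\#\{|r^*| \ge |r|\} + 1)/(n_{perm}+1)$, whose
floor $10^{-4}$ matches the conventional minimum printed for 10,000
permutations. Label permutations ignore spatial autocorrelation;
surface-based "spin" nulls are out of scope. FDR adjustment
(Benjamini–Hochberg) is applied across the disorders within one
modality family.

# Mendelian randomization

Harmonization aligns each SNP to a common effect allele (direct match,
allele swap with sign flip, strand complement, or both), removes
palindromic A/T and C/G SNPs outright, and optionally removes SNPs
inside supplied exclusion regions. Instruments are exposure-significant
SNPs at $5\times10^{-8}$ by default (the exact threshold used by any
given study is rarely printed; it is configurable).

With aligned effects $(\hat b_{xj}, \hat b_{yj})$ and ratio estimates
$r_j = \hat b_{yj}/\hat b_{xj}$:

* **IVW**: weighted mean of $r_j$ with weights $\hat
  b_{xj}^2/\mathrm{se}_{yj}^2$ (fixed-effect SE).
* **Egger**: weighted regression with free intercept, exposure effects
  oriented positive; the intercept estimates directional pleiotropy.
  SEs use $t_{k-2}$ with multiplicative overdispersion bounded below
  by 1. The Egger intercept inherits the usual weak-instrument (NOME)
  sensitivity: under the package generator's instrument strengths
  (non-centrality 7–12) its null coverage sits around 93–95%.
* **Weighted median**: inverse-variance-weighted median of $r_j$ by the
  standard interpolation estimator; SE by seeded parametric bootstrap
  (resampling the summary statistics), 1,000 resamples by default.
* **Weighted mode**: mode of the weighted kernel density of $r_j$
  (normal kernel, modified-Silverman bandwidth times a configurable
  factor, default 1); bootstrap SE.
* **GSMR-style**: IVW under identity LD with an iterative HEIDI outlier
  filter. Each iteration scores every SNP by $z_j = (r_j -
  \hat\beta)/\sqrt{v_j}$ with the delta-method variance $v_j =
  (\mathrm{se}_{yj}^2 + r_j^2\,\mathrm{se}_{xj}^2)/\hat b_{xj}^2$, and
  removes the single worst SNP among those with $p(z_j) < 0.01$,
  re-estimating until none falls below the threshold. One removal per
  iteration is deliberate: a gross outlier biases the pooled estimate
  enough to push valid instruments past the threshold, so removing all
  flagged SNPs at once cascades into mass deletion (observed directly
  with a 10-SE spike-in: 25 of 30 instruments lost, versus exactly the
  spike under one-at-a-time removal).

Sensitivity analyses report Cochran's Q with the same delta-method
per-SNP variances — first-order IVW weights ignore exposure noise and
were measured to reject 6.6–8% of null replicates at the 5% level,
versus 3.2–3.4% (slightly conservative) for the delta-method form — the
Egger intercept test, and a leave-one-out IVW series flagging the
maximally deviating SNP.

`runBidirectionalMr()` runs every (brain measure, disorder) pair in both
directions — forward estimates are reported on the odds-ratio scale,
reverse on the beta scale — with the three-tier annotation nominal
$p<0.05$, disease-wise $p < 0.05/3 \approx 1.6\times10^{-2}$ (three
global measures) and study-wise $p < 0.05/39 \approx 1.2\times10^{-3}$
(13 disorders); cells whose estimation fails (no shared SNPs, no
instruments) are marked `unavailable` rather than dropped.

# Quadrant enrichment

PRS and a global measure are standardized over the **full** sample
(patients included — whether the original analyses standardized within
the healthy subsample is not documented; the full sample is the simpler
convention and is flagged here). Diagnosed cases are cross-classified by
the sign of the two z-scores, with exact zeros assigned to the low side
(a measure-zero event on continuous data that still needs a
deterministic rule). The one-sided exact binomial test compares the
count in the high-PRS / low-measure quadrant with the chance rate 0.25;
the direction follows the prior hypothesis that high genetic liability
and smaller brains are risk factors. Discreteness at realistic case
counts (tens of cases) makes the test conservative, which the null
calibration in the test suite confirms.

# Numerical and design choices

* Degenerate inputs error early with the offending field named:
  zero-variance PRS, constant INT input, rank-deficient covariates,
  non-symmetric correlation matrices, zero pooled SDs, empty SNP
  intersections.
* All randomness flows through explicit `seed` arguments; seeded calls
  save and restore the caller's RNG state, and the pipeline derives
  per-stage child seeds (below $2^{31}$) from one master seed, so reruns
  are byte-identical.
* Hemisphere combination is assumed done upstream (sum for surface area
  and volumes, mean for thickness): the atlas vectors are the 34
  bilateral Desikan–Killiany regions and 7 subcortical structures.
* The pipeline stage sizes used by the test suite and the acceptance
  script (cohorts of 2,000–33,861; 500–2,000 Monte-Carlo replicates;
  50-instrument GWAS; 10,000 permutations) were chosen as the smallest
  sizes at which each check's Monte-Carlo error is well below the
  property being asserted.

# Known limitations

* Identity-LD MR only; a reference-panel LD matrix (as full GSMR uses)
  is not consumed.
* Region-label permutation nulls ignore spatial autocorrelation.
* The synthetic generator's independence assumptions (covariates,
  disorders, SNPs) mean calibration results certify the estimators, not
  the behavior under correlated real-world structure.
* Published odds ratios and map values from restricted cohort data
  cannot be reproduced here; the analytic quantities (binomial tails,
  interval half-widths, Bonferroni thresholds) can and are.
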