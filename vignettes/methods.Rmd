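---
title: "Cross-trait cFDR and Mendelian randomization: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-trait cFDR and Mendelian randomization: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiocfdr)
```

# The problem

Two complex traits — the motivating pair is type 2 diabetes (T2D) and birth
weight (BW) — can share genetic determinants that neither trait's GWAS detects
on its own at genome-wide significance. `pleiocfdr` implements a targeted
cross-trait workflow over GWAS *summary statistics*:

1. restrict attention to potentially functional **CpG-SNPs** (variants whose
   alleles create or destroy a CG dinucleotide, hence a potential DNA
   methylation target);
2. merge and harmonize the two traits' per-SNP statistics, and thin them to
   approximate linkage-disequilibrium independence against a genotype
   reference panel;
3. quantify cross-trait enrichment with stratified conditional Q-Q and
   fold-enrichment curves, and call per-SNP significance with the conditional
   and conjunction false discovery rate (cFDR / ccFDR);
4. probe causal direction with a bi-directional two-sample Mendelian
   randomization (MR) suite.

A seeded synthetic generator with known per-SNP truth stands in for consortium
downloads so that every statistical guarantee is testable at desk scale.

# CpG-SNP classification

A biallelic SNP with flanking reference bases $l$ (5') and $r$ (3') is a
CpG-SNP iff the set of CG dinucleotides overlapping the site differs between
its two alleles. For allele $X$, the possible sites are $lX$ = "CG" (requires
$l = C$, $X = G$) and $Xr$ = "CG" (requires $X = C$, $r = G$). Because the CG
dinucleotide is its own reverse complement, plus-strand checks suffice. The
classifier compares the two alleles' site *sets*, not mere presence: a
C$\to$G substitution between a C on the left and a G on the right moves the
CpG site and is classified as a CpG-SNP even though both alleles contain a
CG. The test suite checks all $4 \times 4 \times 12 = 192$ contexts against a
string-scanning enumerator.

# Harmonization

Summary statistics are merged by SNP id and the second study's effects are
re-signed onto the first study's effect allele: an allele swap negates the
effect and complements the frequency; strand flips are resolved through base
complementation. Palindromic SNPs (A/T, C/G) cannot be resolved by strand, so
they are oriented by allele frequency, and dropped when the effect-allele
frequency lies in $[0.42, 0.58]$ (inclusive) — the conventional ambiguity
window; near 0.5 the frequency carries no orientation information. The same
rules drive both trait merging and MR instrument harmonization (`action = 2`;
`action = 1` trusts the strand, `action = 3` drops all palindromes). Input
p-values of exactly 0 are clamped to the smallest positive double (required
for $-\log_{10}$ transforms) and logged; genomic control is *not* re-applied
at merge time, since consortium statistics arrive already GC-corrected at the
study level.

# LD pruning and clumping

`indep_pairwise()` follows the windowed procedure of standard pruning tools:
within a 50-SNP window, one SNP of any pair with $r^2 > 0.2$ (squared Pearson
correlation of dosages, pairwise-complete over missing values) is removed
until the window is clean, then the window shifts 5 SNPs forward, repeating
until stable. Two details are pinned down that the classic tools leave to
their internals:

* **Tie-break.** The removed SNP is the one with the larger principal-trait
  p-value; absent p-values, the later positional SNP. A deterministic rule is
  required for reproducibility.
* **Termination.** A step larger than 1 can leave a violating pair that no
  stepped window straddles, so a final unit-step sweep runs after the stepped
  passes stabilize. The output therefore satisfies, exactly, the invariant
  that no retained pair within any 50-SNP span exceeds the ceiling.

`clump_by_pvalue()` is the greedy instrument selector: SNPs sorted by
ascending p (ties broken by id), each accepted iff its $r^2$ with every
previously accepted same-chromosome SNP is below the ceiling (0.001 for MR
instruments). Zero-variance dosage columns yield undefined LD, which callers
treat as 0 with a log note.

# Conditional and conjunction FDR

For principal-trait p-values $p_1$ and conditional-trait p-values $p_2$, the
per-SNP estimator is the pointwise empirical-Bayes quantity

$$\widehat{\mathrm{cFDR}}_i = \min\!\left(1,\;
  p_{1i} \cdot \frac{\#\{k : p_{2k} \le p_{2i}\}}
                    {\#\{k : p_{1k} \le p_{1i},\, p_{2k} \le p_{2i}\}}\right),$$

the conditional analogue of the classic empirical FDR $p \cdot N / \mathrm{rank}$,
to which it reduces exactly when all $p_2$ are equal. Ties are counted
inclusively in both counts, and the denominator is always at least 1 because
SNP $i$ counts itself. The implementation uses an $O(N \log N)$ Fenwick-tree
dominance count (Rcpp); the unit tests pin it to a double-loop oracle.
Design choices:

* **No smoothing, no monotonization.** Raw pointwise values are reported (the
  `monotonized` attribute is `FALSE`); interpolated lookup-table smoothing is
  a possible extension, not the default. With constant conditioning, applying
  a running minimum along sorted $p_1$ makes the calls identical to
  Benjamini–Hochberg step-up calls; without it the called set is a subset.
  Both facts are asserted in the tests.
* **Conjunction.** $\mathrm{ccFDR} = \max(\mathrm{cFDR}_{1|2}, \mathrm{cFDR}_{2|1})$,
  element-wise; small values support association with *both* traits.
* **Thresholds.** Significance is called inclusively at
  $\mathrm{cFDR} \le 0.05$, with $0.01$ as the conservative tier; the
  Manhattan reference line sits at $-\log_{10} 0.05 = 1.301$.
* **Scale invariance.** The estimator depends on $p_2$ only through ranks, so
  it is invariant to any strictly monotone transform of the conditional
  p-values (tested).

Enrichment visualization: conditional Q-Q curves plot the sorted
$-\log_{10} p_1$ within nested strata $p_2 \le 1, 0.1, 0.01, 0.001$ against
$-\log_{10}(i/(|S|+1))$; fold-enrichment curves divide each stratum's
cumulative fraction below a nominal p by the full panel's, on a 200-point
log-spaced grid between 1 and $10^{-8}$. The genomic-control factor
$\lambda = \mathrm{median}(z^2)/0.4549$ corrects the principal trait only
(deflating $z^2$ by $\lambda$), as inflation correction attaches to the
nominal axis; the baseline stratum is identically 1.

# Two-sample Mendelian randomization

Instruments are exposure SNPs with $p < 5 \times 10^{-8}$, clumped at
$r^2 < 0.001$. With harmonized per-SNP effects
$(\hat\beta_{Ei}, \hat\beta_{Oi})$ and outcome standard errors
$\sigma_{Oi}$, weights are $w_i = \sigma_{Oi}^{-2}$ and the per-SNP Wald
ratio is $\hat\theta_i = \hat\beta_{Oi}/\hat\beta_{Ei}$ with first-order SE
$\sigma_{Oi}/|\hat\beta_{Ei}|$ (zero exposure betas are excluded; zero
*outcome* betas — which occur in rounded published tables — are handled
without special-casing).

* **IVW**: weighted least squares of $\hat\beta_O$ on $\hat\beta_E$ without
  intercept; algebraically the $w_i \hat\beta_{Ei}^2$-weighted mean of the
  Wald ratios (asserted numerically). The reported SE follows the
  multiplicative random-effects convention floored at fixed effect:
  $\mathrm{SE} = \mathrm{SE}_{FE} \cdot \max(1, \hat\sigma)$ with
  $\hat\sigma^2$ the weighted residual mean square on $n-1$ df; p-values are
  normal. One instrument degenerates to its fixed-effect Wald ratio.
* **MR-Egger**: the same regression with a free intercept, after orienting
  every SNP so $\hat\beta_E \ge 0$ (required for the intercept to estimate
  directional pleiotropy); SEs scaled by $\max(1, \hat\sigma)$, inference on
  $t_{n-2}$; needs $n \ge 3$ for finite residual df.
* **Weighted median**: the interpolated median of the Wald-ratio distribution
  weighted by inverse squared ratio SEs; SE by parametric bootstrap
  (resampling each beta from its normal) under a fixed, recorded seed.
* **Simple / weighted mode**: argmax of a normal-kernel density of the
  ratios, bandwidth $\varphi \cdot 0.9 \min(\mathrm{SD}, \mathrm{MAD})
  n^{-1/5}$ with $\varphi = 1$; uniform or inverse-variance weights; bootstrap
  SE. Mode estimates are intrinsically bandwidth-sensitive, which is why the
  shipped worked example checks them at a loose tolerance while IVW, Egger
  and the weighted median reproduce the published values to three decimals.

These conventions reproduce, from the packaged BW$\to$T2D instrument table
(46 harmonized instruments after two ambiguous palindromic SNPs are dropped
from the 48 published rows), the published estimates: IVW $b = 0.441$,
$\mathrm{SE} = 0.207$, OR $= 1.554$, $p = 0.033$; Egger slope $0.968$
($\mathrm{SE}$ $0.723$); weighted median $0.000$ — computed live by
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`.
`run_bidirectional()` repeats selection, harmonization and all five
estimators in both causal directions and reports a direction with fewer than
three instruments as not estimable.

# The synthetic generator

`mixture_spec()` defines a four-component per-SNP mixture: null
($\pi_{00} = 0.90$), trait-1-only ($\pi_{10} = 0.04$), trait-2-only
($\pi_{01} = 0.04$), pleiotropic ($\pi_{11} = 0.02$). Non-null z-score means
are $N(0, \sigma^2)$ with $\sigma_1 = \sigma_2 = 3$ — a typical magnitude for
replicable GWAS signals — and pleiotropic means are correlated at
$\rho = 0.5$. Observed $z = \mu + N(0,1)$, $p = 2\Phi(-|z|)$, and effect
sizes come from the standard GWAS approximation
$\mathrm{SE} = 1/\sqrt{2 n f (1-f)}$ with $n = 10^5$ per trait. CpG flags are
Bernoulli(0.25), independent of class by default. Signals sit on index SNPs
only — no LD leakage into neighbours — to keep the truth table crisp for FDR
evaluation.

Reference panels discretize a blockwise AR(1) latent Gaussian (blocks of 20
SNPs, within-block parameter 0.8) at Hardy–Weinberg quantiles of a
$U(0.05, 0.5)$ allele frequency. Discretization attenuates correlation, so
the latent AR parameter is inflated by the arcsine relation
$\sin(\tfrac{\pi}{2} r_{ld})$, making `r_ld` approximately the correlation
realized on the dosage scale.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: coalescent LD structure and allele-frequency /
LD-score coupling, population stratification and relatedness, case-control
ascertainment, association leakage from causal SNPs into LD neighbours, and
CpG-flag enrichment among causal variants (available via `cpg_enrichment` but
off by default).

# Numerical choices and degenerate inputs

* p-values of exactly 0 are clamped to `.Machine$double.xmin`; generated
  p-values are bounded away from 0 the same way.
* Undefined LD (zero variance, fewer than two complete pairs) is `NA` from
  `pairwise_r2()` and treated as 0 by pruning, clumping and novelty linking.
* Weighted-median interpolation clamps to the extreme ratio when the target
  quantile falls outside the half-weight grid; the mode estimator falls back
  to the highest-weight ratio when the bandwidth degenerates to 0.
* Empty strata are omitted with a warning; fold-enrichment grid points with
  an empty denominator are omitted.
* Bootstrap seeds are explicit arguments, recorded in the fit object, and
  restored on exit so estimator calls do not perturb the caller's RNG state.

# Problem sizes used in the shipped checks

The test suite exercises the statistical guarantees at sizes chosen to make
Monte-Carlo error small relative to the margins being asserted: null
conservatism over 200 replicates of 5,000 SNPs; realized false-discovery
proportion and Q-Q separation over 100 seeded mixtures of 10,000 SNPs;
pruning equivalence on 100 random 30-sample panels; MR parameter recovery
over 100 seeds of 100 instruments. All are regenerated in code at run time;
nothing is stored.

# Known limitations

* The cFDR estimator is the pointwise empirical form; it is conservative on
  average but individual values are not monotone in $p_1$, and no
  covariate-adjusted or LD-weighted variants are provided.
* Pruning operates on SNP-count windows, not physical distance, and the
  reported "independence" of called loci is entirely delegated to the
  upstream pruning — there is no second-stage clumping of significant hits.
* Only biallelic SNPs with single-base alleles are supported; no indels,
  no liftover, no VCF parsing (convert VCFs to TSV upstream, e.g. with
  `bcftools query`).
* Two-sample MR assumes non-overlapping samples and NOME-style exposure
  precision; no MR-PRESSO outlier removal, Steiger filtering, or
  multivariable extensions.
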