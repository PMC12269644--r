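---
title: "Methods: ASM-aware meQTL mapping with asmqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ASM-aware meQTL mapping with asmqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bisulfite sequencing of a natural, pedigreed population yields, for each
sample and CpG site, a count of methylated reads out of a read total. When
genotypes can be called from the same reads, every SNP within a read length
of a CpG (100 bp here) defines a SNP--CpG pair at which a local (cis)
genetic effect on methylation can be tested. `asmqtl` implements that test
and everything around it: genotype calling from bisulfite pileups, the
CpG/SNP/pair filters, an overdispersed binomial mixed model that exploits
allele-specific methylation (ASM), permutation-based empirical FDR control,
variance decomposition, cis-eQTL mapping on expression from the same
population, meQTL--eQTL integration, and genomic-annotation enrichment. A
synthetic-data generator with a known truth table supports end-to-end
validation of all of it.

## The core model

For one SNP--CpG pair, observations are arranged as *allele rows*. A sample
with genotype information contributes:

* homozygotes: one row with the sample's full counts and allele indicator
  $a \in \{0, 1\}$ (copies of the non-reference allele / 2);
* heterozygotes whose reads can be assigned to alleles: two rows, one per
  allele, holding the allele's methylated/total counts with $a = 0$ and
  $a = 1$;
* heterozygotes without allele-assignable reads: one row with the full
  counts at $a = 1/2$.

Row $t$ of sample $i(t)$ is modelled as

$$y_t \sim \text{Binomial}(r_t, \pi_t), \qquad
  \operatorname{logit}(\pi_t) = \mu + \beta a_t + \alpha^\top x_{i(t)} + u_{i(t)},$$
$$u \sim \text{MVN}(0,\; \sigma_g^2 K + \sigma_e^2 I),$$

with fixed covariates $x_i$ (sequencing batch, sex, age), a relatedness
matrix $K$ from the pedigree (entries for two samples of one individual set
to 1, so repeated measures are absorbed by the same random effect), and an
independent per-sample effect capturing extra-binomial dispersion. The
random effects are shared across the rows of a sample, which is what makes
the within-heterozygote allele contrast informative: the two allele rows
share $u_i$, so their difference estimates $\beta$ free of all sample-level
variation. The genotype-only variant collapses each sample to one row with
$a = \text{dosage}/2$, so $\beta$ is per allele copy in both modes and the
two modes agree exactly when no heterozygote has assignable reads.

### Fitting

The model is fitted by penalized quasi-likelihood (PQL): iteratively
re-weighted working variables $z_t = \eta_t + (y_t - r_t\pi_t)/w_t$,
$w_t = r_t \pi_t (1 - \pi_t)$, with the variance components of the working
linear mixed model re-estimated by REML at every iteration (a 2-d
Nelder--Mead on $(\log\sigma_g^2, \log\sigma_e^2)$). All sample-dimension
algebra runs in the eigenbasis of $K$ (decomposed once and shared across
pairs and permutations) through the Woodbury identity, so one REML
evaluation costs a single $m \times m$ Cholesky. The implementation is in
C++ (RcppArmadillo), which the permutation machinery requires: a mapping
run refits every pair once per permutation.

Numerical choices: convergence tolerance $10^{-5}$ on the fixed effects and
variance components, at most 100 iterations; non-converged pairs are
reported with `converged = FALSE` and their p-values withheld; variance
components are bounded below by (effectively) zero via the log
parameterization, with profile-likelihood ties broken toward smaller
$\sigma_g^2$; a ridge of $10^{-6}$ keeps $K$ positive definite; working
weights are floored at $10^{-6}$. With both components pinned at zero the
fit reduces to a grouped logistic regression and matches IRLS to machine
precision, and at $K = I$, $n = 6$ the fitter's ML flavor
(`method = "ml"`, which drops the REML projection term so the criterion
matches a marginal-likelihood oracle) matches direct maximization of the
quadrature-integrated binomial likelihood to well under the reporting
precision of $\beta$ — both checks are in the test suite. REML remains
the default for mapping because its variance estimates are less biased at
the covariate counts used there.

### Which reads are allele-assignable

Bisulfite chemistry converts unmethylated C to T on the original-top (OT)
strand and, equivalently, G to A on the original-bottom (OB) strand. At a
C/T SNP, an OT-strand read showing T is therefore ambiguous — a true T
allele or a converted unmethylated C. The obvious rule, discarding just
those ambiguous reads, is *biased*: the C-allele reads that survive on that
strand are exactly the methylated ones, so the C allele's methylation
fraction is overestimated. `asmqtl` instead discards the entire strand on
which either called allele is convertible: C/T SNPs are assessed from OB
reads only, A/G SNPs from OT reads only (C/G and A/T SNPs would be
assessable on both strands). We adopted the strand-exclusion rule after
observing the bias directly in null simulations, where the read-level rule
produced median null p-values near 0.01 and systematically positive effect
estimates at A/G SNPs.

## Genotype calling from pileups

Per strand record, an observed base supports an allele with weight
$1-\varepsilon$ when it matches it; the converted base of the strand
(T on OT, A on OB) supports both of its source alleles equally (the
"wildcard"); any other base carries $\varepsilon/3$. A read's likelihood
under a diploid genotype is the mean of its two allele supports, the site
likelihood multiplies over reads and strands, and a uniform prior over the
10 genotypes gives the posterior. Calls require depth $\ge 5$, posterior
above a depth-dependent threshold $\min(0.999,\, 1 - 10^{-1 - d/10})$
(stringency grows with depth; the cap keeps deep sites callable), and at
least two unambiguous reads per called allele. The threshold form is this
package's operationalization of depth-adaptive calling; it is monotone and
simple, and the caller's accuracy is validated against simulated truth:
the acceptance suite requires $\ge$ 90% concordance overall and $\ge$ 95%
at homozygous sites at depth $\ge$ 10, and `scripts/acceptance.R` reports
the realized values.

## Multiple testing

Observed p-values are compared against an empirical null built by refitting
each pair under sample permutations of its genotype data, ten permutations
per chromosome (seeded at base seed + chromosome index), pooled genome-wide.
For a threshold $t$,
$$\widehat{\text{FDR}}(t) = \hat\pi_0\,
  \frac{\overline{\#\{p_{\text{null}} \le t\}}}{\max(1, \#\{p_{\text{obs}} \le t\})},
  \qquad
  \hat\pi_0 = \min\!\Big(1, \frac{\#\{p_{\text{obs}} > 0.5\}}
  {\overline{\#\{p_{\text{null}} > 0.5\}}}\Big),$$
and a pair's q-value is the running minimum of
$\widehat{\text{FDR}}$ over thresholds at or above its p-value. The single
anchor $\lambda = 0.5$ for $\hat\pi_0$ is deliberately crude but robust with
only ten permutations.

Three design choices matter for the permutation null:

1. Dosages are permuted across samples; methylation counts, covariates and
   $K$ stay put (the null of no genetic effect).
2. ASM assignments cannot be moved between samples (they are methylation
   data), so samples that are heterozygous *after* permutation have their
   own reads re-tagged by an exchangeable split — allele totals
   $\text{Binomial}(r, 1/2)$, methylated counts hypergeometric — after
   thinning to the pair's observed assignable-read fraction, so null fits
   carry the same information as the observed fit.
3. Permuted refits start the variance components at the observed pair's
   estimates and freeze them after one short refinement. Beyond speed, this
   coupling is a calibration device: PQL/REML underestimate
   $(\sigma_g^2, \sigma_e^2)$ in small samples, and the underestimate
   inflates observed test statistics (whose genotypes are kinship-aligned)
   more than permuted ones (whose genotypes are not), making uncoupled
   permutation nulls anticonservative. Sharing the observed components
   lets the null inherit the same bias. The shipped calibration suite
   (2,000 null + 500 signal pairs, 20 seeds) verifies that the coupled
   scheme keeps realized FDR of the 5% call set at or below 1.5$\times$
   nominal, and `scripts/acceptance.R` reports a realized value per run.

Storey q-values (smoother $\hat\pi_0(\lambda)$ over a $\lambda$ grid,
cubic smoothing spline, evaluated at $\lambda = 0.95$) serve the eQTL and
correlation scans; below 100 tests the Benjamini--Hochberg adjustment is
returned instead because the $\pi_0$ smoother is unstable there.

## Variance decomposition

Two PVE conventions are implemented. The headline genotype PVE residualizes
the empirical logit $\log\{(y + 0.5)/(r - y + 0.5)\}$ on the covariates and
reports $\operatorname{clip}(\hat\beta^2 \mathrm{Var}(d/2) / \mathrm{Var}(\tilde m), 0, 1)$;
a flag switches the residual to the raw methylation ratio for the
proportion-scale convention, since which scale the field's scripts use is
not standardized. The per-predictor decomposition works on the latent
scale: $\mathrm{PVE}_k = \mathrm{Var}(\hat\theta_k x_k) / (\sum_j
\mathrm{Var}(\hat\theta_j x_j) + \hat\sigma_g^2 + \hat\sigma_e^2)$, with
pairs flagged out when the total estimated variance is not positive.

## cis-eQTL mapping

Expression is first residualized for latent structure with age and sex
protected: regress each gene on (intercept, age, sex), take the top
principal factors of those residuals (SVD over samples), and residualize
the original expression on the factors (five by default). This
deterministic principal-factor scheme plays the role that surrogate
variable analysis plays in practice; it preserves the protect-age-sex
contract and is exactly reproducible. Each SNP within 200 kb of a gene
(distance to the gene-body boundary by default; a flag switches the anchor
to the TSS, since both conventions are common) is tested with
$y = \mu + x\beta_e + \alpha^\top c + u + \epsilon$,
$u \sim \text{MVN}(0, \sigma^2 K_{\text{GRM}})$, where $K_{\text{GRM}}$ is
the centered genotype relationship matrix. REML profiles the variance
ratio in the eigenbasis of $K_{\text{GRM}}$ (one 1-d optimization per
test), covariates are age, sex and RIN, and calls use a 20% FDR.

## Integration and enrichment

meQTL and eQTL call sets intersect on exact SNP position, yielding
SNP--CpG--gene trios; effect-direction concordance is tested against 1/2
with the exact binomial test (denominator: unique trios by default, unique
SNP--gene pairs behind a flag); methylation--expression correlation uses
Spearman's rho with midranks over strictly one-to-one matched samples.
Annotation assigns each site exactly one CpG-context class (island > shore
> shelf > open sea, shores/shelves 2 kb), overlapping gene-feature classes
(promoter = 2 kb upstream of the TSS, exon, intron/UTR = body minus exon),
chromatin states, open-chromatin and DMR flags. Enrichment runs one-tailed
Fisher tests: exact hypergeometric tail p, sample odds ratio with Haldane
0.5 correction on zero cells, normal-approximation CI on the log OR. The
gene-level test permutes CpG significance labels genome-wide (100 times),
recomputes each gene's proportion of significant CpGs among its $\ge 10$
tested CpGs within 50 kb of the body, and classifies genes outside the
5th/95th order statistics of their permuted proportions; with exactly 100
permutations the order statistics themselves are used rather than
interpolated percentiles.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, with
defaults fixed at the study conditions the pipeline targets where those are
stated: negative-binomial read depth with mean 18 per SNP--CpG pair,
bisulfite conversion 0.99, sequencing error 0.01, ~12% of individuals
resampled (repeated measures), founder MAF at least 0.05 (drawn in
[0.1, 0.5]), logit-scale effects with magnitude centred at 0.8,
$\sigma_g^2 = 0.5$, $\sigma_e^2 = 0.3$, and 20% of pairs non-null. Values
the design does not pin down were chosen once as field-plausible: a
founder fraction of 0.4 in a random-mating pedigree; depth dispersion
(negative-binomial size 2, giving the right-skewed depths bisulfite data
show); per-CpG baselines $\mathcal{N}(0, 1)$ on the logit scale
(intermediate methylation, where meQTL are detectable); covariate effects
on 20% of CpGs (age 0.02/yr, sex 0.3, batch 0.3 logit units); 25% C/T
SNPs, the rest A/G; 5% missingness; four autosomes; genes of 5 kb with a
nearest-cis-SNP effect shared with an meQTL for half the genes; three
injected latent expression factors. Sizes (CpGs, pedigree size) are
per-analysis choices; the shipped validation suites state theirs
explicitly — e.g. the FDR-calibration runs use 50 individuals and 2,500
pairs, and effect-recovery runs use 270 individuals (~300 samples) with
100 pairs.

Reads are generated per haplotype: depth is split binomially between a
heterozygote's alleles and between strands, methylation states are drawn
per read group, and observed bases at the SNP follow the conversion
chemistry with sequencing errors, so the genotype caller and the ASM
extractor can be validated against the same truth. Pileups are emitted at
SNP positions only. What the generator does *not* emulate: linkage
disequilibrium beyond pedigree transmission (SNPs transmit independently),
read-level sequence context, CpG-density structure along the genome, or
cell-composition effects; passing tests therefore demonstrate statistical
correctness of the methods under the declared model, not robustness to
those real-data features.

## Known limitations

* PQL underestimates variance components at small sample sizes and low
  depth; the permutation coupling above compensates for FDR control, but
  reported $\hat\sigma^2$ are mildly shrunken.
* The permutation null assumes exchangeability of samples, which family
  structure violates; the coupled-refit scheme mitigates but does not
  remove this (an explicit gene-dropping null would).
* The dynamic posterior threshold makes confident heterozygote calls
  require roughly balanced allele support, so the two-read minor-allele
  rule is nearly always subsumed by it; it is retained as a safety net.
* Heterozygotes with assignable reads contribute only those reads; the
  remainder of their coverage is discarded rather than entering as an
  $a = 1/2$ row, keeping rows conditionally independent at the cost of a
  little information.
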