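---
title: "Methods: genotype-to-splicing association with sqtlkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-to-splicing association with sqtlkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sqtlkit)
```

# Overview

`sqtlkit` chains five statistical stages that together take a cohort from
genotypes and splice-junction read counts to a claim about a shared causal
variant:

1. **PSI quantification** — per-sample inclusion fractions for the elements
   of a local splicing variation (LSV), with quantifiability thresholds;
2. **sQTL association** — inverse-normal transformed PSI against
   residualized dosage, Bonferroni-corrected at the LSV-variant pair level,
   with a genotype-group effect filter;
3. **GWAS** — per-cohort association on standardized residual phenotypes,
   fixed-effects inverse-variance meta-analysis, sex-heterogeneity, and
   genomic inflation;
4. **fine-mapping** — single-causal-variant posteriors from Wakefield
   approximate Bayes factors and 95% credible sets;
5. **colocalization** — the five-hypothesis posterior over a shared variant
   panel, plus RT-PCR percent-intron-retention quantification as an
   orthogonal experimental readout.

Because the individual-level data such analyses are usually run on are
access-controlled, the package ships a synthetic-data module that emulates
the statistical structure every stage assumes. All tests and the
reproduction script run on synthetic data alone.

# The splicing model

## LSVs and PSI

A splice graph holds exons, junctions (keyed by the last exonic base of the
donor and the first exonic base of the acceptor, 1-based inclusive), and
retained introns. An LSV is the set of splicing choices leaving (source) or
entering (target) a reference exon. For LSV element $e$ with read count
$n_e$ in a sample, the Percent Selected Index is the plug-in ratio

$$\Psi_e = \frac{n_e}{\sum_{k \in \text{LSV}} n_k},$$

computed only when the LSV total reaches `min_total_reads` (default 10,
matching the intron-coverage threshold); below it the sample is flagged
unquantifiable rather than set to zero. The plug-in estimator (rather than
a full Bayesian posterior over PSI) is deliberate: every downstream stage
consumes point PSI values, and an optional symmetric pseudo-count is
exposed for stability at low totals (default 0).

Elements enter an LSV only with read support in at least two-thirds of
samples, where support means at least 3 reads across at least 2 distinct
read start positions for a junction, and at least 10 reads for a retained
intron (the higher intron bar reflects how spurious intronic coverage
scales with expression). LSVs reduced below two elements are dropped.
Target LSVs are partially redundant with their source counterparts, so
association testing defaults to source LSVs only.

## Genotype-group summaries

`genotype_group_delta_psi()` reports, on the percent scale, both the
per-genotype median PSI and the expected PSI from the linear dosage
regression. The headline effect size is the **median difference**
$\Delta\Psi = \tilde\Psi_{\text{hom-alt}} - \tilde\Psi_{\text{hom-ref}}$,
which also drives the $|\Delta\Psi| > 10$ effect filter; the
regression-expected difference is reported alongside because both
conventions circulate and they differ under skewed within-group
distributions. An empty homozygous group leaves the difference undefined
and flagged — never silently zero.

# The sQTL association procedure

For each source LSV and each variant within 10 kb (inclusive) of any exon
of the event, with minor allele count ≥ 5 and MAF ≥ 0.1 **among the
PSI-quantifiable samples**, the pipeline:

1. mean-imputes missing dosages from the quantifiable samples;
2. maps each element's PSI vector onto standard-normal quantiles by the
   rank-based transform $\Phi^{-1}((r_i - 0.5)/n)$ with average ranks for
   ties — the offset keeps arguments off 0 and 1 and is symmetric, so any
   tie-free output sums to zero;
3. regresses the covariates (known factors, hidden-factor surrogates,
   genotype PCs) out of both the transformed PSI and the dosage;
4. tests the OLS slope of the PSI residuals on the dosage residuals. The
   two-sided p-value uses $t_{n-c-2}$ where $c$ counts the covariate
   columns regressed out: the two-stage residual-on-residual regression
   must be charged for those degrees of freedom or its type-I error is
   anticonservative at modest $n$.

A pair's p-value is the minimum across the LSV's elements and Bonferroni
correction is applied at the pair level, $p_{\text{adj}} = \min(1, p
\cdot m)$ with $m$ the number of pairs. Collapsing multi-element LSVs by
the minimum is a design choice (the within-LSV rule used in the original
analyses is not documented); since elements of one LSV are strongly
negatively dependent, the minimum is a conservative representative paired
with pair-level correction.

Hidden covariates deserve a note. At transcriptome scale, latent-factor
corrections (PEER-like) are standard, and `run_sqtl(n_psi_pcs = 15)`
appends the top principal components of the transformed PSI matrix in that
role. For a *targeted* analysis of one or a few LSVs — every synthetic
scenario in this package — the top PSI PCs are essentially the tested
signal itself, and regressing them out destroys the association, so the
default is `n_psi_pcs = 0`. This is the one place the package departs from
a transcriptome-scale default on purpose.

Sex-stratified scans rerun the identical procedure per stratum;
`stratified_heterogeneity()` compares two independent stratum estimates
with $z = (b_A - b_B)/\sqrt{SE_A^2 + SE_B^2}$ and a **two-sided** normal
p-value. When checking published stratified results, note that some
stratified-scan tools report the one-sided tail, which is half this value;
back-derive stratum SEs with `qnorm(p/2, lower.tail = FALSE)` because
`1 - p/2` rounds to 1 in double precision once $p < 10^{-16}$.

# GWAS, meta-analysis and fine-mapping

Phenotypes are standardized within sex strata: residual of the outcome on
the stratum covariates, divided by the stratum residual SD. Cohort
association is per-variant OLS on dosage. Fixed-effects inverse-variance
pooling uses $w_i = 1/SE_i^2$, $\hat\beta = \sum w_i b_i / \sum w_i$,
$SE = (\sum w_i)^{-1/2}$, with p-values from the normal approximation (the
convention of the standard meta-analysis tools). Allele alignment flips
swapped and strand-flipped records and drops unresolvable or
strand-ambiguous (A/T, C/G) mismatches with a warning. Genomic inflation
is $\lambda = \mathrm{median}(\chi^2_1)/0.4549$.

Fine-mapping under a single causal variant needs no stochastic search: the
Wakefield approximate Bayes factor

$$\log \mathrm{ABF} = \tfrac12 \log\frac{SE^2}{SE^2 + W}
  + \frac{z^2}{2}\,\frac{W}{SE^2 + W}$$

is exact per variant, and with a uniform prior the posterior inclusion
probabilities are the normalized ABFs (log-sum-exp throughout). The prior
effect variance defaults to $W = 0.04$ (prior SD 0.2 on the standardized
scale), appropriate for a quantitative trait; it is configurable, and
per-variant $\log_{10}$ Bayes factors are reported because their absolute
values are prior-dependent. The 95% credible set is the smallest
posterior-sorted prefix reaching 0.95.

Because the set is a discrete object, its *attained* mass overshoots the
nominal level (the last variant added carries finite mass). In the
package's calibration simulations (one causal variant, $\beta = 0.14$,
$n = 4557$, 50 LD partners, 500 regions) the mean attained mass is ~0.97
and the empirical probability that the causal variant is inside the set is
~0.98 — consistent with the attained mass, i.e. Bayes-calibrated, and
strictly above the nominal 0.95, never below. Users comparing empirical
coverage to the nominal level should expect this conservative overshoot.

Variance explained is reported as the Hardy-Weinberg form
$100 \cdot \beta^2 \, 2f(1-f) / \mathrm{Var}(y)$; an in-sample model $R^2$
generally differs slightly, and neither is asserted to reproduce published
in-sample values. Genotype least-square means come from a three-level
genotype factor plus covariates via `emmeans`, with the homozygote
contrast and its SE. Relatedness corrections (mixed models) are out of
scope: synthetic cohorts are unrelated, and a sample-exclusion hook is the
intended substitute for related samples.

# Colocalization

`coloc_abf()` enumerates the five hypotheses over a shared variant panel
with per-variant priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ (the
defaults of the established Bayesian colocalization methodology). With
per-variant Bayes factors $B_{ti}$ for trait $t$:

- $H_1 \propto p_1 \sum_i B_{1i}$, similarly $H_2$;
- $H_3 \propto p_1 p_2 \big[(\sum_i B_{1i})(\sum_j B_{2j}) - \sum_i
  B_{1i} B_{2i}\big]$ (two distinct causal variants);
- $H_4 \propto p_{12} \sum_i B_{1i} B_{2i}$ (one shared causal variant);
- $H_0 \propto 1$.

All accumulation is in log space; no raw products are formed. With one
shared variant $H_3$ is combinatorially impossible and its posterior is
exactly 0. Colocalization is called at $PP_4 > 0.8$. The sQTL slope is
supplied on the transformed (standard-normal PSI) scale with $W = 0.04$
per trait; absolute $PP_4$ values are mildly sensitive to that scale
choice.

# RT-PCR quantification

Percent intron retention from densitometry is the replicate-averaged
intron-retained band divided by the sum of the three products:

$$\mathrm{PIR} = 100 \cdot \frac{\overline{I_{170}}}
 {\overline{I_{170}} + \overline{I_{196}} + \overline{I_{274}}}$$

(170 nt intron-retained, 196 nt exon-skip, 274 nt exon-include). Band
intensities are assumed background-corrected upstream; a constant
background subtraction is optionally applied. Genotype is coded as
C-allele dosage so the slope sign matches "retention rises with C".
`genotype_correlation()` reports Pearson $r^2$ with the $t$-transform
p-value on $n-2$ df and applies an exclusion filter first, supporting
outlier-exclusion reanalyses (dropping a sample can also silently drop a
genotype class — at $n \le 9$ this changes the answer materially, which
is why the filtered $n$ is always reported).

# The synthetic-data generators

The generators encode the study conditions the tests assume; their
defaults are fixed, not tuning knobs.

**Genotypes.** A first-order copying process over a haplotype pool: each
haplotype carries a latent uniform value retained between adjacent
variants with probability $0.5^{d/\text{ld\_decay}}$ ($d$ = distance in
bp), and the allele is the indicator of that value falling below the
variant's allele frequency. This is the simplest mechanism with tunable,
monotonically decaying LD: the haplotype correlation at one half-distance
is 0.5 by construction. Diploid dosage is the sum of two haplotypes; the
pool is retained as an attribute for LD diagnostics. It makes no claim to
realistic demography, recombination hotspots, or allele-frequency spectra.

**Splicing counts.** Per sample, total LSV depth is Poisson around
`depth_mean` (default 100, a typical well-expressed-gene LSV depth; no
overdispersion by default because none is estimated for the motivating
locus — a Dirichlet-multinomial switch is provided). Each read makes a
multinomial choice among elements. The genotype effect is specified in
percentage points per alternative allele and applied through a logistic
link: at dosage $g$ the shifted element's log-odds move by
$\mathrm{logit}(p + g\delta) - \mathrm{logit}(p)$ and probabilities are
renormalized. With a single shifted element this makes the expected PSI
*exactly* $p + g\delta$ (clamped away from 0 and 1) while staying a valid
probability vector at any dosage — which is why a +10 pp/allele intron
shift on a 10% baseline yields exactly 20 points between homozygotes in
expectation. The packaged `cassette_ir_model()` uses baseline
(skip, include, intron) = (0.55, 0.35, 0.10) with a +10 pp/allele intron
shift at a MAF-0.47 causal variant: a 20-point homozygote contrast on the
percent scale, the regime of a strong intron-retention sQTL.

**Covariates and phenotypes.** Binary sex/platform/protocol columns,
standard-normal hidden factors and genotype-PC columns; phenotypes are
$\sum \beta \cdot \text{dosage}$ plus covariate effects plus Gaussian
noise, with per-sex strata labelled. The GWAS-scale simulations use
$\beta = 0.14$ at MAF 0.41 with unit noise in cohorts of 3510 and 1047 —
the discovery-scale signal-to-noise regime (per-variant $z \approx 6.5$
after pooling).

**Gel bands.** Three intensities proportional to per-sample fractions with
mean-corrected multiplicative log-normal noise (`noise_cv` 0.1 as a
plausible densitometry error); nine samples in three genotype groups with
retention rising 10 pp per C allele emulate a small validation cohort.

**Randomness.** Every generator derives a child seed from its master seed
and a fixed operation label, so one master seed drives a reproducible
multi-stage pipeline and the same call is bit-identical. Growing
`n_samples` redraws the vectorized streams, so per-sample stability under
cohort growth is *not* provided.

What passing tests on these data do show: correct arithmetic of every
estimator; exact agreement with closed forms and brute-force enumerations;
calibrated type-I error, uniform null p-values, and credible-set behavior;
parameter recovery at the simulated effect scales. What they cannot show:
robustness to alignment artifacts, annotation errors, population
stratification beyond simple PCs, relatedness, or overdispersion patterns
of real RNA-seq — the generators are deliberately cleaner than real data.

# Numerical choices and degenerate inputs

- Bayes-factor sums and hypothesis posteriors use log-sum-exp; posteriors
  sum to 1 within 1e-10 by construction.
- The inverse-normal transform refuses vectors with fewer than 3 finite or
  all-identical values; constant-PSI elements are skipped per pair rather
  than failing a scan.
- Residualization checks design rank via QR and names collinear columns.
- PSI conservation is enforced at 1e-9 per quantifiable sample; dosages are
  hard-called in {0, 1, 2} with `NA` missingness, and mean imputation never
  alters observed values.
- Distance windows, MAF and MAC thresholds are inclusive; MAF boundary
  comparison carries a 1e-12 guard against float representation.
- Problem sizes in the shipped tests and reproduction script (2000 null
  pairs at n = 200; 100 replicates of the 208-sample splicing cohort; 200
  colocalization and 500 fine-mapping regions; GWAS cohorts of 3510 +
  1047) are chosen so the full suite completes on one CPU in minutes while
  holding Monte-Carlo error well inside each assertion's tolerance.

# Known limitations

- Single-causal-variant fine-mapping only; no multi-signal search or
  conditional analysis.
- No trans-QTL scanning, interaction models, or FDR alternatives to
  Bonferroni.
- The PSI estimator is the plug-in ratio, not a posterior; uncertainty in
  PSI is not propagated into the association stage.
- VCF is the only genotype dialect (GT fields, biallelic records);
  de novo junction discovery from alignments is out of scope — counts are
  taken as given.
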