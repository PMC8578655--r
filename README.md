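# sqtlkit

Splicing QTL mapping, GWAS meta-analysis, fine-mapping and colocalization
in one reusable R pipeline — with a synthetic-data module so everything is
testable without access-controlled cohort data.

## The problem

Genetic variants that alter mRNA splicing are a major mechanism behind
GWAS signals. Demonstrating one requires chaining several analyses that
usually live in separate tools:

- quantify splicing from junction read counts as **PSI** (percent spliced
  in): for each element of a local splicing variation (LSV — the set of
  splicing choices at a reference exon, alternative junctions and/or a
  retained intron), `PSI_e = n_e / Σ_k n_k`, with support thresholds for
  building events and per-sample quantifiability flags;
- test **sQTL association**: inverse-normal transformed PSI against
  covariate-residualized dosage, `t`-test on the OLS slope with degrees of
  freedom charged for the regressed-out covariates, pair-level Bonferroni
  correction, and a genotype-group effect filter (`|ΔPSI| > 10` points
  between homozygotes);
- run the **GWAS side**: per-cohort association on standardized residual
  phenotypes, fixed-effects inverse-variance meta-analysis
  (`β = Σwᵢbᵢ/Σwᵢ`, `w = 1/se²`), sex-heterogeneity z-tests, genomic
  inflation λ;
- **fine-map** under a single causal variant with Wakefield approximate
  Bayes factors, `log ABF = ½·log(se²/(se²+W)) + z²W/(2(se²+W))`, giving
  exact posterior inclusion probabilities and 95% credible sets;
- **colocalize** the GWAS and sQTL signals over a shared variant panel via
  the five-hypothesis posterior (PP0–PP4, shared causal variant called at
  PP4 > 0.8);
- validate experimentally with **RT-PCR percent intron retention**:
  `PIR = 100·I₁₇₀/(I₁₇₀+I₁₉₆+I₂₇₄)` from gel densitometry, correlated
  with genotype.

`sqtlkit` implements all of these behind one consistent set of R
functions, plus generators for genotypes with tunable MAF and local LD,
genotype-dependent junction counts, covariates, phenotypes, and gel band
intensities. It is aimed at statistical geneticists who want a tested,
deterministic desk-scale implementation of this pipeline — for method
checks, power exploration, and teaching — and at reanalyses where only
summary-level inputs are available.

## Worked example

An intron-retention sQTL in a 208-sample cohort: a cassette-exon +
retained-intron LSV whose causal variant (MAF 0.47) raises retention by
10 percentage points per C allele, scanned together with an LD partner.

```r
library(sqtlkit)

model <- cassette_ir_model()          # baseline PSI (skip, incl, intron) = (.55, .35, .10)
variants <- rbind(model$causal_variant,
                  variant_panel("rs_null", "8", 97000L, "A", "G", 0.30))
geno <- simulate_genotypes(variants, n_samples = 208, ld_decay = 5000, seed = 11)
sim  <- simulate_splicing_counts(geno, model, seed = 11)

res <- run_sqtl(sim$counts, geno, covariates = NULL,
                graph = as_splice_graph(model))
res[, c("variant", "n", "slope", "p_adj", "delta_psi", "passes_effect_filter")]
#>   variant   n     slope        p_adj delta_psi passes_effect_filter
#> 1 rs_null 208 0.5878375 6.881293e-09  9.511596                FALSE
#> 2  rs_sim 208 1.2246682 3.636377e-55 19.459981                 TRUE
```

The causal variant is recovered at `p_adj ≈ 4e-55` with a 19.5-point
median PSI difference between homozygotes (truth: 20), passing the
`|ΔPSI| > 10` filter; the LD partner picks up a residual association but
fails the effect filter. The genotype-group summary behind that ΔPSI:

```r
lsv <- Filter(function(l) l$kind == "source",
              build_quantifiable_lsvs(as_splice_graph(model), sim$counts))[[1]]
psi <- quantify_psi(sim$counts, lsv)
genotype_group_delta_psi(psi, geno, "rs_sim", "IR:100201-100999")
#> delta PSI for IR:100201-100999 at rs_sim
#>   medians (%): 10.00 / 20.20 / 29.46 (n = 55/111/42)
#>   delta PSI = 19.46 (median), 19.64 (expected)
```

And the experimental readout on the packaged synthetic densitometry table
(nine samples, three per genotype):

```r
path <- system.file("extdata", "synthetic_gel_bands.tsv", package = "sqtlkit")
quant <- pir_from_bands(read_band_table(path))
fit <- genotype_correlation(quant)
#> RT-PCR r^2 = 0.96, P = 5.4e-06, n = 9
```

PIR rises from ~10% in TT carriers to ~28% in CC carriers — the
percent-scale signature of a strong intron-retention sQTL.

See `vignettes/sqtlkit-methods.Rmd` for the statistical model behind each
stage, the generator design, and numerical conventions.

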