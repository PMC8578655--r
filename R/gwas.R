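# Cohort association, fixed-effects meta-analysis, inflation, fine-mapping,
# and genotype least-square means.

#' Standardize a phenotype within sex strata
#'
#' Within each stratum, the outcome is regressed on the named covariates and
#' the residual divided by its stratum standard deviation, giving mean-0,
#' sd-1 residuals per stratum.
#'
#' @param pheno `data.frame` with the outcome, covariates, and a stratum
#'   column.
#' @param outcome name of the outcome column.
#' @param covariate_names character vector of covariate column names.
#' @param strata name of the stratum column (e.g. `"sex"`).
#' @return `pheno` with an added column `z`, the standardized residual.
#' @export
standardize_phenotype <- function(pheno, outcome, covariate_names,
                                  strata = "sex") {
  z <- rep(NA_real_, nrow(pheno))
  for (s in unique(pheno[[strata]])) {
    idx <- which(pheno[[strata]] == s)
    if (length(idx) < 10L) {
      warning(sprintf("stratum '%s' has fewer than 10 samples", s))
    }
    sub <- pheno[idx, , drop = FALSE]
    if (length(covariate_names)) {
      f <- stats::reformulate(covariate_names, response = outcome)
      r <- stats::residuals(stats::lm(f, data = sub))
    } else {
      r <- sub[[outcome]] - mean(sub[[outcome]])
    }
    s_sd <- stats::sd(r)
    if (s_sd <= 1e-8 * max(stats::sd(sub[[outcome]]), 1e-300)) {
      stop(sprintf("zero residual variance in stratum '%s'", s))
    }
    z[idx] <- r / s_sd
  }
  pheno$z <- z
  pheno
}

#' Per-variant linear association in one cohort
#'
#' OLS of the standardized residual phenotype on alternative-allele dosage,
#' one variant at a time, returning effect, standard error, two-sided
#' p-value (t distribution), effect-allele frequency, and sample size.
#' Monomorphic variants are skipped with a message.
#'
#' @param z numeric vector of standardized residuals, named by sample or
#'   aligned with the genotype rows.
#' @param genotypes a [genotype_matrix()].
#' @return `data.frame` with columns `variant`, `chrom`, `pos`,
#'   `effect_allele` (ALT), `other_allele` (REF), `eaf`, `beta`, `se`, `p`,
#'   `n`.
#' @export
cohort_association <- function(z, genotypes) {
  dos <- genotypes$dosage
  if (length(z) != nrow(dos)) stop("phenotype and genotypes differ in length")
  if (length(z) < 30L) stop("need at least 30 samples")
  vm <- genotypes$variants
  out <- vector("list", ncol(dos))
  for (j in seq_len(ncol(dos))) {
    g <- dos[, j]
    ok <- !is.na(g) & is.finite(z)
    gg <- g[ok]; yy <- z[ok]
    if (stats::var(gg) == 0) {
      message(sprintf("variant %s monomorphic; skipped", vm$id[j]))
      next
    }
    n <- length(gg)
    gc <- gg - mean(gg); yc <- yy - mean(yy)
    sxx <- sum(gc^2)
    beta <- sum(gc * yc) / sxx
    rss <- sum((yc - beta * gc)^2)
    se <- sqrt(rss / (n - 2) / sxx)
    tval <- beta / se
    out[[j]] <- data.frame(
      variant = vm$id[j], chrom = vm$chrom[j], pos = vm$pos[j],
      effect_allele = vm$alt[j], other_allele = vm$ref[j],
      eaf = mean(gg) / 2, beta = beta, se = se,
      p = 2 * stats::pt(-abs(tval), n - 2), n = n,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

# complement for strand flips
flip_allele <- function(a) chartr("ACGT", "TGCA", a)

#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools per-cohort association records with weights `1/se^2`:
#' `beta = sum(w b) / sum(w)`, `se = 1/sqrt(sum(w))`, p from the normal
#' approximation. Cohort records whose alleles are swapped relative to the
#' first cohort are flipped (beta sign change, eaf reflected); strand flips
#' are resolved by complementing; strand-ambiguous A/T and C/G variants
#' that do not match are dropped with a warning.
#'
#' @param cohorts list of per-cohort `data.frame`s as returned by
#'   [cohort_association()].
#' @return `data.frame` with the pooled fields plus `n_cohorts` and, for
#'   each variant, the total sample size.
#' @export
meta_fixed_ivw <- function(cohorts) {
  stopifnot(length(cohorts) >= 1L)
  ref <- cohorts[[1L]]
  variants <- ref$variant
  out <- vector("list", length(variants))
  for (i in seq_along(variants)) {
    v <- variants[i]
    ea <- ref$effect_allele[i]; oa <- ref$other_allele[i]
    betas <- ses <- eafs <- ns <- numeric(0)
    for (co in cohorts) {
      r <- co[co$variant == v, ]
      if (nrow(r) == 0L) next
      b <- r$beta; f <- r$eaf
      if (r$effect_allele == ea && r$other_allele == oa) {
        # aligned
      } else if (r$effect_allele == oa && r$other_allele == ea) {
        b <- -b; f <- 1 - f
      } else if (flip_allele(r$effect_allele) == ea &&
                 flip_allele(r$other_allele) == oa) {
        # strand flip, same orientation
      } else if (flip_allele(r$effect_allele) == oa &&
                 flip_allele(r$other_allele) == ea) {
        b <- -b; f <- 1 - f
      } else {
        warning(sprintf("variant %s: alleles unresolvable (%s/%s vs %s/%s); cohort dropped",
                        v, r$effect_allele, r$other_allele, ea, oa))
        next
      }
      if (ea == flip_allele(oa) && !(r$effect_allele == ea &&
                                     r$other_allele == oa)) {
        warning(sprintf("variant %s is strand-ambiguous (%s/%s); cohort dropped",
                        v, ea, oa))
        next
      }
      betas <- c(betas, b); ses <- c(ses, r$se)
      eafs <- c(eafs, f); ns <- c(ns, r$n)
    }
    if (!length(betas)) next
    w <- 1 / ses^2
    beta <- sum(w * betas) / sum(w)
    se <- 1 / sqrt(sum(w))
    out[[i]] <- data.frame(
      variant = v, chrom = ref$chrom[i], pos = ref$pos[i],
      effect_allele = ea, other_allele = oa,
      eaf = sum(w * eafs) / sum(w), beta = beta, se = se,
      p = 2 * stats::pnorm(-abs(beta / se)), n = sum(ns),
      n_cohorts = length(betas), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Sex-heterogeneity test between two meta-analysis strata
#'
#' Identical contract to [stratified_heterogeneity()]; provided under the
#' GWAS-facing name.
#'
#' @inheritParams stratified_heterogeneity
#' @return list with `z` and `p_het`.
#' @export
sex_heterogeneity <- function(beta_a, se_a, beta_b, se_b) {
  stratified_heterogeneity(beta_a, se_a, beta_b, se_b)
}

#' Genomic inflation factor lambda
#'
#' Median of the 1-df chi-square statistics implied by the p-values,
#' divided by the null median `qchisq(0.5, 1)` (0.4549...).
#'
#' @param p_values vector of p-values in (0, 1], at least 100 of them.
#' @return scalar lambda.
#' @export
genomic_lambda <- function(p_values) {
  if (length(p_values) < 100L) stop("need at least 100 p-values")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Single-causal-variant fine-mapping via approximate Bayes factors
#'
#' Computes Wakefield log approximate Bayes factors per variant,
#' `log ABF = 0.5 log(se^2 / (se^2 + W)) + z^2 W / (2 (se^2 + W))`, turns
#' them into posterior inclusion probabilities under a single causal
#' variant with a uniform prior (log-sum-exp normalization), and reports
#' the smallest posterior-sorted set of variants reaching the coverage
#' level. This is the exact single-causal configuration of Bayes-factor
#' fine-mapping; no stochastic search is needed for one causal variant.
#'
#' @param records `data.frame` with columns `variant`, `beta`, `se` (at
#'   least 2 variants, all `se > 0`).
#' @param W prior variance of the effect size (default 0.04, i.e. prior
#'   effect SD 0.2 on the standardized scale).
#' @param coverage credible-set coverage level.
#' @return object of class `credible_set`: list with `records` (input plus
#'   `log_abf`, `log10_bf`, `pip`), `members` (variant ids in the set,
#'   posterior-sorted), `coverage`, and `W`.
#' @export
abf_finemap <- function(records, W = 0.04, coverage = 0.95) {
  if (W <= 0) stop("prior variance W must be positive")
  if (nrow(records) < 2L) stop("need at least 2 variants")
  if (any(records$se <= 0)) stop("all standard errors must be positive")
  labf <- log_abf(records$beta, records$se, W)
  pip <- exp(labf - logsumexp(labf))
  ord <- order(pip, decreasing = TRUE)
  cum <- cumsum(pip[ord])
  n_set <- which(cum >= coverage - 1e-12)[1L]
  records$log_abf <- labf
  records$log10_bf <- labf / log(10)
  records$pip <- pip
  structure(list(records = records,
                 members = records$variant[ord[seq_len(n_set)]],
                 coverage = coverage, W = W),
            class = "credible_set")
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf("%d%% credible set: %d of %d variants (W = %s)\n",
              round(100 * x$coverage), length(x$members),
              nrow(x$records), fmt(x$W)))
  cat("  top:", utils::head(x$members, 5), "\n")
  invisible(x)
}

#' Phenotypic variance explained by one variant
#'
#' `100 * beta^2 * 2 * eaf * (1 - eaf) / phenotype_variance`, the
#' Hardy-Weinberg dosage variance times the squared per-allele effect, as a
#' percent of the phenotype variance.
#'
#' @param beta per-allele effect.
#' @param eaf effect-allele frequency in (0, 1).
#' @param phenotype_variance variance of the phenotype (1 for a
#'   standardized outcome).
#' @return percent of variance explained.
#' @export
variance_explained <- function(beta, eaf, phenotype_variance = 1) {
  if (eaf <= 0 || eaf >= 1) stop("eaf must lie in (0, 1)")
  if (phenotype_variance <= 0) stop("phenotype variance must be positive")
  100 * beta^2 * 2 * eaf * (1 - eaf) / phenotype_variance
}

#' Covariate-adjusted genotype means (least-square means)
#'
#' Fits a linear model with genotype as a three-level factor plus
#' covariates, and reports the adjusted mean outcome per genotype at the
#' covariate averages together with the homozygote contrast
#' (hom-alt minus hom-ref) and its standard error.
#'
#' @param pheno `data.frame` holding the outcome and covariates.
#' @param outcome name of the outcome column.
#' @param genotype integer vector of dosages 0/1/2 aligned with `pheno`
#'   rows; all three classes must be present.
#' @param covariate_names character vector of covariate columns (may be
#'   empty).
#' @return list with `means` (a `data.frame`: genotype, lsmean, se) and
#'   `contrast` (estimate, se, p for hom-alt vs hom-ref).
#' @export
genotype_lsmeans <- function(pheno, outcome, genotype,
                             covariate_names = character(0)) {
  g <- factor(round(genotype), levels = 0:2)
  if (any(table(g) == 0L)) stop("all three genotype classes must be present")
  dat <- cbind(pheno, .geno = g)
  rhs <- c(".geno", covariate_names)
  f <- stats::reformulate(rhs, response = outcome)
  fit <- stats::lm(f, data = dat)
  a <- stats::alias(fit)
  if (!is.null(a$Complete)) {
    stop("design is rank-deficient: a covariate is confounded with genotype")
  }
  em <- emmeans::emmeans(fit, specs = ".geno")
  ems <- as.data.frame(em)
  ct <- as.data.frame(emmeans::contrast(
    em, method = list("hom_alt - hom_ref" = c(-1, 0, 1))))
  list(
    means = data.frame(genotype = 0:2, lsmean = ems$emmean, se = ems$SE),
    contrast = list(estimate = ct$estimate, se = ct$SE, p = ct$p.value)
  )
}
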