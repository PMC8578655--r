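make_pheno <- function(n = 400, seed = 1) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("S%04d", 1:n),
    age = rnorm(n, 10, 0.5),
    bmi = rnorm(n, 17.5, 2.5),
    sex = rep(c("M", "F"), length.out = n),
    skeletal_age = rnorm(n, 9.5, 1.2),
    stringsAsFactors = FALSE)
}

test_that("phenotype standardization yields mean-0 sd-1 per-sex residuals", {
  ph <- make_pheno()
  ph$skeletal_age <- ph$skeletal_age + 0.4 * ph$age + 0.05 * ph$bmi
  out <- standardize_phenotype(ph, "skeletal_age", c("age", "bmi"), "sex")
  for (s in c("M", "F")) {
    z <- out$z[out$sex == s]
    expect_equal(mean(z), 0, tolerance = 1e-10)
    expect_equal(sd(z), 1, tolerance = 1e-10)
    # residuals orthogonal to the covariates within the stratum
    expect_lt(abs(cor(z, out$age[out$sex == s])), 1e-8)
    expect_lt(abs(cor(z, out$bmi[out$sex == s])), 1e-8)
  }
  # covariates explaining nothing reduce to centering and scaling
  ph2 <- make_pheno(seed = 2)
  out2 <- standardize_phenotype(ph2, "skeletal_age", character(0), "sex")
  m <- ph2$sex == "M"
  expect_equal(out2$z[m],
               as.vector(scale(ph2$skeletal_age[m])), tolerance = 1e-10)
})

test_that("a phenotype exactly linear in a covariate is degenerate", {
  ph <- make_pheno()
  ph$skeletal_age <- 2 * ph$age
  expect_error(
    standardize_phenotype(ph, "skeletal_age", "age", "sex"),
    "zero residual variance")
})

test_that("cohort association recovers a noiseless dosage effect", {
  g <- simulate_genotypes(toy_panel(3, maf = 0.4), 200, seed = 5)
  z <- 0.5 * g$dosage[, 2]
  res <- cohort_association(z, g)
  r2 <- res[res$variant == "v002", ]
  expect_equal(r2$beta, 0.5, tolerance = 1e-9)
  expect_lt(r2$p, 1e-200)
  expect_equal(r2$eaf, mean(g$dosage[, 2]) / 2)
})

test_that("monomorphic variants are skipped with a message", {
  dos <- cbind(v1 = rep(1L, 50), v2 = rep(c(0L, 1L), 25))
  rownames(dos) <- sprintf("S%04d", 1:50)
  g <- genotype_matrix(dos, data.frame(id = c("v1", "v2"), chrom = "1",
                                       pos = c(1L, 2L), ref = "A",
                                       alt = "G", maf = c(0.5, 0.25)))
  expect_message(res <- cohort_association(rnorm(50), g), "monomorphic")
  expect_identical(res$variant, "v2")
})

test_that("null GWAS p-values are uniform", {
  g <- simulate_genotypes(
    variant_panel(sprintf("n%04d", 1:2000),
                  "1", seq(1L, by = 100000L, length.out = 2000), "A", "G",
                  rep(0.3, 2000)),
    400, ld_decay = 10, seed = 8)
  set.seed(9)
  res <- cohort_association(rnorm(400), g)
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("IVW meta-analysis matches its closed form", {
  one <- data.frame(variant = "v", chrom = "8", pos = 1L,
                    effect_allele = "A", other_allele = "G", eaf = 0.41,
                    beta = 0.14, se = 0.02, p = 2.7e-12, n = 3510,
                    stringsAsFactors = FALSE)
  expect_equal(meta_fixed_ivw(list(one))$beta, 0.14)
  expect_equal(meta_fixed_ivw(list(one))$se, 0.02)

  two <- one; two$beta <- 0.2; two$se <- 0.05
  m2 <- meta_fixed_ivw(list(two, two))
  expect_equal(m2$beta, 0.2)
  expect_equal(m2$se, 0.05 / sqrt(2), tolerance = 1e-12)

  a <- one; a$beta <- 0.1; a$se <- 0.1
  b <- one; b$beta <- 0.3; b$se <- 0.2
  m <- meta_fixed_ivw(list(a, b))
  expect_equal(m$beta, 0.14, tolerance = 1e-12)
  expect_equal(m$se, 0.0894427191, tolerance = 1e-9)
  # pooled beta bounded by the cohort betas
  expect_true(m$beta >= 0.1 && m$beta <= 0.3)
})

test_that("allele alignment flips swapped records and drops ambiguous ones", {
  a <- data.frame(variant = "v", chrom = "8", pos = 1L,
                  effect_allele = "A", other_allele = "G", eaf = 0.4,
                  beta = 0.2, se = 0.1, p = 0.05, n = 100,
                  stringsAsFactors = FALSE)
  swapped <- a
  swapped$effect_allele <- "G"; swapped$other_allele <- "A"
  swapped$beta <- -0.2; swapped$eaf <- 0.6
  m <- meta_fixed_ivw(list(a, swapped))
  expect_equal(m$beta, 0.2, tolerance = 1e-12)
  expect_equal(m$n_cohorts, 2L)

  amb <- a
  amb$effect_allele <- "T"; amb$other_allele <- "A"  # A/T ambiguous
  bad <- amb; bad$effect_allele <- "C"; bad$other_allele <- "T"
  expect_warning(m2 <- meta_fixed_ivw(list(amb, bad)), "ambiguous|unresolvable")
  expect_equal(m2$n_cohorts, 1L)
})

test_that("sex heterogeneity reproduces the published stratified contrast", {
  expect_equal(sex_heterogeneity(0.14, 0.02, 0.14, 0.02)$p_het, 1)
  # boys beta 0.20 (P = 1.7e-10), girls beta 0.10 (P = 0.001); SEs
  # back-derived from the stratum p-values
  se_b <- 0.20 / qnorm(1.7e-10 / 2, lower.tail = FALSE)
  se_g <- 0.10 / qnorm(0.001 / 2, lower.tail = FALSE)
  het <- sex_heterogeneity(0.20, se_b, 0.10, se_g)
  expect_equal(het$p_het, 0.02, tolerance = 0.005 / 0.02)
  expect_equal(sex_heterogeneity(0.2, 0.05, -0.2, 0.05)$z, 5.656854,
               tolerance = 1e-6)
})

test_that("genomic lambda behaves at its reference points", {
  expect_equal(genomic_lambda(rep(0.5, 200)), 1.0)
  set.seed(4)
  p <- runif(1e5)
  expect_equal(genomic_lambda(p), 1.0, tolerance = 0.01)
  expect_gt(genomic_lambda(p / 2), genomic_lambda(p))
  expect_error(genomic_lambda(c(rep(0.5, 100), 0)), "0, 1")
  expect_error(genomic_lambda(rep(0.5, 99)), "100")
})

test_that("ABF fine-mapping resolves symmetric and dominant signals", {
  rec <- data.frame(variant = c("a", "b"), beta = 0.14, se = 0.02)
  cs <- abf_finemap(rec)
  expect_equal(cs$records$pip, c(0.5, 0.5), tolerance = 1e-12)
  expect_setequal(cs$members, c("a", "b"))

  rec9 <- data.frame(variant = sprintf("v%d", 1:10),
                     beta = c(7 * 0.03, rep(0, 9)), se = 0.03)
  cs9 <- abf_finemap(rec9)
  expect_identical(cs9$members, "v1")
  expect_equal(sum(cs9$records$pip), 1, tolerance = 1e-12)
  expect_error(abf_finemap(rec9, W = 0), "positive")
  expect_error(abf_finemap(rec9[1, , drop = FALSE]), "2 variants")
})

test_that("variance explained follows the Hardy-Weinberg dosage formula", {
  expect_equal(variance_explained(0, 0.3), 0)
  expect_equal(variance_explained(1, 0.5, 1), 50)
  expect_equal(variance_explained(0.14, 0.41, 1), 0.948248,
               tolerance = 1e-6)
  expect_error(variance_explained(0.1, 0), "eaf")
  expect_error(variance_explained(0.1, 0.4, 0), "positive")
})

test_that("genotype least-square means recover known group offsets", {
  set.seed(11)
  n <- 300
  geno <- rep(0:2, each = n / 3)
  ph <- data.frame(age = rnorm(n, 10), stringsAsFactors = FALSE)
  ph$y <- 0.25 * geno + 0.3 * ph$age + rnorm(n, sd = 0.5)
  fit <- genotype_lsmeans(ph, "y", geno, "age")
  expect_equal(fit$contrast$estimate, 0.5,
               tolerance = 2 * fit$contrast$se / 0.5)
  # without covariates the adjusted means are the raw group means
  fit0 <- genotype_lsmeans(ph, "y", geno)
  raw <- tapply(ph$y, geno, mean)
  expect_equal(fit0$means$lsmean, as.vector(raw), tolerance = 1e-10)
  # perfectly confounded covariate is a rank error
  ph$conf <- geno
  expect_error(genotype_lsmeans(ph, "y", geno, "conf"), "rank|confounded")
  expect_error(genotype_lsmeans(ph, "y", rep(0:1, 150)), "three genotype")
})
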