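# builds a quantified toy LSV plus genotypes for pair-filter tests
pair_fixture <- function(n = 60, positions = c(89999L, 90000L, 99500L),
                         mafs = c(0.3, 0.3, 0.3), seed = 11) {
  m <- toy_model()
  vp <- variant_panel(sprintf("p%d", seq_along(positions)), "8", positions,
                      "A", "G", mafs)
  vp <- rbind(vp, m$causal_variant)
  g <- simulate_genotypes(vp, n, seed = seed)
  sim <- simulate_splicing_counts(g, m, seed = seed)
  lsvs <- Filter(function(l) l$kind == "source",
                 build_quantifiable_lsvs(toy_graph(), sim$counts))
  psi <- lapply(lsvs, function(l) quantify_psi(sim$counts, l))
  list(lsvs = lsvs, psi = psi, g = g, sim = sim)
}

test_that("the 10-kb distance window is inclusive", {
  # event exons span 100000-102300; 90000 is exactly 10 kb from exon 1
  fx <- pair_fixture(positions = c(89999L, 90000L, 99500L))
  pairs <- enumerate_test_pairs(fx$lsvs, fx$psi, fx$g)
  expect_false("p1" %in% pairs$variant_id)  # 10,001 bp away
  expect_true("p2" %in% pairs$variant_id)   # exactly 10,000 bp
  expect_equal(pairs$distance_bp[pairs$variant_id == "p2"], 10000)
})

test_that("MAF and MAC are computed on the quantifiable-sample subset", {
  fx <- pair_fixture(n = 40)
  # make half the samples unquantifiable and concentrate the minor allele
  # in them: whole-cohort MAC stays >= 5 but the subset MAC drops below
  psi <- fx$psi[[1]]
  g <- fx$g
  dos <- g$dosage
  quant_names <- colnames(psi$psi)[!is.na(psi$psi[1, ])]
  carriers <- which(dos[, "p3"] > 0)
  drop <- rownames(dos)[carriers[seq_len(max(0, length(carriers) - 2))]]
  psi$psi[, drop] <- NA
  subset_dos <- dos[setdiff(quant_names, drop), "p3"]
  expect_lt(min(sum(subset_dos), 2 * length(subset_dos) - sum(subset_dos)), 5)
  expect_gte(min(sum(dos[, "p3"]), 2 * nrow(dos) - sum(dos[, "p3"])), 5)
  pairs <- enumerate_test_pairs(fx$lsvs, list(psi), g)
  expect_false("p3" %in% pairs$variant_id)
})

test_that("a variant at MAF exactly 0.1 is included", {
  n <- 60
  dos <- matrix(0L, n, 1, dimnames = list(sprintf("S%04d", 1:n), "vx"))
  dos[1:12, 1] <- 1L  # 12/120 alleles = 0.1, MAC 12
  g <- genotype_matrix(dos, data.frame(id = "vx", chrom = "8",
                                       pos = 100100L, ref = "A", alt = "G",
                                       maf = 0.1))
  fx <- pair_fixture(n = n)
  pairs <- enumerate_test_pairs(fx$lsvs, fx$psi, g)
  expect_true("vx" %in% pairs$variant_id)
  expect_equal(pairs$maf[pairs$variant_id == "vx"], 0.1)
})

test_that("mean imputation fills missing dosages from quantifiable samples", {
  expect_equal(impute_genotypes(c(0, 1, 2, 1, NA)), c(0, 1, 2, 1, 1))
  x <- c(0, 1, 2)
  expect_identical(impute_genotypes(x), x)
  expect_error(impute_genotypes(c(NA_real_, NA_real_)), "no observed")
  # mask restricts the donor pool
  expect_equal(impute_genotypes(c(2, 0, NA), c(TRUE, FALSE, TRUE))[3], 2)
})

test_that("inverse normal transform matches the offset rank formula", {
  out <- inverse_normal_transform(c(3, 1, 2))
  expect_equal(out, c(qnorm(5 / 6), qnorm(1 / 6), 0), tolerance = 1e-7)
  expect_equal(out[1], 0.9674216, tolerance = 1e-6)
  # ties share their average rank
  tied <- inverse_normal_transform(c(1, 1, 2))
  expect_equal(tied[1], tied[2])
  # the symmetric rank offsets make any tie-free output sum to zero
  set.seed(3)
  for (x in list(rnorm(11), rexp(20), c(9, 4, 7, 2, 8.5))) {
    expect_lt(abs(sum(inverse_normal_transform(x))), 1e-9)
  }
  expect_error(inverse_normal_transform(c(1, 1, 1, 1)), "constant")
  expect_error(inverse_normal_transform(c(1, 2)), "3 finite")
})

test_that("residualization is an exact least-squares projection", {
  set.seed(42)
  n <- 50
  covs <- data.frame(a = rnorm(n), b = rnorm(n), s = rbinom(n, 1, 0.5))
  y <- rnorm(n)
  res <- residualize(y, covs)
  # brute-force oracle: explicit projection matrix
  x <- cbind(1, as.matrix(covs))
  p_mat <- x %*% solve(crossprod(x)) %*% t(x)
  expect_equal(res, as.vector((diag(n) - p_mat) %*% y), tolerance = 1e-10)
  expect_true(all(abs(crossprod(x, res)) < 1e-8 * n))
  # a covariate equal to the feature leaves nothing
  expect_true(all(abs(residualize(covs$a, covs)) < 1e-12))
  # intercept-only centering
  expect_equal(residualize(y), y - mean(y))
  # rank deficiency names the collinear column
  covs$dup <- covs$a
  expect_error(residualize(y, covs), "dup")
})

test_that("association statistics behave at the extremes", {
  set.seed(7)
  x <- rnorm(20)
  fit <- test_association(2.5 * x, x)
  expect_lt(fit$p, 1e-12)
  expect_gt(fit$slope, 0)
  expect_equal(fit$slope, 2.5, tolerance = 1e-9)
  expect_error(test_association(rnorm(10), rep(1, 10)), "constant")
})

test_that("the t-based p agrees with a permutation oracle at small n", {
  set.seed(123)
  n <- 15
  x <- rnorm(n)
  y <- 0.4 * x + rnorm(n)
  obs <- test_association(y, x)
  nperm <- 10000
  xc <- x - mean(x); yc <- y - mean(y)
  t_of <- function(xp) {
    sxx <- sum(xp^2)
    b <- sum(xp * yc) / sxx
    rss <- sum((yc - b * xp)^2)
    abs(b / sqrt(rss / (n - 2) / sxx))
  }
  perm <- replicate(nperm, t_of(sample(xc)))
  p_perm <- mean(perm >= abs(obs$statistic))
  mc_se <- sqrt(p_perm * (1 - p_perm) / nperm)
  expect_lt(abs(obs$p - p_perm), 2 * mc_se + 1e-8)
})

test_that("null association p-values are uniform", {
  set.seed(31)
  n <- 100
  covs <- data.frame(a = rnorm(n), b = rnorm(n))
  ps <- replicate(2000, {
    y <- residualize(inverse_normal_transform(rnorm(n)), covs)
    x <- residualize(rbinom(n, 2, 0.3), covs)
    test_association(y, x, n_covariates = 2)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("heterogeneity z-test matches its closed form and published stratified effects", {
  expect_equal(stratified_heterogeneity(0.5, 0.1, 0.5, 0.2)$p_het, 1)
  expect_equal(stratified_heterogeneity(1, 0.1, -1, 0.1)$z, 14.14214,
               tolerance = 1e-6)
  # sex-stratified intron-retention slopes with SEs back-derived from the
  # stratum p-values: the two-sided heterogeneity p equals its closed form,
  # and its one-sided tail is the 0.13 convention seen in stratified scans
  se_m <- 0.78 / qnorm(9.7e-24 / 2, lower.tail = FALSE)
  se_f <- 0.65 / qnorm(5.59e-14 / 2, lower.tail = FALSE)
  het <- stratified_heterogeneity(0.78, se_m, 0.65, se_f)
  z_expected <- 0.13 / sqrt(se_m^2 + se_f^2)
  expect_equal(het$z, z_expected, tolerance = 1e-12)
  expect_equal(het$p_het, 0.2633146, tolerance = 1e-6)
  expect_equal(het$p_het / 2, 0.13, tolerance = 0.015 / 0.13)
  expect_error(stratified_heterogeneity(1, 0, 1, 0.1), "positive")
})

test_that("run_sqtl applies pair-level Bonferroni and is order-invariant", {
  fx <- pair_fixture(n = 120, positions = c(95000L, 98000L),
                     mafs = c(0.3, 0.4), seed = 19)
  cov <- simulate_covariates(120, n_hidden = 2, n_geno_pc = 0,
                             binary = c(sex = 0.5), seed = 19)
  cov$sample_id <- rownames(fx$g$dosage)
  res <- run_sqtl(fx$sim$counts, fx$g, cov, toy_graph())
  m <- attr(res, "m_pairs")
  expect_equal(res$p_adj, pmin(1, res$p * m))
  # shuffling the sample order leaves p-values unchanged
  perm <- sample(nrow(fx$g$dosage))
  g2 <- genotype_matrix(fx$g$dosage[perm, , drop = FALSE], fx$g$variants)
  cnt2 <- fx$sim$counts
  cnt2$counts <- cnt2$counts[, perm]
  cnt2$positions <- cnt2$positions[, perm]
  res2 <- run_sqtl(cnt2, g2, cov, toy_graph())
  expect_equal(res2$p, res$p, tolerance = 1e-10)
  # dropping a variant changes m and p_adj but never the raw p
  keep <- fx$g$variants$id != "p1"
  g3 <- genotype_matrix(fx$g$dosage[, keep, drop = FALSE],
                        fx$g$variants[keep, ])
  res3 <- run_sqtl(fx$sim$counts, g3, cov, toy_graph())
  expect_equal(attr(res3, "m_pairs"), m - 1L)
  shared <- intersect(res3$variant, res$variant)
  expect_equal(res3$p[match(shared, res3$variant)],
               res$p[match(shared, res$variant)], tolerance = 1e-12)
  expect_equal(res3$p_adj, pmin(1, res3$p * (m - 1L)))
})

test_that("the causal variant wins the scan and passes the effect filter", {
  m <- toy_model(delta_psi_per_allele = c(0, 0, 12.5))  # 25 points hom-hom
  vp <- rbind(toy_panel(12, maf = 0.3, from = 95000L, to = 104000L),
              m$causal_variant)
  hits <- vapply(1:25, function(s) {
    g <- simulate_genotypes(vp, 200, seed = 5000 + s)
    sim <- simulate_splicing_counts(g, m, seed = 6000 + s)
    res <- run_sqtl(sim$counts, g, NULL, toy_graph())
    top <- res[which.min(res$p_adj), ]
    top$variant == "rs_sim" && top$passes_effect_filter
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("power rises with effect size and sample size", {
  cell <- function(shift, n) {
    mean(vapply(1:3, function(s) {
      m <- toy_model(delta_psi_per_allele = c(0, 0, shift))
      g <- simulate_genotypes(m$causal_variant, n,
                              seed = 100 + n + shift + 17 * s)
      sim <- simulate_splicing_counts(g, m, seed = 200 + n + shift + 31 * s)
      res <- run_sqtl(sim$counts, g, NULL, toy_graph())
      -log10(res$p[res$variant == "rs_sim"])
    }, numeric(1)))
  }
  grid_p <- sapply(c(4, 8, 12), function(shift) {
    sapply(c(60, 120, 240), function(n) cell(shift, n))
  })
  # signal strength grows along both axes of the 3x3 grid
  expect_true(all(diff(rowMeans(grid_p)) > 0))
  expect_true(all(diff(colMeans(grid_p)) > 0))
})
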