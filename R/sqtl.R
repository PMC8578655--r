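# The sQTL association pipeline: pair filtering, transforms, residualization,
# linear association, Bonferroni correction, and effect-size filtering.

#' Enumerate testable LSV-variant pairs
#'
#' A pair is kept when, among the samples for which the LSV is quantifiable,
#' the variant has minor allele count of at least `mac_min` and minor allele
#' frequency of at least `maf_min` (both boundaries inclusive), and the
#' variant lies within `window_bp` of the nearest base of any exon
#' associated with the splicing event.
#'
#' @param lsvs list of `lsv` objects.
#' @param psi_list list of [psi_matrix()] objects parallel to `lsvs`.
#' @param genotypes a [genotype_matrix()].
#' @param window_bp distance window in bp (inclusive).
#' @param mac_min minimum minor allele count among quantifiable samples.
#' @param maf_min minimum minor allele frequency among quantifiable samples.
#' @return `data.frame` with one row per retained pair: `lsv_id`,
#'   `variant_id`, `n_quantifiable`, `maf`, `mac`, `distance_bp`.
#' @export
enumerate_test_pairs <- function(lsvs, psi_list, genotypes,
                                 window_bp = 10000, mac_min = 5,
                                 maf_min = 0.1) {
  stopifnot(length(lsvs) == length(psi_list))
  vmeta <- genotypes$variants
  rows <- list()
  for (i in seq_along(lsvs)) {
    lsv <- lsvs[[i]]
    psi <- psi_list[[i]]
    samples <- intersect(colnames(psi$psi), rownames(genotypes$dosage))
    if (length(samples) == 0L) stop("no overlap between PSI and genotype samples")
    quant <- samples[!is.na(psi$psi[1L, samples])]
    if (length(quant) == 0L) next
    ex <- lsv$event_exons
    for (v in seq_len(nrow(vmeta))) {
      pos <- vmeta$pos[v]
      dist <- min(pmax(0L, pmax(ex$start - pos, pos - ex$end)))
      if (dist > window_bp) next
      d <- genotypes$dosage[quant, vmeta$id[v]]
      d <- d[!is.na(d)]
      if (length(d) == 0L) next
      s <- sum(d)
      mac <- min(s, 2 * length(d) - s)
      af <- s / (2 * length(d))
      maf <- min(af, 1 - af)
      if (mac < mac_min || maf < maf_min - 1e-12) next
      rows[[length(rows) + 1L]] <- data.frame(
        lsv_id = lsv$id, variant_id = vmeta$id[v],
        n_quantifiable = length(quant), maf = maf, mac = mac,
        distance_bp = dist, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(lsv_id = character(), variant_id = character(),
                      n_quantifiable = integer(), maf = numeric(),
                      mac = numeric(), distance_bp = numeric()))
  }
  do.call(rbind, rows)
}

#' Mean-impute missing genotype dosages
#'
#' Missing dosages are replaced by the mean observed dosage over the
#' quantifiable samples; observed entries are untouched.
#'
#' @param dosages numeric vector with possible `NA`.
#' @param quantifiable_mask logical vector marking the samples whose PSI was
#'   quantifiable (defaults to all).
#' @return complete numeric vector.
#' @export
impute_genotypes <- function(dosages,
                             quantifiable_mask = rep(TRUE, length(dosages))) {
  obs <- dosages[quantifiable_mask & !is.na(dosages)]
  if (length(obs) == 0L) stop("no observed dosage among quantifiable samples")
  dosages[is.na(dosages)] <- mean(obs)
  dosages
}

#' Rank-based inverse normal transform
#'
#' Maps values onto standard-normal quantiles via
#' `qnorm((rank - 0.5) / n)` with average ranks for ties; the offset keeps
#' the arguments away from 0 and 1 and makes the output of any input
#' symmetric around zero.
#'
#' @param values numeric vector with at least 3 finite values, not all
#'   identical; `NA`s are preserved in place.
#' @return transformed vector on the standard-normal scale.
#' @examples
#' inverse_normal_transform(c(3, 1, 2))  # 0.9674 -0.9674 0
#' @export
inverse_normal_transform <- function(values) {
  ok <- is.finite(values)
  x <- values[ok]
  if (length(x) < 3L) stop("need at least 3 finite values")
  if (max(x) == min(x)) stop("constant vector cannot be transformed")
  r <- rank(x, ties.method = "average")
  out <- values
  out[ok] <- stats::qnorm((r - 0.5) / length(x))
  out
}

# covariate design matrix with intercept; errors name collinear columns
covariate_design <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1,
                                         dimnames = list(NULL, "intercept")))
  if (is.data.frame(covariates)) {
    covariates <- covariates[, setdiff(names(covariates), "sample_id"),
                             drop = FALSE]
    x <- stats::model.matrix(~ ., data = covariates)
  } else {
    x <- cbind(intercept = 1, as.matrix(covariates))
  }
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    drop <- colnames(x)[qrx$pivot[(qrx$rank + 1L):ncol(x)]]
    stop(sprintf("covariate design is rank-deficient; collinear columns: %s",
                 paste(drop, collapse = ", ")))
  }
  x
}

#' Regress covariates out of a matrix of features
#'
#' Replaces every feature (column) by its least-squares residual on the
#' covariates plus an intercept. Residuals are orthogonal to every covariate
#' column.
#'
#' @param mat numeric matrix or vector, samples x features.
#' @param covariates covariate `data.frame` (a `sample_id` column is
#'   ignored), numeric matrix, or `NULL` for intercept-only centering.
#' @return residual matrix (or vector, matching the input shape).
#' @export
residualize <- function(mat, covariates = NULL) {
  vec <- is.null(dim(mat))
  m <- as.matrix(mat)
  x <- covariate_design(covariates, nrow(m))
  res <- stats::lm.fit(x, m)$residuals
  if (vec) as.vector(res) else res
}

#' Linear association between residualized PSI and genotype
#'
#' Ordinary least-squares slope of the PSI residuals on the genotype
#' residuals, with a two-sided p-value from the t distribution on
#' `n - n_covariates - 2` degrees of freedom: the covariates regressed out
#' upstream are charged here so the two-stage residual regression does not
#' overstate its degrees of freedom.
#'
#' @param psi_resid numeric vector of residualized (transformed) PSI.
#' @param geno_resid numeric vector of residualized dosages, not constant.
#' @param n_covariates number of covariate columns regressed out upstream
#'   (excluding the intercept).
#' @return list with `slope`, `statistic` (t), `p`, `df`, `se`.
#' @export
test_association <- function(psi_resid, geno_resid, n_covariates = 0) {
  stopifnot(length(psi_resid) == length(geno_resid))
  ok <- is.finite(psi_resid) & is.finite(geno_resid)
  y <- psi_resid[ok]; x <- geno_resid[ok]
  n <- length(y)
  df <- n - n_covariates - 2
  if (df < 1) stop("not enough samples for the residual degrees of freedom")
  if (stats::var(x) == 0) stop("constant genotype residual")
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2)
  slope <- sum(xc * yc) / sxx
  rss <- sum((yc - slope * xc)^2)
  se <- sqrt(rss / df / sxx)
  tval <- slope / se
  list(slope = slope, statistic = tval,
       p = 2 * stats::pt(-abs(tval), df), df = df, se = se)
}

#' Sex/stratum heterogeneity z-test for two independent effect estimates
#'
#' `z = (b_a - b_b) / sqrt(se_a^2 + se_b^2)` with a two-sided normal
#' p-value. Used both for sex-stratified sQTL slopes and for sex-stratified
#' GWAS meta-analysis effects.
#'
#' @param beta_a,se_a effect and standard error in stratum A.
#' @param beta_b,se_b effect and standard error in stratum B.
#' @return list with `z` and `p_het`.
#' @export
stratified_heterogeneity <- function(beta_a, se_a, beta_b, se_b) {
  if (se_a <= 0 || se_b <= 0) stop("standard errors must be positive")
  z <- (beta_a - beta_b) / sqrt(se_a^2 + se_b^2)
  list(z = z, p_het = 2 * stats::pnorm(-abs(z)))
}

#' Principal components of the quantifiable PSI matrix
#'
#' Stand-in for latent splicing confounders: the top principal components of
#' the inverse-normal transformed PSI matrix over the samples quantifiable
#' in every LSV.
#'
#' @param psi_list list of [psi_matrix()] objects.
#' @param k number of components requested (capped by the available rank).
#' @return matrix of PC scores, samples x components (possibly 0 columns).
#' @keywords internal
psi_principal_components <- function(psi_list, k) {
  mats <- lapply(psi_list, function(p) t(p$psi))
  x <- do.call(cbind, mats)
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  x <- x[, apply(x, 2, stats::var) > 0, drop = FALSE]
  k <- min(k, nrow(x) - 1L, ncol(x))
  if (k <= 0) return(matrix(0, sum(keep), 0))
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  pc$x[, seq_len(k), drop = FALSE]
}

#' Run the sQTL pipeline on a count table and genotypes
#'
#' Orchestrates the full association procedure for every source LSV of the
#' splice graph: build quantifiable LSVs, quantify PSI, enumerate
#' LSV-variant pairs inside the distance/MAF/MAC filters, mean-impute
#' missing dosages from the quantifiable samples, inverse-normal transform
#' PSI, regress the covariates out of both transformed PSI and dosage, test
#' each LSV element, and Bonferroni-correct at the pair level (a pair's p is
#' the minimum across its elements; `m` is the number of pairs). The
#' genotype-group effect filter keeps pairs whose median |delta PSI| exceeds
#' `delta_psi_threshold` percentage points.
#'
#' @param counts a [junction_counts()].
#' @param genotypes a [genotype_matrix()].
#' @param covariates covariate `data.frame` aligned with the genotype
#'   samples (a `sample_id` column is matched by name), or `NULL`.
#' @param graph the [splice_graph()] the counts map onto.
#' @param min_reads,min_positions,sample_fraction,min_intron_cov LSV build
#'   thresholds, see [build_quantifiable_lsvs()].
#' @param min_total_reads per-sample PSI quantifiability threshold.
#' @param window_bp,mac_min,maf_min pair filters, see
#'   [enumerate_test_pairs()].
#' @param delta_psi_threshold effect filter on |delta PSI|, percent.
#' @param n_psi_pcs number of PSI principal components appended to the
#'   covariates as hidden-factor surrogates. The default 0 is appropriate
#'   for targeted analyses of one or a few LSVs, where the top PSI PCs are
#'   collinear with the signal under test; at transcriptome scale 15 mirrors
#'   common practice.
#' @param source_only drop target LSVs (partially redundant with their
#'   source counterparts) before testing.
#' @param stratum label recorded in the output rows.
#' @return `data.frame` of class `sqtl_result` ordered by LSV id then
#'   variant position, one row per pair, with the best-element association,
#'   Bonferroni-adjusted p, genotype-group PSI summaries (percent), and the
#'   effect filter flag.
#' @export
run_sqtl <- function(counts, genotypes, covariates = NULL, graph,
                     min_reads = 3, min_positions = 2,
                     sample_fraction = 2 / 3, min_intron_cov = 10,
                     min_total_reads = 10, window_bp = 10000, mac_min = 5,
                     maf_min = 0.1, delta_psi_threshold = 10, n_psi_pcs = 0,
                     source_only = TRUE, stratum = "all") {
  lsvs <- build_quantifiable_lsvs(graph, counts, min_reads, min_positions,
                                  sample_fraction, min_intron_cov)
  if (source_only) lsvs <- Filter(function(l) l$kind == "source", lsvs)
  if (!length(lsvs)) return(empty_sqtl_result())
  psi_list <- lapply(lsvs, function(l) quantify_psi(counts, l, min_total_reads))
  pairs <- enumerate_test_pairs(lsvs, psi_list, genotypes, window_bp,
                                mac_min, maf_min)
  if (!nrow(pairs)) return(empty_sqtl_result())
  m <- nrow(pairs)

  samples <- intersect(colnames(counts$counts), rownames(genotypes$dosage))
  cov_df <- NULL
  if (!is.null(covariates)) {
    cov_df <- covariates
    if ("sample_id" %in% names(cov_df)) {
      cov_df <- cov_df[match(samples, cov_df$sample_id), , drop = FALSE]
      if (anyNA(cov_df$sample_id)) stop("covariates missing for some samples")
    }
  }
  if (n_psi_pcs > 0) {
    pcs <- psi_principal_components(psi_list, n_psi_pcs)
    pcs_df <- as.data.frame(pcs)
    cov_df <- if (is.null(cov_df)) pcs_df else cbind(cov_df, pcs_df)
  }

  vmeta <- genotypes$variants
  out <- vector("list", m)
  for (r in seq_len(m)) {
    pr <- pairs[r, ]
    li <- which(vapply(lsvs, function(l) l$id, character(1)) == pr$lsv_id)
    psi <- psi_list[[li]]
    quant <- samples[!is.na(psi$psi[1L, samples])]
    dos <- impute_genotypes(genotypes$dosage[quant, pr$variant_id],
                            rep(TRUE, length(quant)))
    cov_q <- NULL
    n_cov <- 0
    if (!is.null(cov_df)) {
      cov_q <- cov_df[match(quant, samples), , drop = FALSE]
      n_cov <- ncol(covariate_design(cov_q, length(quant))) - 1L
    }
    geno_resid <- residualize(dos, cov_q)
    best <- NULL
    for (el in rownames(psi$psi)) {
      y <- psi$psi[el, quant]
      ty <- tryCatch(inverse_normal_transform(y), error = function(e) NULL)
      if (is.null(ty)) next  # constant PSI: element skipped for this pair
      yr <- residualize(ty, cov_q)
      fit <- tryCatch(test_association(yr, geno_resid, n_cov),
                      error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$p < best$p) best <- c(fit, element = el)
    }
    if (is.null(best)) next
    dsum <- withCallingHandlers(
      genotype_group_delta_psi(psi, genotypes, pr$variant_id, best$element),
      warning = function(w) invokeRestart("muffleWarning"))
    vrow <- vmeta[vmeta$id == pr$variant_id, ]
    out[[r]] <- data.frame(
      lsv_id = pr$lsv_id, element = best$element,
      variant = pr$variant_id, chrom = vrow$chrom, pos = vrow$pos,
      ref = vrow$ref, alt = vrow$alt, n = length(quant), maf = pr$maf,
      slope = best$slope, stat = best$statistic, p = best$p,
      p_adj = min(1, best$p * m),
      psi_hom_ref = dsum$median_psi[["hom_ref"]],
      psi_het = dsum$median_psi[["het"]],
      psi_hom_alt = dsum$median_psi[["hom_alt"]],
      delta_psi = dsum$delta_psi,
      passes_effect_filter = isTRUE(dsum$defined &&
                                    abs(dsum$delta_psi) > delta_psi_threshold),
      stratum = stratum, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(empty_sqtl_result())
  res <- res[order(res$lsv_id, res$pos), ]
  rownames(res) <- NULL
  attr(res, "m_pairs") <- m
  class(res) <- c("sqtl_result", "data.frame")
  res
}

empty_sqtl_result <- function() {
  res <- data.frame(lsv_id = character(), element = character(),
                    variant = character(), chrom = character(),
                    pos = integer(), ref = character(), alt = character(),
                    n = integer(), maf = numeric(), slope = numeric(),
                    stat = numeric(), p = numeric(), p_adj = numeric(),
                    psi_hom_ref = numeric(), psi_het = numeric(),
                    psi_hom_alt = numeric(), delta_psi = numeric(),
                    passes_effect_filter = logical(), stratum = character(),
                    stringsAsFactors = FALSE)
  attr(res, "m_pairs") <- 0L
  class(res) <- c("sqtl_result", "data.frame")
  res
}
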