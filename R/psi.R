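# PSI quantification and genotype-group inclusion summaries.

#' Construct a PSI matrix object
#'
#' Usually produced by [quantify_psi()]; the constructor is exported so that
#' inclusion fractions from other quantifiers can enter the pipeline.
#'
#' @param psi numeric matrix of inclusion fractions, elements x samples;
#'   `NA` marks unquantifiable samples. Quantifiable columns must sum to 1.
#' @param total per-sample total LSV reads (optional).
#' @param lsv_id identifier of the LSV the elements belong to.
#' @return an object of class `psi_matrix`.
#' @export
psi_matrix <- function(psi, total = NULL, lsv_id = "LSV") {
  psi <- as.matrix(psi)
  quant <- !is.na(psi[1L, ])
  if (any(quant)) {
    s <- colSums(psi[, quant, drop = FALSE])
    if (any(abs(s - 1) > 1e-9)) {
      stop("element PSIs must sum to 1 for each quantifiable sample")
    }
  }
  structure(list(psi = psi, total = total, lsv_id = lsv_id),
            class = "psi_matrix")
}

#' Quantify per-sample PSI for one LSV
#'
#' The Percent Selected Index of an element is its share of the reads
#' falling on any element of the LSV: `PSI_e = n_e / sum_k n_k`. Samples
#' whose LSV total falls below `min_total_reads` are flagged unquantifiable
#' (`NA`), not zero. A symmetric pseudo-count can stabilize low totals; the
#' default of 0 gives the plug-in ratio.
#'
#' @param counts a [junction_counts()] containing all LSV elements.
#' @param lsv an `lsv` from [build_quantifiable_lsvs()].
#' @param min_total_reads per-sample quantifiability threshold.
#' @param pseudocount symmetric pseudo-count added to every element.
#' @return a [psi_matrix()].
#' @examples
#' # see vignette("sqtlkit-methods") for a worked pipeline
#' @export
quantify_psi <- function(counts, lsv, min_total_reads = 10,
                         pseudocount = 0) {
  idx <- match(lsv$elements$element_id, rownames(counts$counts))
  if (anyNA(idx)) {
    stop(sprintf("LSV elements missing from counts: %s",
                 paste(lsv$elements$element_id[is.na(idx)], collapse = ", ")))
  }
  x <- counts$counts[idx, , drop = FALSE]
  total <- colSums(x)
  k <- nrow(x)
  psi <- sweep(x + pseudocount, 2, total + k * pseudocount, "/")
  psi[, total < min_total_reads] <- NA_real_
  psi_matrix(psi, total = total, lsv_id = lsv$id)
}

#' Summarize inclusion by genotype group
#'
#' Splits the quantifiable samples by hard genotype (0/1/2 copies of the
#' alternative allele) and reports, on the percent scale, the per-group
#' median PSI, the expected PSI from the linear dosage regression, and
#' `delta_psi` = median(homozygous alternative) - median(homozygous
#' reference). An empty homozygous group leaves the difference undefined
#' (flagged, never silently zero).
#'
#' @param psi a [psi_matrix()].
#' @param genotypes a [genotype_matrix()] sharing sample names with `psi`.
#' @param variant_id variant used to group samples.
#' @param element_id LSV element to summarize.
#' @return an object of class `delta_psi_summary`: list with `median_psi`,
#'   `expected_psi` (each length-3, percent), `delta_psi`,
#'   `delta_psi_expected`, group sizes `n`, and `defined`.
#' @export
genotype_group_delta_psi <- function(psi, genotypes, variant_id, element_id) {
  if (!element_id %in% rownames(psi$psi)) {
    stop(sprintf("element '%s' not in PSI matrix", element_id))
  }
  samples <- intersect(colnames(psi$psi), rownames(genotypes$dosage))
  if (length(samples) == 0L) stop("no shared samples")
  y <- psi$psi[element_id, samples]
  g <- round(genotypes$dosage[samples, variant_id])
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- g[ok]
  n <- vapply(0:2, function(k) sum(g == k), integer(1))
  names(n) <- c("hom_ref", "het", "hom_alt")
  med <- vapply(0:2, function(k) {
    if (n[k + 1L] == 0L) NA_real_ else stats::median(y[g == k])
  }, numeric(1)) * 100
  fit <- stats::lm(y ~ g)
  expected <- unname(stats::predict(fit, newdata = data.frame(g = 0:2))) * 100
  defined <- n["hom_ref"] > 0L && n["hom_alt"] > 0L
  if (!defined) {
    warning(sprintf(
      "variant %s: empty homozygous group (n = %s); delta PSI undefined",
      variant_id, paste(n, collapse = "/")))
  }
  structure(list(
    element_id = element_id,
    variant_id = variant_id,
    n = n,
    median_psi = stats::setNames(med, names(n)),
    expected_psi = stats::setNames(expected, names(n)),
    delta_psi = if (defined) med[3L] - med[1L] else NA_real_,
    delta_psi_expected = expected[3L] - expected[1L],
    defined = defined
  ), class = "delta_psi_summary")
}

#' @export
print.delta_psi_summary <- function(x, ...) {
  cat(sprintf("delta PSI for %s at %s\n", x$element_id, x$variant_id))
  cat(sprintf("  medians (%%): %s (n = %s)\n",
              paste(fmt(x$median_psi), collapse = " / "),
              paste(x$n, collapse = "/")))
  cat(sprintf("  delta PSI = %s (median), %s (expected)\n",
              fmt(x$delta_psi), fmt(x$delta_psi_expected)))
  invisible(x)
}
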