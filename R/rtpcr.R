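# RT-PCR densitometry: percent intron retention and its genotype
# correlation.

#' Percent intron retention from gel band intensities
#'
#' For each sample, replicate band intensities are averaged per product and
#' PIR is the intron-retained band's share of all three products:
#' `PIR = 100 * mean(170nt) / (mean(170nt) + mean(196nt) + mean(274nt))`,
#' where the 170 nt product is the intron-retained form, 196 nt the
#' exon-skip form, and 274 nt the exon-include form. Genotype is coded as
#' the count of C alleles, matching the convention that the C allele tracks
#' increased retention.
#'
#' @param bands `data.frame` with columns `sample_id`, `genotype`
#'   (two-letter allele pair over \{C, T\}, e.g. `"TC"`), `band_170`,
#'   `band_196`, `band_274`; replicate rows per sample are averaged.
#' @param background constant background subtracted from every band before
#'   averaging (default 0; negative results are clipped at 0).
#' @return `data.frame` of class `gel_quant` with columns `sample_id`,
#'   `genotype`, `dosage` (C-allele count) and `pir` (percent).
#' @examples
#' b <- data.frame(sample_id = "a", genotype = "TC",
#'                 band_170 = 30, band_196 = 50, band_274 = 20)
#' pir_from_bands(b)$pir  # 30
#' @export
pir_from_bands <- function(bands, background = 0) {
  req <- c("sample_id", "genotype", "band_170", "band_196", "band_274")
  miss <- setdiff(req, names(bands))
  if (length(miss)) {
    stop(sprintf("band table missing columns: %s", paste(miss, collapse = ", ")))
  }
  alleles <- gsub("[^CT]", "", toupper(bands$genotype))
  if (any(nchar(alleles) != 2L)) {
    stop("genotypes must be unordered pairs over alleles C and T")
  }
  for (col in c("band_170", "band_196", "band_274")) {
    bands[[col]] <- pmax(bands[[col]] - background, 0)
    if (any(bands[[col]] < 0)) stop("band intensities must be non-negative")
  }
  agg <- stats::aggregate(
    bands[, c("band_170", "band_196", "band_274")],
    by = list(sample_id = bands$sample_id), FUN = mean)
  agg <- agg[match(unique(bands$sample_id), agg$sample_id), , drop = FALSE]
  rownames(agg) <- NULL
  geno <- bands$genotype[match(agg$sample_id, bands$sample_id)]
  total <- agg$band_170 + agg$band_196 + agg$band_274
  if (any(total <= 0)) {
    stop(sprintf("all-zero band intensities for sample(s): %s",
                 paste(agg$sample_id[total <= 0], collapse = ", ")))
  }
  out <- data.frame(
    sample_id = agg$sample_id,
    genotype = geno,
    dosage = vapply(strsplit(toupper(geno), ""),
                    function(a) sum(a == "C"), integer(1)),
    pir = 100 * agg$band_170 / total,
    stringsAsFactors = FALSE)
  class(out) <- c("gel_quant", "data.frame")
  out
}

#' Pearson correlation between genotype and percent intron retention
#'
#' Squared Pearson correlation between C-allele dosage and PIR with a
#' two-sided p-value from the t transform on `n - 2` degrees of freedom.
#' An exclusion filter applied before computing supports outlier-exclusion
#' reanalyses.
#'
#' @param quants a `gel_quant` table from [pir_from_bands()].
#' @param exclude optional character vector of `sample_id`s to drop, or a
#'   predicate function on the table returning the rows to keep.
#' @return list with `r_squared`, `r`, `p`, `n`.
#' @export
genotype_correlation <- function(quants, exclude = NULL) {
  q <- quants
  if (is.function(exclude)) {
    q <- q[exclude(q), , drop = FALSE]
  } else if (!is.null(exclude)) {
    q <- q[!q$sample_id %in% exclude, , drop = FALSE]
  }
  n <- nrow(q)
  if (n < 3L) stop("need at least 3 samples after exclusion")
  if (stats::var(q$dosage) == 0) stop("constant dosage after exclusion")
  if (stats::var(q$pir) == 0) stop("constant PIR after exclusion")
  r <- stats::cor(q$dosage, q$pir)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r_squared = r^2, r = r, p = 2 * stats::pt(-abs(tval), n - 2), n = n)
}
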