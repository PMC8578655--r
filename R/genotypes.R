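# Genotype containers and the LD-structured genotype simulator.

#' Describe a panel of biallelic variants
#'
#' Builds the variant metadata table used by [simulate_genotypes()] and the
#' genotype readers. Positions are 1-based genomic coordinates; `maf` is the
#' target minor allele frequency of the simulated alternative allele.
#'
#' @param id character vector of unique variant identifiers (e.g. rs numbers).
#' @param chrom chromosome label, recycled to the number of variants.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-character reference / alternative nucleotides.
#' @param maf numeric vector of minor allele frequencies in (0, 0.5].
#' @return a `data.frame` with columns `id, chrom, pos, ref, alt, maf`.
#' @examples
#' variant_panel("rs1", "8", 1000, "T", "C", maf = 0.41)
#' @export
variant_panel <- function(id, chrom, pos, ref, alt, maf) {
  n <- length(id)
  if (n < 1L) stop("at least one variant is required")
  if (anyDuplicated(id)) stop("variant ids must be unique within a panel")
  if (any(pos < 1)) stop("positions are 1-based and must be >= 1")
  if (any(!is.finite(maf)) || any(maf <= 0) || any(maf > 0.5)) {
    stop("maf must lie in (0, 0.5]")
  }
  data.frame(
    id = as.character(id),
    chrom = rep_len(as.character(chrom), n),
    pos = as.integer(pos),
    ref = rep_len(as.character(ref), n),
    alt = rep_len(as.character(alt), n),
    maf = as.numeric(maf),
    stringsAsFactors = FALSE
  )
}

#' Construct a genotype matrix object
#'
#' Couples an alternative-allele dosage matrix (samples x variants, values in
#' \{0, 1, 2\} or `NA` for missing genotypes) with its variant metadata.
#'
#' @param dosage numeric matrix, samples in rows, variants in columns; column
#'   names must match `variants$id`.
#' @param variants variant metadata as returned by [variant_panel()] (the
#'   `maf` column is optional for observed data).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants) {
  dosage <- as.matrix(dosage)
  if (is.null(colnames(dosage))) colnames(dosage) <- variants$id
  if (!identical(colnames(dosage), variants$id)) {
    stop("dosage column names must match variants$id in order")
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("S%04d", seq_len(nrow(dosage)))
  }
  bad <- dosage[!is.na(dosage)]
  if (any(bad < 0 | bad > 2)) stop("dosages must lie in [0, 2]")
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              nrow(x$dosage), ncol(x$dosage)))
  cat(sprintf("  chrom %s, span %s-%s\n",
              x$variants$chrom[1], min(x$variants$pos), max(x$variants$pos)))
  invisible(x)
}

#' Simulate biallelic genotypes with local linkage disequilibrium
#'
#' Draws `2 * n_samples` haplotypes from a first-order copying process: each
#' haplotype carries a latent uniform value that is retained from the previous
#' variant with probability `0.5^(distance / ld_decay)` and redrawn otherwise,
#' and the allele at each variant is the indicator that the latent value falls
#' below that variant's allele frequency. Between two variants at distance
#' `ld_decay` the haplotype correlation is therefore 0.5 (a correlation
#' half-distance), decaying monotonically with distance. Genotype dosage is
#' the sum of the two haplotypes.
#'
#' @param variants variant metadata from [variant_panel()]; must be sorted by
#'   position (they are sorted internally).
#' @param n_samples number of diploid samples (>= 2).
#' @param ld_decay correlation half-distance in base pairs.
#' @param seed integer seed; the same seed gives bit-identical output.
#' @return a [genotype_matrix()] with integer dosages; the underlying 0/1
#'   haplotype pool is attached as attribute `"haplotypes"` (a
#'   `2*n_samples x n_variants` matrix) for LD diagnostics.
#' @examples
#' g <- simulate_genotypes(variant_panel("v1", "8", 100, "T", "C", 0.3),
#'                         n_samples = 50, seed = 1)
#' table(g$dosage)
#' @export
simulate_genotypes <- function(variants, n_samples, ld_decay = 10000, seed) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (any(variants$maf <= 0 | variants$maf > 0.5)) {
    stop("maf must lie in (0, 0.5]")
  }
  variants <- variants[order(variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  m <- nrow(variants)
  nh <- 2L * n_samples
  set.seed(child_seed(seed, "simulate_genotypes"))
  hap <- matrix(0L, nh, m)
  u <- stats::runif(nh)
  hap[, 1L] <- as.integer(u < variants$maf[1L])
  if (m > 1L) {
    for (j in 2:m) {
      d <- variants$pos[j] - variants$pos[j - 1L]
      keep <- stats::runif(nh) < 0.5^(d / ld_decay)
      fresh <- stats::runif(nh)
      u <- ifelse(keep, u, fresh)
      hap[, j] <- as.integer(u < variants$maf[j])
    }
  }
  dos <- hap[seq_len(n_samples), , drop = FALSE] +
    hap[n_samples + seq_len(n_samples), , drop = FALSE]
  storage.mode(dos) <- "integer"
  rownames(dos) <- sprintf("S%04d", seq_len(n_samples))
  colnames(dos) <- variants$id
  out <- genotype_matrix(dos, variants)
  attr(out, "haplotypes") <- hap
  out
}

#' Squared Pearson LD between two variants
#'
#' @param genotypes a [genotype_matrix()].
#' @param variant_a,variant_b variant identifiers.
#' @return squared Pearson correlation of the dosage vectors, in \[0, 1\].
#' @export
ld_r2 <- function(genotypes, variant_a, variant_b) {
  d <- genotypes$dosage
  for (v in c(variant_a, variant_b)) {
    if (!v %in% colnames(d)) stop(sprintf("variant '%s' not found", v))
  }
  a <- d[, variant_a]
  b <- d[, variant_b]
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("monomorphic variant: LD undefined")
  }
  unname(stats::cor(a, b)^2)
}
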