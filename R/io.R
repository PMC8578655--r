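# Standard-format readers and writers: VCF genotypes and tab-separated
# count / covariate / phenotype / band / summary-statistics tables.
# Readers validate and reject rather than coerce; writers round-trip.

#' Read biallelic genotypes from a VCF file
#'
#' Parses GT fields into alternative-allele dosages. Missing genotypes
#' (`./.`) become missing dosages (never 0); multiallelic records are
#' skipped with a warning.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @return a [genotype_matrix()]; the `maf` column of the variant metadata
#'   holds realized minor allele frequencies.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warning(sprintf("%d multiallelic record(s) skipped", sum(multi)))
  }
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  count_alt <- function(s) {
    if (is.na(s)) return(NA_real_)
    a <- strsplit(s, "[/|]")[[1]]
    if (any(a == ".")) return(NA_real_)
    sum(a == "1")
  }
  dos <- t(apply(gt, 1, function(row) vapply(row, count_alt, numeric(1))))
  if (ncol(gt) == 1L) dos <- matrix(dos, ncol = 1L,
                                    dimnames = list(rownames(gt), colnames(gt)))
  dos <- t(dos)  # samples x variants
  af <- colMeans(dos, na.rm = TRUE) / 2
  variants <- data.frame(
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    maf = pmin(af, 1 - af), stringsAsFactors = FALSE)
  colnames(dos) <- variants$id
  genotype_matrix(dos, variants)
}

#' Write genotypes as a minimal VCF
#'
#' Emits a VCFv4.2 file with GT-only genotype fields. Dosage 1 is written
#' as `0/1` and missing dosage as `./.`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  vm <- genotypes$variants
  dos <- genotypes$dosage
  gt_of <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=sqtlkit",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dos)), collapse = "\t"))
  body <- vapply(seq_len(nrow(vm)), function(i) {
    g <- dos[, i]
    gt <- ifelse(is.na(g), "./.", gt_of[round(g) + 1L])
    paste(c(vm$chrom[i], vm$pos[i], vm$id[i], vm$ref[i], vm$alt[i], ".",
            "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  x <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = "NA")
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  }
  x
}

#' Write a junction count table as TSV
#'
#' One row per element, keyed by `gene_id, chrom, element_id, kind, start,
#' end`, followed by one count column per sample. Distinct start-position
#' counts are written alongside with a `pos:` prefix on the sample name.
#'
#' @param counts a [junction_counts()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(counts, path) {
  pos <- counts$positions
  colnames(pos) <- paste0("pos:", colnames(counts$counts))
  out <- cbind(counts$info, as.data.frame(counts$counts, check.names = FALSE),
               as.data.frame(pos, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a junction count table written by [write_counts_table()]
#'
#' @param path path to the TSV.
#' @return a [junction_counts()].
#' @export
read_counts_table <- function(path) {
  key <- c("gene_id", "chrom", "element_id", "kind", "start", "end")
  x <- read_tsv_checked(path, key)
  sample_cols <- setdiff(names(x), key)
  pos_cols <- grep("^pos:", sample_cols, value = TRUE)
  cnt_cols <- setdiff(sample_cols, pos_cols)
  cnt <- as.matrix(x[, cnt_cols, drop = FALSE])
  rownames(cnt) <- x$element_id
  for (j in seq_len(ncol(cnt))) {
    bad <- which(cnt[, j] < 0 | cnt[, j] != floor(cnt[, j]))
    if (length(bad)) {
      stop(sprintf("invalid count at row '%s', column '%s'",
                   x$element_id[bad[1]], cnt_cols[j]))
    }
  }
  pos <- NULL
  if (length(pos_cols)) {
    pos <- as.matrix(x[, pos_cols, drop = FALSE])
    colnames(pos) <- sub("^pos:", "", pos_cols)
    pos <- pos[, colnames(cnt), drop = FALSE]
    rownames(pos) <- x$element_id
  }
  junction_counts(x[, key], cnt, pos)
}

#' Write a sample table (covariates, phenotypes, band records) as TSV
#'
#' @param table `data.frame` with a `sample_id` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(table, path) {
  if (!"sample_id" %in% names(table)) stop("table must have a sample_id column")
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample-keyed table, rejecting duplicate sample ids
#'
#' @param path path to a TSV with a header including `sample_id`.
#' @param required additional required column names.
#' @return validated `data.frame`.
#' @export
read_sample_table <- function(path, required = character(0)) {
  x <- read_tsv_checked(path, c("sample_id", required))
  dup <- x$sample_id[duplicated(x$sample_id)]
  if (length(dup)) {
    stop(sprintf("duplicate sample id(s): %s",
                 paste(unique(dup), collapse = ", ")))
  }
  x
}

#' Read a band-intensity table for RT-PCR quantification
#'
#' Replicate rows per sample are allowed (they are averaged downstream), so
#' only column presence and non-negativity are validated.
#'
#' @param path TSV with columns `sample_id, genotype, band_170, band_196,
#'   band_274`.
#' @return validated `data.frame`.
#' @export
read_band_table <- function(path) {
  x <- read_tsv_checked(path, c("sample_id", "genotype", "band_170",
                                "band_196", "band_274"))
  for (col in c("band_170", "band_196", "band_274")) {
    if (any(x[[col]] < 0, na.rm = TRUE)) {
      stop(sprintf("negative intensity in column '%s'", col))
    }
  }
  x
}

#' Read / write GWAS summary statistics
#'
#' The summary-statistics dialect has columns `variant, chrom, pos,
#' effect_allele, other_allele, eaf, beta, se, p, n`; it is what
#' [cohort_association()] and [meta_fixed_ivw()] produce and what
#' [abf_finemap()] and [coloc_abf()] consume.
#'
#' @param path TSV path.
#' @return validated `data.frame`.
#' @export
read_sumstats <- function(path) {
  x <- read_tsv_checked(path, c("variant", "chrom", "pos", "effect_allele",
                                "other_allele", "eaf", "beta", "se", "p",
                                "n"))
  if (any(x$se <= 0)) stop("all standard errors must be positive")
  if (any(x$eaf <= 0 | x$eaf >= 1)) stop("eaf must lie in (0, 1)")
  x
}

#' @rdname read_sumstats
#' @param sumstats summary-statistics `data.frame`.
#' @export
write_sumstats <- function(sumstats, path) {
  utils::write.table(sumstats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
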