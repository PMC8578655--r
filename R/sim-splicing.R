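# Genotype-dependent splicing-count simulator.

#' Define a generative model for one local splicing variation
#'
#' Describes a source LSV with alternative junctions and (optionally) one
#' retained intron, a causal variant, baseline inclusion fractions, and a
#' per-allele inclusion shift. The shift is specified in percentage points
#' per alternative allele and applied through a logistic link (see
#' [psi_given_dosage()]), so probabilities stay inside (0, 1) for any dosage.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome label.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame` with columns `start`, `end` (1-based inclusive).
#' @param junctions `data.frame` with columns `donor`, `acceptor`.
#' @param retained_intron optional length-2 vector `c(start, end)`.
#' @param causal_variant one-row [variant_panel()] entry.
#' @param baseline_psi inclusion fractions at dosage 0 over the elements
#'   (junctions in order, then the retained intron last); must sum to 1.
#' @param delta_psi_per_allele per-allele shift for each element in
#'   percentage points (0 = unaffected).
#' @param depth_mean mean total LSV read depth per sample (Poisson), >= 1.
#' @return an object of class `lsv_model`.
#' @examples
#' m <- cassette_ir_model()  # the packaged cassette-exon + intron model
#' psi_given_dosage(m, 0:2)
#' @export
lsv_model <- function(gene_id, chrom, strand = "+", exons, junctions,
                      retained_intron = NULL, causal_variant, baseline_psi,
                      delta_psi_per_allele, depth_mean = 100) {
  k <- nrow(junctions) + as.integer(!is.null(retained_intron))
  if (length(baseline_psi) != k || length(delta_psi_per_allele) != k) {
    stop("baseline_psi and delta_psi_per_allele must have one entry per element")
  }
  if (abs(sum(baseline_psi) - 1) > 1e-9) stop("baseline_psi must sum to 1")
  if (any(baseline_psi < 0)) stop("baseline_psi must be non-negative")
  if (depth_mean < 1) stop("depth_mean must be >= 1")
  ids <- junction_element_id(junctions$donor, junctions$acceptor)
  kinds <- rep("junction", nrow(junctions))
  starts <- junctions$donor
  ends <- junctions$acceptor
  if (!is.null(retained_intron)) {
    ids <- c(ids, intron_element_id(retained_intron[1], retained_intron[2]))
    kinds <- c(kinds, "intron")
    starts <- c(starts, retained_intron[1])
    ends <- c(ends, retained_intron[2])
  }
  info <- data.frame(gene_id = gene_id, chrom = chrom, element_id = ids,
                     kind = kinds, start = as.integer(starts),
                     end = as.integer(ends), stringsAsFactors = FALSE)
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, junctions = junctions,
                 retained_intron = retained_intron,
                 causal_variant = causal_variant,
                 baseline_psi = baseline_psi,
                 delta_psi_per_allele = delta_psi_per_allele,
                 depth_mean = depth_mean, element_info = info),
            class = "lsv_model")
}

#' The splice graph implied by an LSV model
#'
#' @param model an [lsv_model()].
#' @return a [splice_graph()] covering the model's exons and elements.
#' @export
as_splice_graph <- function(model) {
  ri <- if (is.null(model$retained_intron)) NULL else
    data.frame(start = model$retained_intron[1], end = model$retained_intron[2])
  splice_graph(model$gene_id, model$chrom, model$strand, model$exons,
               model$junctions, ri)
}

#' Expected inclusion fractions at each genotype dosage
#'
#' For an element with baseline fraction `p` and per-allele shift `d`
#' (percent / 100), the log-odds of that element against the others is
#' shifted by `logit(p + g d) - logit(p)` at dosage `g` and the element
#' probabilities are renormalized. With a single shifted element this makes
#' the element's expected PSI exactly `p + g d` (clamped away from 0 and 1);
#' with several shifted elements the renormalized fractions are the model's
#' definition of truth.
#'
#' @param model an [lsv_model()].
#' @param dosage vector of dosages (any reals; hard calls are 0/1/2).
#' @return matrix of probabilities, elements x `length(dosage)`.
#' @export
psi_given_dosage <- function(model, dosage) {
  p0 <- model$baseline_psi
  d <- model$delta_psi_per_allele / 100
  eps <- 1e-6
  out <- vapply(dosage, function(g) {
    theta <- rep(0, length(p0))
    shift <- d != 0
    if (any(shift)) {
      tgt <- pmin(pmax(p0[shift] + g * d[shift], eps), 1 - eps)
      base <- pmin(pmax(p0[shift], eps), 1 - eps)
      theta[shift] <- stats::qlogis(tgt) - stats::qlogis(base)
    }
    l <- log(pmax(p0, eps * (p0 > 0 | shift))) + theta
    l[p0 == 0 & !shift] <- -Inf
    w <- exp(l - max(l[is.finite(l)]))
    w[!is.finite(w)] <- 0
    w / sum(w)
  }, numeric(length(p0)))
  rownames(out) <- model$element_info$element_id
  out
}

#' Simulate junction and intron read counts for an LSV
#'
#' Per sample, the total LSV depth is Poisson around `depth_mean` and each
#' read makes a multinomial splicing choice with probabilities given by the
#' logistic-shifted baseline for that sample's dosage of the causal variant.
#' Distinct read start positions are simulated by occupancy sampling over
#' `n_start_positions` possible starts. Samples that draw zero reads are
#' flagged unquantifiable rather than propagated as `NaN`.
#'
#' @param genotypes a [genotype_matrix()] containing the causal variant.
#' @param model an [lsv_model()].
#' @param seed integer seed; identical seeds give identical counts.
#' @param n_start_positions number of possible read start positions per
#'   element.
#' @param dispersion optional Dirichlet-multinomial overdispersion; 0
#'   (default) draws plain multinomial counts, larger values spread
#'   per-sample splicing fractions around the model truth.
#' @return list of class `splicing_sim` with fields `counts` (a
#'   [junction_counts()]), `true_psi` (elements x samples), `depth`, and
#'   `unquantifiable` (logical per sample).
#' @export
simulate_splicing_counts <- function(genotypes, model, seed,
                                     n_start_positions = 50,
                                     dispersion = 0) {
  cv <- model$causal_variant$id
  if (!cv %in% colnames(genotypes$dosage)) {
    stop(sprintf("causal variant '%s' absent from genotypes", cv))
  }
  if (any(model$baseline_psi == 0 & model$delta_psi_per_allele != 0)) {
    warning("non-zero shift requested on an element with baseline PSI 0")
  }
  g <- round(genotypes$dosage[, cv])
  n <- length(g)
  k <- length(model$baseline_psi)
  set.seed(child_seed(seed, "simulate_splicing_counts"))
  probs3 <- psi_given_dosage(model, 0:2)
  true_psi <- probs3[, g + 1L, drop = FALSE]
  colnames(true_psi) <- rownames(genotypes$dosage)
  depth <- stats::rpois(n, model$depth_mean)
  counts <- matrix(0L, k, n,
                   dimnames = list(model$element_info$element_id,
                                   rownames(genotypes$dosage)))
  for (i in seq_len(n)) {
    if (depth[i] == 0L) next
    p <- true_psi[, i]
    if (dispersion > 0) {
      a <- stats::rgamma(k, shape = p / dispersion)
      p <- if (sum(a) > 0) a / sum(a) else p
    }
    counts[, i] <- stats::rmultinom(1L, depth[i], p)
  }
  positions <- counts
  nz <- which(counts > 1L)
  for (j in nz) {
    positions[j] <- length(unique(sample.int(n_start_positions, counts[j],
                                             replace = TRUE)))
  }
  structure(list(
    counts = junction_counts(model$element_info, counts, positions),
    true_psi = true_psi,
    depth = depth,
    unquantifiable = depth == 0L
  ), class = "splicing_sim")
}

#' A packaged cassette-exon + retained-intron LSV model
#'
#' A compact three-element source LSV used throughout the examples and
#' tests: from the reference exon, transcripts either skip the cassette
#' exon, include it, or retain the downstream intron. Defaults emulate an
#' intron-retention sQTL whose alternative allele raises retention by about
#' ten percentage points per allele.
#'
#' @param causal_variant one-row [variant_panel()]; defaults to a common
#'   variant just upstream of the reference exon.
#' @param baseline_psi baseline fractions for (skip, include, intron).
#' @param delta_psi_per_allele per-allele percent shifts, same order.
#' @param depth_mean mean LSV depth.
#' @return an [lsv_model()].
#' @export
cassette_ir_model <- function(causal_variant = variant_panel("rs_sim", "8",
                                                             99500L, "T", "C",
                                                             0.47),
                              baseline_psi = c(0.55, 0.35, 0.10),
                              delta_psi_per_allele = c(0, 0, 10),
                              depth_mean = 100) {
  exons <- data.frame(start = c(100000L, 101000L, 102000L),
                      end = c(100200L, 101100L, 102300L))
  junctions <- data.frame(donor = c(100200L, 100200L),
                          acceptor = c(102000L, 101000L))
  # elements: skip (exon1->exon3), include (exon1->exon2), intron after exon1
  lsv_model(
    gene_id = "GENE1", chrom = "8", strand = "+",
    exons = exons,
    junctions = junctions,
    retained_intron = c(100201L, 100999L),
    causal_variant = causal_variant,
    baseline_psi = baseline_psi,
    delta_psi_per_allele = delta_psi_per_allele,
    depth_mean = depth_mean
  )
}
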