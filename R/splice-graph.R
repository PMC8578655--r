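# Splice graphs, local splicing variations (LSVs), and junction count tables.

#' Build a splice graph for one gene
#'
#' A splice graph holds the exons of a gene together with the splice
#' junctions and retained introns observed between them. Coordinates are
#' 1-based inclusive. Junctions are keyed by the last exonic base of the
#' donor exon and the first exonic base of the acceptor exon (left < right on
#' the genome, regardless of strand).
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome label.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame` with columns `start`, `end`; non-overlapping.
#' @param junctions `data.frame` with columns `donor`, `acceptor`; each
#'   endpoint must coincide with an exon boundary.
#' @param retained_introns optional `data.frame` with columns `start`, `end`;
#'   each must be flanked by exon boundaries.
#' @return an object of class `splice_graph`.
#' @export
splice_graph <- function(gene_id, chrom, strand = "+", exons, junctions,
                         retained_introns = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    stop("exon intervals must be non-overlapping")
  }
  bounds_end <- exons$end
  bounds_start <- exons$start
  for (i in seq_len(nrow(junctions))) {
    d <- junctions$donor[i]; a <- junctions$acceptor[i]
    if (d >= a) stop("junction donor must precede acceptor")
    if (!(d %in% bounds_end) || !(a %in% bounds_start)) {
      stop(sprintf("junction %d-%d does not lie on exon boundaries", d, a))
    }
  }
  if (!is.null(retained_introns)) {
    for (i in seq_len(nrow(retained_introns))) {
      s <- retained_introns$start[i]; e <- retained_introns$end[i]
      if (!((s - 1L) %in% bounds_end) || !((e + 1L) %in% bounds_start)) {
        stop(sprintf("retained intron %d-%d is not flanked by exons", s, e))
      }
    }
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, junctions = junctions,
                 retained_introns = retained_introns),
            class = "splice_graph")
}

# canonical element identifiers
junction_element_id <- function(donor, acceptor) {
  sprintf("J:%d-%d", donor, acceptor)
}
intron_element_id <- function(start, end) sprintf("IR:%d-%d", start, end)

#' Construct a junction/intron count table
#'
#' Per-sample read support for the elements of a splice graph: total read
#' counts and the number of distinct read start positions (the latter backs
#' the reliability thresholds used when building quantifiable LSVs).
#'
#' @param info `data.frame` with columns `gene_id`, `chrom`, `element_id`,
#'   `kind` (`"junction"` or `"intron"`), `start`, `end`.
#' @param counts integer matrix, elements x samples, row names equal to
#'   `info$element_id`.
#' @param positions optional matrix of distinct start-position counts with
#'   the same shape; defaults to `counts` (every read at its own start),
#'   appropriate when start positions were not tracked.
#' @return an object of class `junction_counts`.
#' @export
junction_counts <- function(info, counts, positions = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- info$element_id
  if (!identical(rownames(counts), info$element_id)) {
    stop("count row names must match info$element_id")
  }
  if (any(counts < 0)) stop("read counts must be non-negative")
  if (is.null(positions)) positions <- counts
  positions <- as.matrix(positions)
  if (any(positions > counts)) {
    stop("start-position counts cannot exceed read counts")
  }
  structure(list(info = info, counts = counts, positions = positions),
            class = "junction_counts")
}

#' @export
print.junction_counts <- function(x, ...) {
  cat(sprintf("junction_counts: %d elements x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$info$gene_id), collapse = ", ")))
  invisible(x)
}

# does each element meet the per-sample support rule in enough samples?
element_supported <- function(kind, counts, positions, min_reads,
                              min_positions, sample_fraction,
                              min_intron_cov) {
  if (kind == "intron") {
    ok <- counts >= min_intron_cov
  } else {
    ok <- counts >= min_reads & positions >= min_positions
  }
  mean(ok) >= sample_fraction
}

#' Enumerate quantifiable LSVs from a splice graph and read support
#'
#' An LSV (local splicing variation) is the set of splicing choices leaving
#' (source) or entering (target) a reference exon: alternative junctions
#' and/or one retained intron. An element is retained only if it is supported
#' in at least `sample_fraction` of samples, where support means at least
#' `min_reads` reads across at least `min_positions` distinct start positions
#' for a junction, or at least `min_intron_cov` reads for a retained intron.
#' LSVs reduced below two elements are dropped.
#'
#' @param graph a [splice_graph()].
#' @param counts a [junction_counts()] whose elements all map onto `graph`.
#' @param min_reads,min_positions junction support thresholds.
#' @param sample_fraction fraction of samples that must support an element.
#' @param min_intron_cov read threshold for retained introns.
#' @return list of `lsv` objects, each with fields `id`, `kind`
#'   (`"source"`/`"target"`), `reference_exon`, `elements` (a `data.frame`)
#'   and `event_exons` (all exons touched by the event, used for the sQTL
#'   distance window).
#' @export
build_quantifiable_lsvs <- function(graph, counts, min_reads = 3,
                                    min_positions = 2,
                                    sample_fraction = 2 / 3,
                                    min_intron_cov = 10) {
  info <- counts$info
  if (nrow(info) == 0L || ncol(counts$counts) == 0L) return(list())
  # map features onto the graph, reporting unknown coordinates
  for (i in seq_len(nrow(info))) {
    if (info$kind[i] == "junction") {
      hit <- any(graph$junctions$donor == info$start[i] &
                 graph$junctions$acceptor == info$end[i])
    } else {
      hit <- !is.null(graph$retained_introns) &&
        any(graph$retained_introns$start == info$start[i] &
            graph$retained_introns$end == info$end[i])
    }
    if (!hit) {
      stop(sprintf("count feature %s (%s:%d-%d) absent from splice graph",
                   info$element_id[i], graph$chrom, info$start[i],
                   info$end[i]))
    }
  }
  supported <- vapply(seq_len(nrow(info)), function(i) {
    element_supported(info$kind[i], counts$counts[i, ],
                      counts$positions[i, ], min_reads, min_positions,
                      sample_fraction, min_intron_cov)
  }, logical(1))

  exons <- graph$exons
  find_exon_at_end <- function(coord) which(exons$end == coord)
  find_exon_at_start <- function(coord) which(exons$start == coord)

  make_lsv <- function(kind, ex_idx) {
    ex <- exons[ex_idx, ]
    keep <- logical(nrow(info))
    for (i in seq_len(nrow(info))) {
      if (!supported[i]) next
      if (info$kind[i] == "junction") {
        keep[i] <- if (kind == "source") info$start[i] == ex$end
                   else info$end[i] == ex$start
      } else {
        keep[i] <- if (kind == "source") info$start[i] == ex$end + 1L
                   else info$end[i] == ex$start - 1L
      }
    }
    if (sum(keep) < 2L) return(NULL)
    elements <- info[keep, , drop = FALSE]
    rownames(elements) <- NULL
    # exons touched by the event: the reference exon plus partners
    touched <- ex_idx
    for (i in which(keep)) {
      if (info$kind[i] == "junction") {
        touched <- c(touched,
                     if (kind == "source") find_exon_at_start(info$end[i])
                     else find_exon_at_end(info$start[i]))
      } else {
        touched <- c(touched, find_exon_at_end(info$start[i] - 1L),
                     find_exon_at_start(info$end[i] + 1L))
      }
    }
    touched <- sort(unique(touched))
    structure(list(
      id = sprintf("%s:%s:%d-%d", graph$gene_id,
                   if (kind == "source") "s" else "t", ex$start, ex$end),
      kind = kind,
      reference_exon = c(start = ex$start, end = ex$end),
      elements = elements,
      event_exons = exons[touched, , drop = FALSE],
      gene_id = graph$gene_id,
      chrom = graph$chrom
    ), class = "lsv")
  }

  # on the minus strand, reads leave an exon at its genomic start
  src_side <- if (graph$strand == "+") "source" else "target"
  lsvs <- list()
  for (e in seq_len(nrow(exons))) {
    for (kind_geom in c("source", "target")) {
      l <- make_lsv(kind_geom, e)
      if (!is.null(l)) {
        if (graph$strand == "-") {
          l$kind <- if (kind_geom == "source") "target" else "source"
          l$id <- sprintf("%s:%s:%d-%d", graph$gene_id,
                          if (l$kind == "source") "s" else "t",
                          l$reference_exon["start"], l$reference_exon["end"])
        }
        lsvs[[length(lsvs) + 1L]] <- l
      }
    }
  }
  lsvs
}

#' @export
print.lsv <- function(x, ...) {
  cat(sprintf("LSV %s (%s): %d elements at exon %d-%d\n", x$id, x$kind,
              nrow(x$elements), x$reference_exon["start"],
              x$reference_exon["end"]))
  invisible(x)
}
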