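# Shared fixture builders: a compact cassette-exon + retained-intron gene
# model and count tables built around it. Everything is generated in code.

# element ids of the packaged cassette/intron model
EL_SKIP <- "J:100200-102000"
EL_INCL <- "J:100200-101000"
EL_IR <- "IR:100201-100999"

toy_model <- function(...) cassette_ir_model(...)

toy_graph <- function() as_splice_graph(cassette_ir_model())

# counts object over the three toy elements from per-element vectors
toy_counts <- function(skip, incl, intron, positions = NULL,
                       samples = NULL) {
  info <- cassette_ir_model()$element_info
  n <- max(length(skip), length(incl), length(intron))
  cnt <- rbind(rep_len(skip, n), rep_len(incl, n), rep_len(intron, n))
  rownames(cnt) <- info$element_id
  colnames(cnt) <- samples %||% sprintf("S%04d", seq_len(n))
  junction_counts(info, cnt, positions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a panel of m variants spread over a window around the toy gene
toy_panel <- function(m, maf = 0.3, from = 95000L, to = 105000L) {
  variant_panel(sprintf("v%03d", seq_len(m)), "8",
                as.integer(round(seq(from, to, length.out = m))),
                "A", "G", rep_len(maf, m))
}

# vectorized per-variant OLS of y on each dosage column; returns beta, se
fast_assoc <- function(y, dos) {
  yc <- y - mean(y)
  gc <- sweep(dos, 2, colMeans(dos))
  sxx <- colSums(gc^2)
  beta <- as.vector(crossprod(gc, yc)) / sxx
  n <- length(y)
  rss <- sum(yc^2) - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  list(beta = beta, se = se, z = beta / se)
}
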