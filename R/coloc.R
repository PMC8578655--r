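# Bayesian colocalization of two association signals over a shared
# variant set, via Wakefield approximate Bayes factors and the
# five-hypothesis posterior.

#' Wakefield log approximate Bayes factor
#'
#' For one association estimate with standard error `se` and a normal
#' effect prior of variance `W`,
#' `log ABF = 0.5 log(se^2 / (se^2 + W)) + z^2 W / (2 (se^2 + W))` with
#' `z = beta / se`. Shared kernel of [abf_finemap()] and [coloc_abf()].
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), positive.
#' @param W prior variance of the effect, positive.
#' @return vector of log Bayes factors (natural log).
#' @export
log_abf <- function(beta, se, W) {
  if (any(se <= 0)) stop("standard errors must be positive")
  if (W <= 0) stop("prior variance W must be positive")
  v <- se^2
  z2 <- (beta / se)^2
  0.5 * log(v / (v + W)) + z2 * W / (2 * (v + W))
}

#' Bayesian colocalization of two traits
#'
#' Enumerates the five causal configurations over a shared, identically
#' ordered variant set: H0 no association with either trait, H1/H2 one
#' causal variant for trait 1/2 only, H3 two distinct causal variants, H4
#' one shared causal variant. Per-variant Wakefield log ABFs are combined
#' with per-variant prior probabilities `p1`, `p2`, `p12`, all accumulation
#' in log space (log-sum-exp); raw probability products are never formed.
#' With a single shared variant H3 is impossible and its posterior is
#' exactly 0.
#'
#' @param trait1,trait2 `data.frame`s with columns `variant`, `beta`, `se`,
#'   over the same variants in the same order (pre-intersected).
#' @param W1,W2 per-trait prior effect variances.
#' @param p1,p2,p12 per-variant prior probabilities of being causal for
#'   trait 1 only, trait 2 only, or both.
#' @param pp4_threshold posterior threshold above which colocalization is
#'   called.
#' @return object of class `coloc_result`: list with `pp` (named vector
#'   pp0..pp4 summing to 1), `colocalized`, `n_variants`, `priors`, and the
#'   per-variant log ABFs.
#' @export
coloc_abf <- function(trait1, trait2, W1 = 0.04, W2 = 0.04,
                      p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      pp4_threshold = 0.8) {
  if (!all(c(p1, p2, p12) > 0) || p1 + p2 + p12 >= 1) {
    stop("priors must be positive and sum below 1")
  }
  if (nrow(trait1) != nrow(trait2) ||
      !identical(as.character(trait1$variant), as.character(trait2$variant))) {
    d1 <- setdiff(trait1$variant, trait2$variant)
    d2 <- setdiff(trait2$variant, trait1$variant)
    stop(sprintf(
      "variant sets must be identical and identically ordered (only in trait1: %s; only in trait2: %s)",
      paste(d1, collapse = ","), paste(d2, collapse = ",")))
  }
  if (nrow(trait1) < 1L) stop("need at least one shared variant")
  l1 <- log_abf(trait1$beta, trait1$se, W1)
  l2 <- log_abf(trait2$beta, trait2$se, W2)
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  lh <- c(
    h0 = 0,
    h1 = log(p1) + s1,
    h2 = log(p2) + s2,
    h3 = if (length(l1) > 1L) log(p1) + log(p2) + logdiffexp(s1 + s2, s12)
         else -Inf,
    h4 = log(p12) + s12
  )
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("pp", 0:4)
  structure(list(pp = pp, colocalized = unname(pp["pp4"] > pp4_threshold),
                 n_variants = nrow(trait1),
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 log_abf1 = l1, log_abf2 = l2),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("colocalization over %d variants\n", x$n_variants))
  print(round(x$pp, 4))
  cat(sprintf("  colocalized (pp4 > threshold): %s\n", x$colocalized))
  invisible(x)
}
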