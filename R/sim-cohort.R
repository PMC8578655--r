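# Covariate, phenotype, and RT-PCR gel-band simulators.

#' Simulate known and hidden covariates
#'
#' Binary columns emulate sex, sequencing platform, and library protocol;
#' continuous standard-normal columns emulate hidden confounding factors
#' (PEER-like) and genotype principal components.
#'
#' @param n_samples number of samples (>= 2).
#' @param n_hidden number of continuous hidden-factor columns.
#' @param n_geno_pc number of genotype principal-component columns.
#' @param binary named numeric vector of Bernoulli probabilities for the
#'   binary covariates; use `NULL` (with `n_hidden = 0`, `n_geno_pc = 0`)
#'   for a table holding only the sample index.
#' @param seed integer seed.
#' @return `data.frame` with a `sample_id` column followed by covariates.
#' @export
simulate_covariates <- function(n_samples, n_hidden = 15, n_geno_pc = 5,
                                binary = c(sex = 0.5, platform = 0.5,
                                           protocol = 0.5),
                                seed) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  set.seed(child_seed(seed, "simulate_covariates"))
  out <- data.frame(sample_id = sprintf("S%04d", seq_len(n_samples)),
                    stringsAsFactors = FALSE)
  for (nm in names(binary)) {
    out[[nm]] <- stats::rbinom(n_samples, 1L, binary[[nm]])
  }
  if (n_hidden > 0) {
    for (j in seq_len(n_hidden)) {
      out[[sprintf("hidden%02d", j)]] <- stats::rnorm(n_samples)
    }
  }
  if (n_geno_pc > 0) {
    for (j in seq_len(n_geno_pc)) {
      out[[sprintf("pc%d", j)]] <- stats::rnorm(n_samples)
    }
  }
  out
}

#' Simulate a quantitative phenotype with per-variant genetic effects
#'
#' The phenotype is the additive genetic value (`sum(beta * dosage)`) plus
#' optional covariate effects and Gaussian noise, emulating a standardized
#' residual outcome. Sex strata are labelled from the covariate table when a
#' `sex` column is present.
#'
#' @param genotypes a [genotype_matrix()].
#' @param effects named numeric vector of per-allele effects on the
#'   standardized scale, names are variant ids (all must exist).
#' @param covariates optional covariate table from [simulate_covariates()]
#'   (rows aligned with samples).
#' @param covariate_effects optional named numeric vector of effects for
#'   covariate columns.
#' @param noise_sd standard deviation of the Gaussian noise.
#' @param seed integer seed.
#' @return `data.frame` with columns `sample_id`, `phenotype`, and `sex`
#'   (`"M"`/`"F"` when available, `NA` otherwise).
#' @export
simulate_cohort_phenotype <- function(genotypes, effects, covariates = NULL,
                                      covariate_effects = NULL,
                                      noise_sd = 1, seed) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  dos <- genotypes$dosage
  unknown <- setdiff(names(effects), colnames(dos))
  if (length(unknown)) {
    stop(sprintf("effects reference unknown variants: %s",
                 paste(unknown, collapse = ", ")))
  }
  n <- nrow(dos)
  set.seed(child_seed(seed, "simulate_cohort_phenotype"))
  y <- rep(0, n)
  if (length(effects)) {
    y <- y + as.vector(dos[, names(effects), drop = FALSE] %*% effects)
  }
  sex <- rep(NA_character_, n)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == n)
    if (!is.null(covariate_effects)) {
      for (nm in names(covariate_effects)) {
        y <- y + covariate_effects[[nm]] * covariates[[nm]]
      }
    }
    if ("sex" %in% names(covariates)) {
      sex <- ifelse(covariates$sex == 1, "M", "F")
    }
  }
  y <- y + stats::rnorm(n, sd = noise_sd)
  data.frame(sample_id = rownames(dos), phenotype = y, sex = sex,
             stringsAsFactors = FALSE)
}

#' Simulate RT-PCR gel band intensities
#'
#' Three band intensities per sample (intron-retained, exon-skip,
#' exon-include products) proportional to the per-sample splicing fractions,
#' with multiplicative log-normal noise of coefficient of variation
#' `noise_cv`. The log-normal is mean-corrected so expected intensity stays
#' proportional to the fraction.
#'
#' @param fractions numeric matrix, samples x 3, columns ordered
#'   (intron-retained, skip, include); each row must sum to 1 (tolerance
#'   1e-6).
#' @param intensity_scale expected total intensity per sample.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @return `data.frame` with columns `sample_id`, `band_170`, `band_196`,
#'   `band_274` (intron-retained, skip, and include products).
#' @export
simulate_gel_bands <- function(fractions, intensity_scale = 1000,
                               noise_cv = 0.1, seed) {
  fractions <- as.matrix(fractions)
  if (ncol(fractions) != 3L) stop("fractions must have 3 columns")
  if (intensity_scale <= 0) stop("intensity_scale must be positive")
  s <- rowSums(fractions)
  if (any(abs(s - 1) > 1e-6)) {
    stop("per-sample fractions must sum to 1 (tolerance 1e-6)")
  }
  n <- nrow(fractions)
  set.seed(child_seed(seed, "simulate_gel_bands"))
  base <- fractions * intensity_scale
  if (noise_cv > 0) {
    sdlog <- sqrt(log1p(noise_cv^2))
    noise <- matrix(stats::rlnorm(3L * n, meanlog = -sdlog^2 / 2,
                                  sdlog = sdlog), n, 3L)
    base <- base * noise
  }
  ids <- rownames(fractions) %||% sprintf("S%04d", seq_len(n))
  data.frame(sample_id = ids, band_170 = base[, 1L], band_196 = base[, 2L],
             band_274 = base[, 3L], stringsAsFactors = FALSE)
}
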