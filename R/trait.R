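#' Define a purely additive trait with given heritability
#'
#' Phenotypic variance is fixed at `sigma2_p` (1 by default) and partitioned
#' exactly into additive genetic variance `h2 * sigma2_p` and residual
#' variance `(1 - h2) * sigma2_p`.
#'
#' @param h2 narrow-sense heritability, strictly inside (0, 1).
#' @param sigma2_p phenotypic variance.
#' @return An object of class `trait_model` (no QTL effects yet; see
#'   [sample_qtl_effects()]).
#' @export
trait_model <- function(h2, sigma2_p = 1) {
  if (!is.numeric(h2) || length(h2) != 1 || h2 <= 0 || h2 >= 1)
    stop_bad_arg("h2 must lie strictly inside (0, 1)")
  if (sigma2_p <= 0) stop_bad_arg("sigma2_p must be positive")
  structure(list(h2 = h2, sigma2_p = sigma2_p,
                 sigma2_g = h2 * sigma2_p,
                 sigma2_e = (1 - h2) * sigma2_p,
                 gamma_shape = 0.4,
                 effects = NULL, base_mean = 0),
            class = "trait_model")
}

#' @exportS3Method base::print
print.trait_model <- function(x, ...) {
  cat("<trait_model> h2 = ", x$h2, ", sigma2_g = ", x$sigma2_g,
      ", sigma2_e = ", x$sigma2_e,
      if (is.null(x$effects)) " (effects not sampled)" else
        paste0(", ", ncol(x$effects), " QTL"), "\n", sep = "")
  invisible(x)
}

qtl_rows <- function(genome) which(genome$loci$type == "qtl")

#' Sample additive QTL allele effects and standardize the genetic variance
#'
#' Each QTL allele receives its own additive effect: a gamma(shape 0.4) draw
#' with a random sign.  All effects are then rescaled by a single constant so
#' that the variance of the true breeding value (TBV) in the supplied cohort
#' -- by convention the founders of the selected recent generations -- equals
#' `h2 * sigma2_p`.  TBVs are centred at the cohort mean.
#'
#' @param genome finalized `genome_map` containing the QTL panel.
#' @param pool `haplotype_pool` of the standardization cohort.
#' @param h2 heritability, or a `trait_model`.
#' @param seed integer seed for the effect draws.
#' @return A `trait_model` with the scaled `effects` matrix (4 x n_qtl,
#'   rows = allele codes) and the cohort `base_mean`.
#' @export
sample_qtl_effects <- function(genome, pool, h2, seed = 1L) {
  model <- if (inherits(h2, "trait_model")) h2 else trait_model(h2)
  qidx <- qtl_rows(genome)
  if (length(qidx) == 0) stop_bad_arg("genome has no QTL")
  na <- genome$loci$n_alleles[qidx]
  eff <- with_seed(seed, {
    e <- matrix(0, 4, length(qidx))
    for (j in seq_along(qidx)) {
      k <- na[j]
      e[seq_len(k), j] <- rgamma(k, shape = model$gamma_shape) *
        sample(c(-1, 1), k, replace = TRUE)
    }
    e
  })
  raw <- cpp_tbv(pool$haps, seq_len(pool$n) - 1L, as.integer(qidx - 1L),
                 eff, as.integer(na))
  v <- var(raw)
  if (!is.finite(v) || v <= 0)
    stop_bad_arg("zero genetic variance before scaling: all QTL are ",
                 "monomorphic in the standardization cohort")
  sc <- sqrt(model$sigma2_g / v)
  model$effects <- eff * sc
  model$qtl_n_alleles <- as.integer(na)
  model$base_mean <- mean(raw) * sc
  model
}

#' True breeding value of individuals
#'
#' The TBV is the sum over QTL of the effects of the two carried alleles,
#' centred at the standardization-cohort mean.  It is simulation truth and is
#' never visible to the evaluation models.
#'
#' @param pool `haplotype_pool` (or `population` haplotypes) carrying the QTL.
#' @param model a `trait_model` with sampled effects.
#' @param ind individuals to score (default all).
#' @param genome genome map matching `pool` (default `pool$genome`).
#' @return Numeric vector of TBVs.
#' @export
true_breeding_value <- function(pool, model, ind = seq_len(pool$n),
                                genome = pool$genome) {
  if (is.null(model$effects)) stop_bad_arg("model has no sampled effects")
  qidx <- qtl_rows(genome)
  cpp_tbv(pool$haps, as.integer(ind - 1L), as.integer(qidx - 1L),
          model$effects, model$qtl_n_alleles) - model$base_mean
}

#' Simulate phenotypes from true breeding values
#'
#' `y = mu + TBV + e`, `e ~ N(0, sigma2_e)`; the overall mean `mu` is 0.
#'
#' @param tbv numeric vector of true breeding values.
#' @param model a `trait_model`.
#' @param seed integer seed for the residual draw.
#' @return Numeric phenotype vector.
#' @export
make_phenotype <- function(tbv, model, seed = 1L) {
  with_seed(seed, tbv + rnorm(length(tbv), 0, sqrt(model$sigma2_e)))
}
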