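#' Specification of the recent-generation breeding scheme
#'
#' Defaults follow a large national beef-cattle nucleus: 275 founder sires and
#' 2,475 founder dams, ten discrete generations with one offspring per dam,
#' 50% male ratio, truncation replacement of 60% of sires and 20% of dams per
#' generation ranked on the selection criterion (own phenotype or pedigree-BLUP
#' EBV), and a 5% rate of independently missing sire/dam records in the
#' recorded pedigree.
#'
#' @param n_founder_males,n_founder_females founder counts drawn from the
#'   expanded population.
#' @param n_generations number of selected generations.
#' @param offspring_per_dam litter size (1).
#' @param male_ratio probability that an offspring is male.
#' @param sire_replacement,dam_replacement replacement ratios.
#' @param missing_parent_rate per-parent probability that a recorded sire or
#'   dam field is missing.
#' @param selection_method `"phenotype"`, `"ebv"`, or `"random"`.
#' @param geno_missing_rate,geno_error_rate marker-genotype missingness and
#'   genotyping-error rates applied when genotypes are extracted.
#' @param mutation_rate recurrent per-locus per-gamete mutation rate.
#' @return An object of class `scheme_spec`.
#' @export
scheme_spec <- function(n_founder_males = 275L, n_founder_females = 2475L,
                        n_generations = 10L, offspring_per_dam = 1L,
                        male_ratio = 0.5,
                        sire_replacement = 0.60, dam_replacement = 0.20,
                        missing_parent_rate = 0.05,
                        selection_method = c("phenotype", "ebv", "random"),
                        geno_missing_rate = 0.01, geno_error_rate = 0.005,
                        mutation_rate = 1e-5) {
  structure(list(
    n_founder_males = check_count(n_founder_males, "n_founder_males", 1),
    n_founder_females = check_count(n_founder_females, "n_founder_females", 1),
    n_generations = check_count(n_generations, "n_generations"),
    offspring_per_dam = check_count(offspring_per_dam, "offspring_per_dam", 1),
    male_ratio = check_fraction(male_ratio, "male_ratio"),
    sire_replacement = check_fraction(sire_replacement, "sire_replacement"),
    dam_replacement = check_fraction(dam_replacement, "dam_replacement"),
    missing_parent_rate = check_fraction(missing_parent_rate, "missing_parent_rate"),
    selection_method = match.arg(selection_method),
    geno_missing_rate = check_fraction(geno_missing_rate, "geno_missing_rate"),
    geno_error_rate = check_fraction(geno_error_rate, "geno_error_rate"),
    mutation_rate = check_fraction(mutation_rate, "mutation_rate")),
    class = "scheme_spec")
}

#' Expand the historical population by random mating
#'
#' Starting from the (typically 100 + 100) historical survivors, runs
#' `n_generations` of discrete random mating in which every dam produces
#' `offspring_per_dam` offspring with a sire drawn uniformly per offspring.
#' Once a generation would exceed `target_size`, dams are subsampled so the
#' generation size stays at the cap.
#'
#' @param founders `haplotype_pool` with a `sex` vector containing both sexes.
#' @param genome genome map of the pool's loci.
#' @param n_generations number of expansion generations (20).
#' @param offspring_per_dam litter size (5).
#' @param target_size population cap (10,000).
#' @param mutation_rate recurrent mutation rate.
#' @param seed integer seed.
#' @return A `haplotype_pool` (with sexes) holding the final expanded
#'   generation.
#' @export
expand_population <- function(founders, genome = founders$genome,
                              n_generations = 20L, offspring_per_dam = 5L,
                              target_size = 10000L, mutation_rate = 1e-5,
                              seed = 1L) {
  n_generations <- check_count(n_generations, "n_generations")
  offspring_per_dam <- check_count(offspring_per_dam, "offspring_per_dam", 1)
  if (!any(founders$sex == "M") || !any(founders$sex == "F"))
    stop_bad_arg("founder pool must contain both sexes")
  co <- chrom_offsets(genome)
  with_seed(seed, {
    H <- founders$haps
    sex <- founders$sex
    for (g in seq_len(n_generations)) {
      males <- which(sex == "M")
      dams <- which(sex == "F")
      if (length(males) == 0 || length(dams) == 0)
        stop_bad_arg("a sex died out during expansion (generation ", g, ")")
      if (!is.null(target_size) &&
          length(dams) * offspring_per_dam > target_size)
        dams <- sort(sample(dams, target_size %/% offspring_per_dam))
      dam_idx <- rep(dams, each = offspring_per_dam)
      sire_idx <- sample(males, length(dam_idx), replace = TRUE)
      out <- matrix(as.raw(0), nrow(H), 2 * length(dam_idx))
      cpp_drop(H, out, 0L, as.integer(sire_idx - 1L), as.integer(dam_idx - 1L),
               co, genome$loci$pos_cM, genome$chrom_length_cM,
               genome$loci$n_alleles, mutation_rate)
      H <- out
      sex <- ifelse(runif(length(dam_idx)) < 0.5, "M", "F")
    }
    new_haplotype_pool(H, genome, sex = sex)
  })
}

# internal view of a population's haplotypes as a pool (no copy)
pop_pool <- function(pop) {
  structure(list(haps = pop$haps, genome = pop$genome,
                 n = nrow(pop$ped), sex = pop$ped$sex),
            class = "haplotype_pool")
}

new_population <- function(ped, haps, genome, trait, spec, seeds) {
  structure(list(ped = ped, haps = haps, genome = genome, trait = trait,
                 spec = spec, seeds = seeds,
                 active_sires = integer(), active_dams = integer(),
                 sire_pool = list()),
            class = "population")
}

#' @exportS3Method base::print
print.population <- function(x, ...) {
  cat("<population> ", nrow(x$ped), " animals, generations 0-",
      max(x$ped$generation), ", selection = ", x$spec$selection_method,
      ", h2 = ", x$trait$h2, "\n", sep = "")
  invisible(x)
}

#' Extract the pedigree of a population
#'
#' @param pop a `population`.
#' @param which `"recorded"` (with missing-parent masking and any injected
#'   sire errors) or `"true"` (simulation truth).
#' @return A tibble with `id`, `sire`, `dam` (0 = unknown), `sex`,
#'   `generation`.
#' @export
pedigree <- function(pop, which = c("recorded", "true")) {
  which <- match.arg(which)
  p <- pop$ped
  if (which == "true")
    tibble::tibble(id = p$id, sire = p$sire, dam = p$dam,
                   sex = p$sex, generation = p$generation)
  else
    tibble::tibble(id = p$id, sire = p$rec_sire, dam = p$rec_dam,
                   sex = p$sex, generation = p$generation)
}

#' Phenotype table of a population
#'
#' The `tbv` column is simulation truth and must not be used as an input to
#' genetic evaluation.
#'
#' @param pop a `population`.
#' @return A tibble `id`, `generation`, `sex`, `phenotype`, `tbv`, `ebv`.
#' @export
phenotypes <- function(pop) {
  p <- pop$ped
  tibble::tibble(id = p$id, generation = p$generation, sex = p$sex,
                 phenotype = p$phenotype, tbv = p$tbv, ebv = p$ebv)
}

# rank ids by criterion with deterministic id tie-break
rank_ids <- function(ids, crit, decreasing = FALSE) {
  o <- if (decreasing) order(-crit, ids) else order(crit, ids)
  ids[o]
}

#' Advance a selected population by one generation
#'
#' Each active dam produces one litter of `offspring_per_dam` offspring with a
#' sire allocated uniformly at random among the active sires.  Offspring are
#' phenotyped at birth; their recorded sire and dam are each masked
#' independently with probability `missing_parent_rate`.  The bottom
#' `sire_replacement` fraction of active sires and `dam_replacement` fraction
#' of active dams -- ranked on the selection criterion with ties broken by
#' animal id -- are culled and replaced by the top-ranked same-sex offspring.
#' Non-replaced parents persist, giving an overlapping parent pool.
#'
#' @param pop a `population` (from [run_recent_generations()] internals or a
#'   previous call).
#' @param spec a [scheme_spec()] (default `pop$spec`).
#' @param trait trait model (default `pop$trait`).
#' @param evaluator function `pop -> named EBV vector` required when
#'   `selection_method == "ebv"`.
#' @param seed integer seed for this generation's randomness.
#' @return The updated `population`.
#' @export
advance_generation <- function(pop, spec = pop$spec, trait = pop$trait,
                               evaluator = NULL, seed = 1L) {
  if (spec$selection_method == "ebv" && is.null(evaluator))
    stop_bad_arg("selection_method = 'ebv' requires an evaluator")
  g <- max(pop$ped$generation) + 1L
  with_seed(seed, {
    dams <- pop$active_dams
    sires <- pop$active_sires
    dam_ids <- rep(dams, each = spec$offspring_per_dam)
    sire_ids <- sample(sires, length(dam_ids), replace = TRUE)
    n_off <- length(dam_ids)
    n0 <- nrow(pop$ped)
    ids <- n0 + seq_len(n_off)

    if (2 * (n0 + n_off) > ncol(pop$haps)) {
      # grow the preallocated haplotype store
      H2 <- matrix(as.raw(0), nrow(pop$haps), 2 * (n0 + n_off))
      H2[, seq_len(2 * n0)] <- pop$haps[, seq_len(2 * n0)]
      pop$haps <- H2
    }
    co <- chrom_offsets(pop$genome)
    cpp_drop(pop$haps, pop$haps, n0, as.integer(sire_ids - 1L),
             as.integer(dam_ids - 1L), co, pop$genome$loci$pos_cM,
             pop$genome$chrom_length_cM, pop$genome$loci$n_alleles,
             spec$mutation_rate)

    sex <- ifelse(runif(n_off) < spec$male_ratio, "M", "F")
    tmp_pool <- structure(list(haps = pop$haps, genome = pop$genome,
                               n = n0 + n_off), class = "haplotype_pool")
    tbv <- true_breeding_value(tmp_pool, trait, ind = ids)
    phen <- tbv + rnorm(n_off, 0, sqrt(trait$sigma2_e))
    rec_sire <- ifelse(runif(n_off) < spec$missing_parent_rate, 0L, sire_ids)
    rec_dam <- ifelse(runif(n_off) < spec$missing_parent_rate, 0L, dam_ids)

    pop$ped <- rbind(pop$ped, tibble::tibble(
      id = ids, sire = sire_ids, dam = dam_ids,
      rec_sire = as.integer(rec_sire), rec_dam = as.integer(rec_dam),
      sex = sex, generation = g, phenotype = phen, tbv = tbv,
      ebv = NA_real_))
    pop$sire_pool[[g]] <- sires

    crit <- switch(spec$selection_method,
      phenotype = pop$ped$phenotype,
      random = runif(nrow(pop$ped)),
      ebv = {
        e <- evaluator(pop)
        pop$ped$ebv <- as.numeric(e[as.character(pop$ped$id)])
        pop$ped$ebv
      })

    replace_group <- function(active, ratio, off_ids) {
      n_cull <- round(ratio * length(active))
      off_ranked <- rank_ids(off_ids, crit[off_ids], decreasing = TRUE)
      n_new <- min(n_cull, length(off_ranked))
      culled <- rank_ids(active, crit[active])[seq_len(n_new)]
      sort(c(setdiff(active, culled), off_ranked[seq_len(n_new)]))
    }
    pop$active_sires <- replace_group(sires, spec$sire_replacement,
                                      ids[sex == "M"])
    pop$active_dams <- replace_group(dams, spec$dam_replacement,
                                     ids[sex == "F"])
    pop
  })
}

#' Simulate the selected recent generations
#'
#' Draws the founder sires and dams from the expanded population, samples the
#' QTL effects standardized against that founder cohort, phenotypes the
#' founders, then runs `n_generations` of selective breeding via
#' [advance_generation()].  Under `"ebv"` selection the default evaluator is a
#' pedigree-BLUP animal model re-fitted each generation on all recorded
#' phenotypes to date, using the recorded (possibly masked) pedigree and the
#' known variance ratio.
#'
#' Marker genotypes are not stored with noise: the missingness
#' (`geno_missing_rate`) and genotyping-error (`geno_error_rate`) processes
#' are applied reproducibly whenever genotypes are extracted with
#' [get_genotypes()].
#'
#' @param expanded `haplotype_pool` from [expand_population()].
#' @param h2 heritability (or a `trait_model`).
#' @param spec a [scheme_spec()].
#' @param seed master seed; per-stage streams are derived with
#'   [seed_stream()].
#' @param evaluator optional EBV provider overriding the default
#'   pedigree-BLUP.
#' @param genome genome map (default `expanded$genome`).
#' @return A `population` covering generations 0 (founders) to
#'   `n_generations`.
#' @export
run_recent_generations <- function(expanded, h2, spec = scheme_spec(),
                                   seed = 1L, evaluator = NULL,
                                   genome = expanded$genome) {
  nfm <- spec$n_founder_males
  nff <- spec$n_founder_females
  males <- which(expanded$sex == "M")
  females <- which(expanded$sex == "F")
  if (length(males) < nfm || length(females) < nff)
    stop_bad_arg("expanded population too small for the founder draw: have ",
                 length(males), " males / ", length(females), " females, need ",
                 nfm, " / ", nff)
  founder_idx <- with_seed(seed_stream(seed, "founders"),
                           c(sample(males, nfm), sample(females, nff)))
  nf <- nfm + nff
  n_total <- nf + spec$n_generations * nff * spec$offspring_per_dam
  H <- matrix(as.raw(0), nrow(expanded$haps), 2 * n_total)
  H[, seq_len(2 * nf)] <- expanded$haps[, as.vector(rbind(2 * founder_idx - 1,
                                                          2 * founder_idx))]
  ped <- tibble::tibble(
    id = seq_len(nf), sire = 0L, dam = 0L, rec_sire = 0L, rec_dam = 0L,
    sex = rep(c("M", "F"), c(nfm, nff)), generation = 0L,
    phenotype = NA_real_, tbv = NA_real_, ebv = NA_real_)

  pop <- new_population(ped, H, genome, trait = NULL, spec = spec,
                        seeds = list(master = seed))
  cohort <- structure(list(haps = H, genome = genome, n = nf),
                      class = "haplotype_pool")
  trait <- sample_qtl_effects(genome, cohort, h2,
                              seed = seed_stream(seed, "effects"))
  pop$trait <- trait
  pop$ped$tbv <- true_breeding_value(cohort, trait)
  pop$ped$phenotype <- make_phenotype(pop$ped$tbv, trait,
                                      seed = seed_stream(seed, "noise"))
  pop$active_sires <- which(pop$ped$sex == "M")
  pop$active_dams <- which(pop$ped$sex == "F")
  pop$geno_seed <- seed_stream(seed, "genotype-noise")

  if (spec$selection_method == "ebv" && is.null(evaluator))
    evaluator <- pblup_evaluator(trait)
  for (g in seq_len(spec$n_generations))
    pop <- advance_generation(pop, spec, trait, evaluator,
                              seed = seed_stream(seed, paste0("breeding-", g)))
  pop
}

#' Extract observed marker dosages for a set of animals
#'
#' Dosages (0/1/2 copies of the second allele) are read off the true
#' haplotypes, then passed through the genotyping observation model: with
#' probability `geno_error_rate` a dosage is replaced by one of the other two
#' dosage values uniformly, and with probability `geno_missing_rate` it is set
#' missing (`NA`).  Noise is deterministic per animal (seeded from the
#' population's genotype-noise stream and the animal id), so the same animal
#' always shows the same observed genotypes regardless of the subset
#' extracted.
#'
#' @param pop a `population`.
#' @param ids animal ids to genotype.
#' @param missing_rate,error_rate override the rates in `pop$spec`.
#' @return Integer matrix (animals x markers) with `NA` for missing calls;
#'   rownames are animal ids.
#' @export
get_genotypes <- function(pop, ids,
                          missing_rate = pop$spec$geno_missing_rate,
                          error_rate = pop$spec$geno_error_rate) {
  mk <- which(pop$genome$loci$type == "marker")
  M <- cpp_dosages(pop$haps, as.integer(ids - 1L), as.integer(mk - 1L))
  m <- ncol(M)
  if (error_rate > 0 || missing_rate > 0) {
    base <- pop$geno_seed %||% 0L
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    for (i in seq_along(ids)) {
      set.seed((base + ids[i]) %% 2147483647)
      k_err <- stats::rbinom(1, m, error_rate)
      if (k_err > 0) {
        pos <- sample.int(m, k_err)
        M[i, pos] <- (M[i, pos] + sample(1:2, k_err, replace = TRUE)) %% 3L
      }
      k_mis <- stats::rbinom(1, m, missing_rate)
      if (k_mis > 0) M[i, sample.int(m, k_mis)] <- NA_integer_
    }
  }
  dimnames(M) <- list(ids, pop$genome$loci$locus_id[mk])
  M
}

`%||%` <- function(a, b) if (is.null(a)) b else a
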