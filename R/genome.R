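#' Build a genome map of evenly spaced markers and randomly placed QTL
#'
#' The simulated genome mirrors the bovine autosomes: `n_chromosomes` pairs of
#' equal genetic length summing to `total_length_cM` (29 chromosomes, 2,349 cM
#' by default, i.e. 81 cM each).  Markers are neutral, bi-allelic and evenly
#' spaced within each chromosome, with per-chromosome counts proportional to
#' chromosome length; QTL positions are drawn uniformly at random and each QTL
#' carries 2 to 4 alleles.  Marker and QTL positions are disjoint.
#'
#' Even spacing places the `k` markers of a chromosome of length `L` at
#' `(i - 0.5) * L / k`, so a single marker sits at the chromosome midpoint.
#'
#' @param n_markers total number of markers across the genome.
#' @param n_qtl total number of QTL across the genome.
#' @param seed integer seed for the random QTL placement and allele counts.
#' @param n_chromosomes number of chromosomes.
#' @param total_length_cM total genome length in centiMorgans.
#' @return An object of class `genome_map`: a list with `n_chromosomes`,
#'   `chrom_length_cM`, and a tibble `loci` (columns `chrom`, `pos_cM`,
#'   `locus_id`, `type`, `n_alleles`) ordered by chromosome and position.
#' @examples
#' gm <- build_genome_map(n_markers = 290, n_qtl = 29, seed = 1)
#' gm$chrom_length_cM[1]  # 81 cM
#' @export
build_genome_map <- function(n_markers, n_qtl, seed = 1L,
                             n_chromosomes = 29L, total_length_cM = 2349) {
  n_markers <- check_count(n_markers, "n_markers")
  n_qtl <- check_count(n_qtl, "n_qtl")
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes", min = 1)
  len <- rep(total_length_cM / n_chromosomes, n_chromosomes)

  # per-chromosome counts proportional to length (equal lengths: as equal as
  # integers allow, remainder assigned to the first chromosomes)
  split_counts <- function(n) {
    base <- n %/% n_chromosomes
    extra <- n %% n_chromosomes
    base + c(rep(1L, extra), rep(0L, n_chromosomes - extra))
  }
  mk <- split_counts(n_markers)
  qk <- split_counts(n_qtl)

  loci <- with_seed(seed, {
    out <- vector("list", n_chromosomes)
    for (c in seq_len(n_chromosomes)) {
      mpos <- if (mk[c] > 0) (seq_len(mk[c]) - 0.5) * len[c] / mk[c] else numeric()
      qpos <- runif(qk[c], 0, len[c])
      while (anyDuplicated(c(mpos, qpos))) qpos <- runif(qk[c], 0, len[c])
      qall <- if (qk[c] > 0) sample(2:4, qk[c], replace = TRUE) else integer()
      df <- data.frame(
        chrom = rep(c, mk[c] + qk[c]),
        pos_cM = c(mpos, qpos),
        type = rep(c("marker", "qtl"), c(mk[c], qk[c])),
        n_alleles = c(rep(2L, mk[c]), qall))
      out[[c]] <- df[order(df$pos_cM), ]
    }
    do.call(rbind, out)
  })
  loci$locus_id <- sprintf("L%d_%d", loci$chrom,
                           as.integer(stats::ave(loci$chrom, loci$chrom,
                                                 FUN = seq_along)))
  rownames(loci) <- NULL
  structure(list(n_chromosomes = n_chromosomes,
                 chrom_length_cM = len,
                 loci = tibble::as_tibble(loci[, c("chrom", "pos_cM", "locus_id",
                                                   "type", "n_alleles")])),
            class = "genome_map")
}

#' @exportS3Method base::print
print.genome_map <- function(x, ...) {
  cat("<genome_map> ", x$n_chromosomes, " chromosomes, ",
      sum(x$chrom_length_cM), " cM, ",
      sum(x$loci$type == "marker"), " markers, ",
      sum(x$loci$type == "qtl"), " QTL\n", sep = "")
  invisible(x)
}

# 0-based locus offsets per chromosome for the compiled engine
chrom_offsets <- function(genome) {
  cnt <- tabulate(genome$loci$chrom, nbins = genome$n_chromosomes)
  as.integer(cumsum(c(0L, cnt)))
}

#' Specification of the historical population phase
#'
#' The historical phase establishes linkage disequilibrium and mutation--drift
#' equilibrium before any selection is applied: `phase1_generations` of random
#' union of gametes at constant size `phase1_size`, followed by a
#' `phase2_generations`-long bottleneck at `phase2_final_size` that inflates
#' short-range LD to cattle-like levels.
#'
#' @param phase1_generations,phase1_size constant-size phase (1,000 x 1,000).
#' @param phase2_generations,phase2_final_size bottleneck phase (95
#'   generations at size 200).
#' @param mutation_rate recurrent per-locus per-gamete mutation probability.
#' @param shrink profile of the reduction: `"step"` (default) holds all
#'   phase-2 generations at `phase2_final_size`, the bottleneck that
#'   generates cattle-like short-range LD; `"linear"` interpolates the size
#'   from `phase1_size` down to `phase2_final_size` across phase 2 instead.
#' @return An object of class `historical_spec`.
#' @export
historical_spec <- function(phase1_generations = 1000L, phase1_size = 1000L,
                            phase2_generations = 95L, phase2_final_size = 200L,
                            mutation_rate = 1e-5,
                            shrink = c("step", "linear")) {
  s <- list(phase1_generations = check_count(phase1_generations, "phase1_generations"),
            phase1_size = check_count(phase1_size, "phase1_size", min = 2),
            phase2_generations = check_count(phase2_generations, "phase2_generations"),
            phase2_final_size = check_count(phase2_final_size, "phase2_final_size", min = 2),
            mutation_rate = check_fraction(mutation_rate, "mutation_rate"),
            shrink = match.arg(shrink))
  if (s$phase2_final_size > s$phase1_size)
    stop_bad_arg("phase2_final_size must not exceed phase1_size")
  structure(s, class = "historical_spec")
}

# generation sizes for the whole historical phase
historical_sizes <- function(spec) {
  p1 <- rep(spec$phase1_size, spec$phase1_generations)
  if (spec$phase2_generations == 0) return(as.integer(p1))
  p2 <- if (spec$shrink == "step") {
    rep(spec$phase2_final_size, spec$phase2_generations)
  } else {
    t <- seq_len(spec$phase2_generations)
    round(spec$phase1_size -
            (spec$phase1_size - spec$phase2_final_size) * t / spec$phase2_generations)
  }
  as.integer(c(p1, p2))
}

new_haplotype_pool <- function(haps, genome, sex = NULL) {
  n <- ncol(haps) / 2
  if (is.null(sex)) sex <- rep_len(c("M", "F"), n)
  structure(list(haps = haps, genome = genome, n = as.integer(n), sex = sex),
            class = "haplotype_pool")
}

#' @exportS3Method base::print
print.haplotype_pool <- function(x, ...) {
  cat("<haplotype_pool> ", x$n, " individuals x ", nrow(x$haps), " loci\n", sep = "")
  invisible(x)
}

# Founder haplotypes: markers Bernoulli(1/2), QTL uniform over allele codes.
founder_haplotypes <- function(genome, n_ind) {
  L <- nrow(genome$loci)
  na <- genome$loci$n_alleles
  H <- matrix(as.raw(0), L, 2 * n_ind)
  for (h in seq_len(2 * n_ind))
    H[, h] <- as.raw(floor(runif(L) * na))
  H
}

#' Simulate the historical population
#'
#' Runs discrete generations of random union of gametes (two distinct parents
#' drawn uniformly per offspring) with Poisson-crossover meiosis (Haldane, no
#' interference) and recurrent symmetric mutation, through the constant-size
#' phase and the bottleneck, and returns the final generation.  Sex is
#' assigned by alternation so the final generation is half male, half female.
#'
#' With both phase lengths zero the founder pool is returned unchanged.
#'
#' @param spec a [historical_spec()].
#' @param genome a [build_genome_map()] result (normally an over-dense
#'   candidate map; see [select_panels()]).
#' @param seed integer seed.
#' @return A `haplotype_pool` holding the final historical generation.
#' @export
simulate_historical <- function(spec, genome, seed = 1L) {
  stopifnot(inherits(spec, "historical_spec"), inherits(genome, "genome_map"))
  if (nrow(genome$loci) == 0) stop_bad_arg("genome has no loci")
  sizes <- historical_sizes(spec)
  with_seed(seed, {
    H <- founder_haplotypes(genome, spec$phase1_size)
    if (length(sizes) > 0)
      H <- cpp_historical(H, sizes, chrom_offsets(genome),
                          genome$loci$pos_cM, genome$chrom_length_cM,
                          genome$loci$n_alleles, spec$mutation_rate)
    new_haplotype_pool(H, genome)
  })
}

#' Per-locus allele frequencies of a haplotype pool
#'
#' @param pool a `haplotype_pool`.
#' @param ind optional integer vector of individuals (default all).
#' @return A 4 x n_loci matrix of allele frequencies (rows = allele codes
#'   0..3); columns sum to 1.
#' @export
allele_frequencies <- function(pool, ind = seq_len(pool$n)) {
  cnt <- cpp_allele_counts(pool$haps, as.integer(ind - 1L), 4L)
  cnt / (2 * length(ind))
}

# minimum frequency among alleles actually present; NA when fixed
min_present_freq <- function(freqs) {
  apply(freqs, 2, function(f) {
    f <- f[f > 0]
    if (length(f) < 2) NA_real_ else min(f)
  })
}

#' Select the final marker and QTL panels from a candidate pool
#'
#' The historical phase is run on an over-dense candidate map; after the
#' bottleneck this operation picks the final panels.  Markers: for each
#' chromosome, the `n` segregating bi-allelic candidates with minor allele
#' frequency at least `marker_maf_min` that lie closest to the even-spacing
#' grid (left to right, keeping positions increasing).  QTL: `n_qtl` loci
#' sampled uniformly among candidates that still segregate with at least two
#' alleles and minimum present-allele frequency at least `qtl_maf_min`.
#'
#' @param pool `haplotype_pool` from [simulate_historical()].
#' @param genome the candidate `genome_map` (defaults to `pool$genome`).
#' @param n_markers,n_qtl final panel sizes.
#' @param marker_maf_min,qtl_maf_min frequency thresholds (0.1 and 0.01).
#' @param seed seed for the random QTL draw.
#' @return A finalized `genome_map` whose `loci` tibble carries a `pool_idx`
#'   column pointing into the candidate pool's locus rows.
#' @export
select_panels <- function(pool, genome = pool$genome, n_markers, n_qtl,
                          marker_maf_min = 0.1, qtl_maf_min = 0.01, seed = 1L) {
  n_markers <- check_count(n_markers, "n_markers")
  n_qtl <- check_count(n_qtl, "n_qtl")
  check_fraction(marker_maf_min, "marker_maf_min")
  check_fraction(qtl_maf_min, "qtl_maf_min")
  freqs <- allele_frequencies(pool)
  minf <- min_present_freq(freqs)
  loci <- pool$genome$loci
  is_mk <- loci$type == "marker"
  mk_ok <- is_mk & !is.na(minf) & minf >= marker_maf_min
  qt_ok <- !is_mk & !is.na(minf) & minf >= qtl_maf_min

  nc <- genome$n_chromosomes
  base <- n_markers %/% nc
  extra <- n_markers %% nc
  per_chrom <- base + c(rep(1L, extra), rep(0L, nc - extra))

  sel_mk <- integer()
  shortfall <- character()
  for (c in seq_len(nc)) {
    k <- per_chrom[c]
    if (k == 0) next
    cand <- which(mk_ok & loci$chrom == c)
    if (length(cand) < k) {
      shortfall <- c(shortfall, sprintf("chromosome %d: need %d, have %d",
                                        c, k, length(cand)))
      next
    }
    L <- genome$chrom_length_cM[c]
    grid <- (seq_len(k) - 0.5) * L / k
    pos <- loci$pos_cM[cand]
    take <- integer(k)
    ptr <- 1L
    for (i in seq_len(k)) {
      lo <- ptr
      hi <- length(cand) - (k - i)    # leave enough candidates for later points
      win <- lo:hi
      j <- win[which.min(abs(pos[win] - grid[i]))]
      take[i] <- cand[j]
      ptr <- j + 1L
    }
    sel_mk <- c(sel_mk, take)
  }
  if (length(shortfall) > 0)
    stop_bad_arg("insufficient segregating markers passing MAF >= ",
                 marker_maf_min, ":\n  ", paste(shortfall, collapse = "\n  "))

  qt_cand <- which(qt_ok)
  if (length(qt_cand) < n_qtl)
    stop_bad_arg("insufficient segregating QTL passing MAF >= ", qtl_maf_min,
                 ": need ", n_qtl, ", have ", length(qt_cand))
  sel_qt <- with_seed(seed, sort(sample(qt_cand, n_qtl)))

  idx <- sort(c(sel_mk, sel_qt))
  out <- loci[idx, ]
  out$pool_idx <- idx
  structure(list(n_chromosomes = genome$n_chromosomes,
                 chrom_length_cM = genome$chrom_length_cM,
                 loci = out),
            class = "genome_map")
}

#' Restrict a haplotype pool to the loci of a finalized panel
#'
#' @param pool a `haplotype_pool` over the candidate map.
#' @param panel a finalized `genome_map` from [select_panels()].
#' @return A `haplotype_pool` over the panel loci only.
#' @export
finalize_pool <- function(pool, panel) {
  stopifnot(!is.null(panel$loci$pool_idx))
  H <- pool$haps[panel$loci$pool_idx, , drop = FALSE]
  panel$loci$pool_idx <- NULL
  new_haplotype_pool(H, panel, sex = pool$sex)
}
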