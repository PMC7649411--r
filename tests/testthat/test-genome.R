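test_that("genome map geometry: equal chromosomes, even spacing, disjoint panels", {
  gm <- build_genome_map(10000, 725, seed = 1)
  expect_equal(gm$n_chromosomes, 29L)
  expect_equal(sum(gm$chrom_length_cM), 2349)
  expect_true(all(abs(gm$chrom_length_cM - 2349 / 29) < 1e-12))

  loci <- gm$loci
  mk <- loci[loci$type == "marker", ]
  qt <- loci[loci$type == "qtl", ]
  expect_equal(nrow(mk), 10000L)
  expect_equal(nrow(qt), 725L)
  expect_true(all(qt$n_alleles %in% 2:4))
  # strictly increasing, evenly spaced markers within every chromosome
  for (c in c(1, 15, 29)) {
    p <- mk$pos_cM[mk$chrom == c]
    expect_true(all(diff(p) > 0))
    expect_lt(diff(range(diff(p))), 1e-9)
  }
  # QTL inside [0, length] and disjoint from marker positions
  expect_true(all(qt$pos_cM >= 0 & qt$pos_cM <= 2349 / 29))
  expect_equal(anyDuplicated(paste(loci$chrom, loci$pos_cM)), 0L)
})

test_that("genome map edge cases: single marker at midpoint, empty panel, bad input", {
  gm1 <- build_genome_map(29, 0, seed = 1)
  expect_true(all(abs(gm1$loci$pos_cM - (2349 / 29) / 2) < 1e-9))
  gm0 <- build_genome_map(0, 50, seed = 1)
  expect_equal(sum(gm0$loci$type == "marker"), 0L)
  expect_equal(sum(gm0$loci$type == "qtl"), 50L)
  expect_error(build_genome_map(-1, 10), "n_markers")
})

test_that("zero historical generations return the founder pool unchanged", {
  gm <- build_genome_map(100, 10, seed = 2)
  spec <- historical_spec(0L, 100L, 0L, 100L, mutation_rate = 0)
  p1 <- simulate_historical(spec, gm, seed = 5)
  p2 <- simulate_historical(spec, gm, seed = 5)
  expect_equal(p1$n, 100L)
  expect_identical(p1$haps, p2$haps)
  f <- allele_frequencies(p1)
  expect_true(all(abs(colSums(f) - 1) < 1e-12))
  # founder markers start near p = 0.5
  mk <- p1$genome$loci$type == "marker"
  expect_lt(abs(mean(f[2, mk]) - 0.5), 0.05)
})

test_that("meiosis conserves parental alleles when mutation is off", {
  gm <- build_genome_map(200, 40, seed = 3)
  spec <- historical_spec(0L, 20L, 0L, 20L)
  pool <- simulate_historical(spec, gm, seed = 9)
  n_off <- 50L
  out <- matrix(as.raw(0), nrow(pool$haps), 2 * n_off)
  withr::with_seed(4, {
    sire <- sample(20, n_off, replace = TRUE)
    dam <- sample(20, n_off, replace = TRUE)
    gblupsim:::cpp_drop(pool$haps, out, 0L, as.integer(sire - 1), as.integer(dam - 1),
                        gblupsim:::chrom_offsets(gm), gm$loci$pos_cM,
                        gm$chrom_length_cM, gm$loci$n_alleles, 0)
  })
  for (o in seq_len(n_off)) {
    sg <- out[, 2 * o - 1]
    h <- pool$haps[, c(2 * sire[o] - 1, 2 * sire[o])]
    expect_true(all(sg == h[, 1] | sg == h[, 2]))
    dg <- out[, 2 * o]
    h <- pool$haps[, c(2 * dam[o] - 1, 2 * dam[o])]
    expect_true(all(dg == h[, 1] | dg == h[, 2]))
  }
})

test_that("crossover counts per chromosome follow Poisson(length in Morgans)", {
  # a fully heterozygous parent makes crossovers visible as allele switches
  gm <- build_genome_map(0, 0, seed = 1, n_chromosomes = 1, total_length_cM = 81)
  loci <- data.frame(chrom = 1L, pos_cM = seq(0.05, 80.95, length.out = 1000),
                     locus_id = sprintf("L%d", 1:1000), type = "marker",
                     n_alleles = 2L)
  gm$loci <- tibble::as_tibble(loci)
  H <- matrix(as.raw(0), 1000, 2)
  H[, 2] <- as.raw(1)
  n_mei <- 10000L
  out <- matrix(as.raw(0), 1000, 2 * n_mei)
  withr::with_seed(11, gblupsim:::cpp_drop(
    H, out, 0L, rep(0L, n_mei), rep(0L, n_mei),
    gblupsim:::chrom_offsets(gm), gm$loci$pos_cM, gm$chrom_length_cM,
    gm$loci$n_alleles, 0))
  switches <- colSums(out[-1, seq(1, 2 * n_mei, 2), drop = FALSE] !=
                        out[-1000, seq(1, 2 * n_mei, 2), drop = FALSE])
  lam <- 0.81
  expect_lt(abs(mean(switches) - lam), 3 * sqrt(lam / n_mei))
  # chi-square goodness of fit on 0,1,2,3+ crossovers
  obs <- c(sum(switches == 0), sum(switches == 1), sum(switches == 2),
           sum(switches >= 3))
  p <- c(dpois(0:2, lam), 1 - ppois(2, lam))
  chi <- sum((obs - n_mei * p)^2 / (n_mei * p))
  expect_lt(chi, qchisq(0.999, df = 3))
})

test_that("heterozygosity decays at the Wright-Fisher rate (drift oracle)", {
  gm <- build_genome_map(200, 0, seed = 6, n_chromosomes = 2,
                         total_length_cM = 200)
  spec <- historical_spec(200L, 50L, 0L, 50L, mutation_rate = 0)
  hets <- vapply(1:20, function(r) {
    pool <- simulate_historical(spec, gm, seed = 100 + r)
    f <- allele_frequencies(pool)[2, ]
    mean(2 * f * (1 - f))
  }, 0)
  # founders are Bernoulli(1/2): E[H0] = 0.5 (for 2N=100 draws, tiny bias)
  h0 <- 0.5 * (1 - 1 / 100)
  expected <- h0 * (1 - 1 / 100)^200
  se <- sd(hets) / sqrt(length(hets))
  expect_lt(abs(mean(hets) - expected), 3 * se)
})

test_that("bottleneck generates LD that decays with distance", {
  pool <- cache_get("ld_pool", function() {
    sc <- reduced_scale()
    cand <- build_genome_map(4000, 290, seed = 21)
    simulate_historical(sc$hp, cand, seed = 22)
  })
  panel <- select_panels(pool, n_markers = 2000, n_qtl = 145, seed = 23)
  base <- finalize_pool(pool, panel)
  mk <- which(base$genome$loci$type == "marker")
  M <- gblupsim:::cpp_dosages(base$haps, 0:(base$n - 1), as.integer(mk - 1))
  chrom <- base$genome$loci$chrom[mk]
  r2 <- function(gap) {
    v <- vapply(seq_len(ncol(M) - gap), function(j) {
      if (chrom[j] != chrom[j + gap]) return(NA_real_)
      suppressWarnings(stats::cor(M[, j], M[, j + gap])^2)
    }, 0)
    mean(v, na.rm = TRUE)
  }
  expect_gt(r2(1), r2(10))
})

test_that("panel selection equals a brute-force MAF filter", {
  n <- 50
  withr::with_seed(32, {
    p_true <- runif(100, 0, 0.5)
    H <- matrix(as.raw(0), 100, 2 * n)
    for (l in 1:100) H[l, ] <- as.raw(runif(2 * n) < p_true[l])
  })
  gm1 <- build_genome_map(50, 0, seed = 31, n_chromosomes = 1,
                          total_length_cM = 50)
  pool1 <- manual_pool(gm1, H[1:50, ])
  f1 <- allele_frequencies(pool1)
  elig1 <- which(pmin(f1[1, ], f1[2, ]) >= 0.1 & f1[1, ] > 0 & f1[2, ] > 0)
  sel <- select_panels(pool1, n_markers = length(elig1), n_qtl = 0,
                       marker_maf_min = 0.1, seed = 1)
  expect_equal(sel$loci$pool_idx, elig1)
  # threshold 0: every segregating locus is eligible
  seg <- which(f1[1, ] > 0 & f1[2, ] > 0)
  sel0 <- select_panels(pool1, n_markers = length(seg), n_qtl = 0,
                        marker_maf_min = 0, seed = 1)
  expect_equal(sel0$loci$pool_idx, seg)
  # asking for more than available names the shortfall
  expect_error(select_panels(pool1, n_markers = length(seg) + 1, n_qtl = 0,
                             marker_maf_min = 0, seed = 1),
               "insufficient segregating markers")
})

test_that("QTL panel draws the requested count among eligible loci", {
  pool <- cache_get("ld_pool", function() {
    sc <- reduced_scale()
    cand <- build_genome_map(4000, 290, seed = 21)
    simulate_historical(sc$hp, cand, seed = 22)
  })
  panel <- select_panels(pool, n_markers = 2000, n_qtl = 145, seed = 23)
  expect_equal(sum(panel$loci$type == "qtl"), 145L)
  f <- allele_frequencies(pool)
  minf <- gblupsim:::min_present_freq(f)
  qsel <- panel$loci$pool_idx[panel$loci$type == "qtl"]
  expect_true(all(minf[qsel] >= 0.01))
})
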