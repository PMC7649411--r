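# Shared fixtures, built once per session and memoized.

sim_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (!exists(key, envir = sim_cache, inherits = FALSE))
    assign(key, build(), envir = sim_cache)
  get(key, envir = sim_cache, inherits = FALSE)
}

# miniature preset for structural tests (seconds, not minutes)
tiny_scale <- function(...) {
  reduced_scale(hp = historical_spec(60L, 120L, 20L, 60L),
                expansion_generations = 6L, expansion_cap = 900L,
                n_founder_males = 25L, n_founder_females = 150L,
                n_validation = 25L, n_qtl = 60L, ...)
}

tiny_expanded <- function() cache_get("tiny_expanded", function()
  simulate_expanded(600, tiny_scale(), seed = 99))

tiny_pop <- function(selection = "phenotype", h2 = 0.3) {
  key <- paste0("tiny_pop_", selection, "_", h2)
  cache_get(key, function()
    simulate_population(600, selection, h2, tiny_scale(), seed = 99,
                        expanded = tiny_expanded()))
}

# reduced-scale base simulation used by the heavier evaluation tests
small_expanded <- function() cache_get("small_expanded", function()
  simulate_expanded(2000, reduced_scale(), seed = 42))

small_pop <- function(selection = "phenotype", h2 = 0.3) {
  key <- paste0("small_pop_", selection, "_", h2)
  cache_get(key, function()
    simulate_population(2000, selection, h2, reduced_scale(), seed = 42,
                        expanded = small_expanded()))
}

# random valid pedigree: founders then animals with random earlier parents
random_pedigree <- function(n, n_founders = 10, p_unknown = 0.1, seed = 1) {
  withr::with_seed(seed, {
    sire <- dam <- integer(n)
    for (i in (n_founders + 1):n) {
      pool <- seq_len(i - 1)
      pick <- sample(pool, 2)
      sire[i] <- if (runif(1) < p_unknown) 0L else pick[1]
      dam[i] <- if (runif(1) < p_unknown) 0L else pick[2]
    }
    data.frame(id = seq_len(n), sire = sire, dam = dam)
  })
}

# hand-buildable haplotype pool over a given genome map
manual_pool <- function(genome, haps) {
  storage.mode(haps) <- "raw"
  gblupsim:::new_haplotype_pool(haps, genome)
}

# GLS oracle for the animal model y = 1*mu + Z g + e with Var(g) = K sigma2g:
# mu by generalized least squares, g = sigma2g K Z' Vinv (y - 1 mu).
gls_oracle <- function(y, lev, K, sigma2_g, sigma2_e) {
  n <- length(y)
  q <- nrow(K)
  Z <- matrix(0, n, q)
  Z[cbind(seq_len(n), lev)] <- 1
  V <- Z %*% K %*% t(Z) * sigma2_g + diag(n) * sigma2_e
  Vi <- solve(V)
  one <- rep(1, n)
  mu <- drop(solve(t(one) %*% Vi %*% one, t(one) %*% Vi %*% y))
  P <- Vi - Vi %*% one %*% solve(t(one) %*% Vi %*% one) %*% t(one) %*% Vi
  g <- drop(sigma2_g * K %*% t(Z) %*% Vi %*% (y - one * mu))
  pev <- diag(sigma2_g * K - sigma2_g^2 * K %*% t(Z) %*% P %*% Z %*% K)
  list(mu = mu, g = unname(g), pev = unname(pev))
}

# The replicated reduced-scale evaluation grid backing the monotonicity and
# calibration checks; ~10 replicates, built lazily on first use.
acceptance_grid <- function(n_reps = 10) cache_get("acceptance_grid", function() {
  rows <- list()
  sc <- reduced_scale()
  # PEV can exceed sigma2_g for a few animals at this scale; the clip
  # warning is expected and silenced here
  add <- function(rep, cell, res) {
    v <- res$animals[res$animals$set == "validation", ]
    rows[[length(rows) + 1]] <<- data.frame(
      rep = rep, cell = cell, acc = res$mean_validation_accuracy,
      corr = stats::cor(v$gebv, v$tbv))
  }
  for (r in seq_len(n_reps)) {
    seed <- 1000 + r
    expd <- simulate_expanded(2000, sc, seed = seed)
    pop_e3 <- simulate_population(2000, "ebv", 0.3, sc, seed, expanded = expd)
    pop_p3 <- simulate_population(2000, "phenotype", 0.3, sc, seed, expanded = expd)
    pop_r3 <- simulate_population(2000, "random", 0.3, sc, seed, expanded = expd)
    pop_p1 <- simulate_population(2000, "phenotype", 0.1, sc, seed, expanded = expd)
    pop_p5 <- simulate_population(2000, "phenotype", 0.5, sc, seed, expanded = expd)
    d200 <- evaluation_design(200, sc$n_validation, seed = seed)
    d500 <- evaluation_design(500, sc$n_validation, seed = seed)

    rows[[length(rows) + 1]] <- data.frame(
      rep = r, cell = c("gain_ebv", "gain_phen", "gain_random"),
      acc = c(mean(pop_e3$ped$tbv[pop_e3$ped$generation == 10]),
              mean(pop_p3$ped$tbv[pop_p3$ped$generation == 10]),
              mean(pop_r3$ped$tbv[pop_r3$ped$generation == 10])),
      corr = NA_real_)

    suppressWarnings({
      add(r, "ebv_gblup_200", run_gblup(pop_e3, d200))
      add(r, "ebv_gblup_500", run_gblup(pop_e3, d500))
      add(r, "ebv_ss95_200", run_ssgblup(pop_e3, d200, w = 0.95))
      add(r, "ebv_ss95_500", run_ssgblup(pop_e3, d500, w = 0.95))
      add(r, "ebv_ss90_200", run_ssgblup(pop_e3, d200, w = 0.90))
      add(r, "ebv_ss85_200", run_ssgblup(pop_e3, d200, w = 0.85))
      for (pe in c(0.2, 0.4)) {
        pop_pe <- inject_sire_errors(pop_e3, error_spec(pe, 1:10, seed = seed))
        add(r, sprintf("ebv_ss95_200_pe%02d", pe * 100),
            run_ssgblup(pop_pe, d200, w = 0.95))
      }
      add(r, "phen_ss95_200", run_ssgblup(pop_p3, d200, w = 0.95))
      add(r, "phen_gblup_200_h01", run_gblup(pop_p1, d200))
      add(r, "phen_gblup_200_h05", run_gblup(pop_p5, d200))
    })
  }
  do.call(rbind, rows)
})

grid_mean <- function(grid, cell) mean(grid$acc[grid$cell == cell])
grid_se_diff <- function(grid, a, b) {
  d <- grid$acc[grid$cell == a][order(grid$rep[grid$cell == a])] -
    grid$acc[grid$cell == b][order(grid$rep[grid$cell == b])]
  list(mean = mean(d), se = stats::sd(d) / sqrt(length(d)))
}
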