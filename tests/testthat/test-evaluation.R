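test_that("single-record closed form: g-hat = h2 * y with known mean", {
  for (h2 in c(0.1, 0.3, 0.5)) {
    f <- solve_mme(y = 1, record_animal = 1, animals = 1,
                   K_inverse = matrix(1), lambda = (1 - h2) / h2,
                   fit_mean = FALSE)
    expect_equal(unname(f$g), h2 * 1, tolerance = 1e-12)
  }
  f <- solve_mme(y = 2.5, record_animal = 1, animals = 1,
                 K_inverse = matrix(1), lambda = (1 - 0.3) / 0.3,
                 fit_mean = FALSE)
  expect_equal(unname(f$g), 0.3 * 2.5, tolerance = 1e-12)
})

test_that("infinite shrinkage drives all effects to zero", {
  ped <- random_pedigree(20, seed = 5)
  A <- build_A(ped)
  withr::with_seed(6, y <- rnorm(20))
  f <- solve_mme(y, ped$id, ped$id, solve(A), lambda = 1e12)
  expect_lt(max(abs(f$g)), 1e-9)
})

test_that("solve_mme agrees with the GLS oracle on random instances", {
  for (seed in 1:3) {
    n_anim <- c(30, 42, 50)[seed]
    ped <- random_pedigree(n_anim, seed = seed)
    A <- build_A(ped)
    sigma2_g <- 0.3; sigma2_e <- 0.7
    # phenotype a random subset (some animals unphenotyped)
    withr::with_seed(100 + seed, {
      rec <- sort(sample(n_anim, n_anim - 8))
      y <- rnorm(length(rec), 0.5)
    })
    lam <- sigma2_e / sigma2_g
    # dense path
    f <- solve_mme(y, rec, ped$id, solve(A), lam, pev_ids = ped$id)
    o <- gls_oracle(y, match(rec, ped$id), A, sigma2_g, sigma2_e)
    expect_equal(f$mu, o$mu, tolerance = 1e-8)
    expect_equal(unname(f$g), o$g, tolerance = 1e-8)
    expect_equal(unname(sigma2_e * f$Cii), o$pev, tolerance = 1e-8)
    # sparse path gives the same answer
    fs <- solve_mme(y, rec, ped$id, build_A_inverse(ped), lam,
                    pev_ids = ped$id)
    expect_equal(unname(fs$g), o$g, tolerance = 1e-8)
    expect_equal(unname(sigma2_e * fs$Cii), o$pev, tolerance = 1e-8)
  }
})

test_that("accuracy fixed points: PEV 0, sigma2_g, 0.75 sigma2_g, clamp", {
  expect_equal(accuracy_from_pev(0, 0.3), 1)
  expect_equal(accuracy_from_pev(0.3, 0.3), 0)
  expect_equal(accuracy_from_pev(0.75 * 0.3, 0.3), 0.5)
  expect_warning(a <- accuracy_from_pev(0.31, 0.3), "clipped")
  expect_equal(a, 0)
  expect_error(accuracy_from_pev(0.1, 0), "sigma2_g")
  expect_error(accuracy_from_pev(-0.1, 0.3), "non-negative")
  expect_equal(accuracy_from_pev(0.15, 0.3, square = TRUE), 0.5)
})

test_that("H-inverse with G = A22 reduces the evaluation to pedigree BLUP", {
  ped <- random_pedigree(60, seed = 11)
  Ainv <- build_A_inverse(ped)
  ids <- 51:60
  A22 <- build_A22(ped, ids)
  H <- build_H_inverse(Ainv, A22, A22, w = 0.95)
  withr::with_seed(12, y <- rnorm(45))
  rec <- 1:45
  f_h <- solve_mme(y, rec, ped$id, H, lambda = 7 / 3, pev_ids = ids)
  f_a <- solve_mme(y, rec, ped$id, Ainv, lambda = 7 / 3, pev_ids = ids)
  expect_equal(f_h$g, f_a$g, tolerance = 1e-8)
  expect_equal(f_h$Cii, f_a$Cii, tolerance = 1e-8)
})

test_that("design sets are disjoint and infeasible designs error", {
  pop <- tiny_pop("phenotype", 0.3)
  d <- evaluation_design(50, 20, seed = 1)
  sets <- gblupsim:::draw_design(pop, d)
  expect_length(intersect(sets$tp, sets$validation), 0)
  expect_true(all(pop$ped$generation[sets$tp] %in% 7:9))
  expect_true(all(pop$ped$generation[sets$validation] == 10))
  expect_error(gblupsim:::draw_design(pop, evaluation_design(10000, 20)),
               "exceeds")
  expect_error(gblupsim:::draw_design(
    pop, evaluation_design(50, 20, tp_generations = 8:10)), "overlap")
})

test_that("evaluation results are well-formed and validation phenotypes unused", {
  pop <- tiny_pop("phenotype", 0.3)
  d <- evaluation_design(100, 25, seed = 2)
  # at this miniature scale a few validation PEVs can exceed sigma2_g and
  # are clipped with a warning; that is expected here
  r <- suppressWarnings(run_gblup(pop, d))
  tab <- tidy(r)
  expect_equal(sum(tab$set == "training"), 100)
  expect_equal(sum(tab$set == "validation"), 25)
  v <- tab[tab$set == "validation", ]
  expect_true(all(v$pev >= 0))
  expect_true(all(v$accuracy >= 0 & v$accuracy <= 1))
  g <- glance(r)
  expect_equal(g$mean_validation_accuracy, mean(v$accuracy))
  # masking validation phenotypes has no effect on the fit
  pop2 <- pop
  pop2$ped$phenotype[pop2$ped$generation == 10] <- 0
  r2 <- suppressWarnings(run_gblup(pop2, d))
  expect_equal(r$mean_validation_accuracy, r2$mean_validation_accuracy)
})

test_that("model-based accuracy tracks realized predictive correlation", {
  # PEV-based accuracy is a model-derived quantity; under selection it is
  # anti-conservative relative to the realized corr(GEBV, TBV) because the
  # base-population sigma2_g in its denominator exceeds the genetic variance
  # left among selected validation cohorts.  The two measures must still
  # move together across designs.
  g <- acceptance_grid()
  ev <- g[!is.na(g$corr), ]
  agg <- stats::aggregate(cbind(acc, corr) ~ cell, ev, mean)
  expect_gt(stats::cor(agg$acc, agg$corr), 0)
  expect_true(all(agg$acc >= agg$corr - 0.05))
})

test_that("ssGBLUP on shared data reuses identical genotype noise", {
  pop <- tiny_pop("phenotype", 0.3)
  d <- evaluation_design(80, 25, seed = 4)
  sets <- gblupsim:::draw_design(pop, d)
  M1 <- get_genotypes(pop, c(sets$tp, sets$validation))
  M2 <- get_genotypes(pop, c(sets$tp, sets$validation))
  expect_identical(M1, M2)
  # and subsets see the same per-animal noise
  M3 <- get_genotypes(pop, sets$validation)
  expect_identical(M1[as.character(sets$validation), ], M3)
})
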