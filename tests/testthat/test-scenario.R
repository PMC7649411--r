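grid_config <- function(replicates = 2) {
  scenario_config(selection = "phenotype", h2 = 0.3, density = 600,
                  tp_sizes = c(80, 150), methods = c("gblup", "ssgblup_w095"),
                  pe_rates = 0, replicates = replicates, master_seed = 2024,
                  scale = tiny_scale())
}

test_that("run_grid bookkeeping: one cell per method x TP size x replicate", {
  rep1 <- cache_get("grid_report",
                    function() suppressWarnings(run_grid(grid_config())))
  expect_equal(nrow(rep1$cells), 2 * 2 * 2)
  expect_setequal(rep1$cells$replicate, 1:2)
  expect_true(all(rep1$summary$n == 2))
  expect_true(all(rep1$cells$mean_validation_accuracy > 0 &
                    rep1$cells$mean_validation_accuracy < 1))
  # paired contrasts: both methods at a cell share TP/validation draw, so
  # GBLUP and ssGBLUP rows exist for exactly the same coordinates
  key <- with(rep1$cells, paste(tp_size, replicate))
  expect_equal(sort(key[rep1$cells$method == "gblup"]),
               sort(key[rep1$cells$method == "ssgblup_w095"]))
})

test_that("the same master seed reproduces a byte-identical report", {
  rep1 <- cache_get("grid_report",
                    function() suppressWarnings(run_grid(grid_config())))
  rep2 <- suppressWarnings(run_grid(grid_config()))
  expect_identical(rep1$cells, rep2$cells)
  expect_identical(rep1$summary, rep2$summary)
})

test_that("infeasible cells are rejected with the cell named", {
  cfg <- grid_config(replicates = 1)
  cfg$tp_sizes <- 100000L
  expect_error(run_grid(cfg), "infeasible cell")
})

test_that("training candidates cover three full generations of dams", {
  pop <- tiny_pop("phenotype", 0.3)
  cand <- sum(pop$ped$generation %in% 7:9)
  expect_equal(cand, 3 * pop$spec$n_founder_females)
})

synthetic_report <- function(cells) {
  cells$w <- vapply(cells$method, gblupsim:::method_w, 0)
  cells$mean <- round(runif(nrow(cells), 0.3, 0.9), 4)
  cells$sd <- 0.01
  cells$n <- 5
  structure(list(cells = NULL, summary = tibble::as_tibble(cells),
                 config = NULL, version = "test"), class = "scenario_report")
}

test_that("rendered tables mirror the reference layouts", {
  dir <- withr::local_tempdir()
  # phenotypic-selection analogue: 12 rows x (2 id + 6 accuracy) columns
  ph <- expand.grid(selection = "phenotype", h2 = c(0.1, 0.3, 0.5),
                    density = c(10000, 50000, 777000),
                    method = c("gblup", "ssgblup_w095"),
                    tp_size = c(1000, 2000, 3000, 5000), pe_rate = 0,
                    stringsAsFactors = FALSE)
  withr::with_seed(1, r <- synthetic_report(ph))
  paths <- render_tables(r, dir)
  t2 <- read.delim(file.path(dir, "accuracy_phenotypic_selection.tsv"))
  expect_equal(dim(t2), c(12L, 2L + 6L))
  # EBV analogue at one density: 12 rows x (2 + 4 methods)
  eb <- expand.grid(selection = "ebv", h2 = c(0.1, 0.3, 0.5), density = 10000,
                    method = c("gblup", "ssgblup_w095", "ssgblup_w090",
                               "ssgblup_w085"),
                    tp_size = c(1000, 2000, 3000, 5000), pe_rate = 0,
                    stringsAsFactors = FALSE)
  withr::with_seed(2, r <- synthetic_report(eb))
  render_tables(r, dir)
  t3 <- read.delim(file.path(dir, "accuracy_ebv_selection_10K.tsv"))
  expect_equal(dim(t3), c(12L, 2L + 4L))
  # pedigree-error analogue: 15 rows x (2 + 4 TP sizes), 4 decimals
  pe <- expand.grid(selection = "ebv", h2 = 0.3, density = 50000,
                    method = c("ssgblup_w095", "ssgblup_w090", "ssgblup_w085"),
                    tp_size = c(1000, 2000, 3000, 5000),
                    pe_rate = c(0, 0.1, 0.2, 0.3, 0.4),
                    stringsAsFactors = FALSE)
  withr::with_seed(3, r <- synthetic_report(pe))
  render_tables(r, dir)
  t6 <- read.delim(file.path(dir, "accuracy_pedigree_error.tsv"),
                   colClasses = "character")
  expect_equal(dim(t6), c(15L, 2L + 4L))
  expect_true(all(grepl("^0\\.\\d{4}$", t6$TP_1000)))
})

test_that("incomplete or empty reports refuse to render", {
  dir <- withr::local_tempdir()
  ph <- expand.grid(selection = "phenotype", h2 = c(0.1, 0.3), density = 10000,
                    method = c("gblup", "ssgblup_w095"),
                    tp_size = c(1000, 2000), pe_rate = 0,
                    stringsAsFactors = FALSE)
  withr::with_seed(4, r <- synthetic_report(ph))
  r$summary <- r$summary[-1, ]   # knock out one cell
  expect_error(render_tables(r, dir), "missing cell")
  r$summary <- r$summary[0, ]
  expect_error(render_tables(r, dir), "no cells")
})

test_that("result exports are readable round-trips", {
  pop <- tiny_pop("phenotype", 0.3)
  dir <- withr::local_tempdir()
  write_pedigree_tsv(pop, file.path(dir, "ped.tsv"))
  ped <- read.delim(file.path(dir, "ped.tsv"))
  expect_equal(nrow(ped), nrow(pop$ped))
  expect_named(ped, c("animal_id", "sire_id", "dam_id", "sex", "generation"))
  write_phenotypes_tsv(pop, file.path(dir, "phe.tsv"))
  phe <- read.delim(file.path(dir, "phe.tsv"))
  expect_equal(phe$tbv, pop$ped$tbv, tolerance = 1e-6)
  ids <- pop$ped$id[1:5]
  write_genotypes_raw(pop, ids, file.path(dir, "geno.raw"))
  raw <- read.table(file.path(dir, "geno.raw"), header = TRUE)
  expect_equal(dim(raw), c(5L, 6L + sum(pop$genome$loci$type == "marker")))
  expect_true(all(unlist(raw[, -(1:6)]) %in% c(0:2, NA)))
  gm_path <- write_genome_map_tsv(pop$genome, file.path(dir, "map.tsv"))
  expect_equal(nrow(read.delim(gm_path)), nrow(pop$genome$loci))
  Ai <- build_A_inverse(pedigree(pop, "recorded")[1:50, ])
  write_matrix_coord(Ai, file.path(dir, "ainv.tsv"))
  tri <- read.delim(file.path(dir, "ainv.tsv"))
  expect_true(all(tri$i <= tri$j))
  # round-trip: rebuild the symmetric matrix and compare
  Ar <- matrix(0, 50, 50)
  Ar[cbind(tri$i, tri$j)] <- tri$value
  Ar[cbind(tri$j, tri$i)] <- tri$value
  expect_equal(Ar, as.matrix(Ai), ignore_attr = TRUE, tolerance = 1e-12)
})
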