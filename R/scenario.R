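#' Scale presets for the scenario runner
#'
#' `full_scale()` reproduces the reference study's population sizes: a
#' 1,000 x 1,000-generation historical phase shrinking to 200 over 95
#' generations, a 20-generation expansion with 5 offspring per dam capped at
#' 10,000, 275 founder sires and 2,475 founder dams, 10 recent generations,
#' training animals from generations 7-9 and 200 validation animals from
#' generation 10.  `reduced_scale()` is a miniature with the same structure
#' (historical 200 generations at N = 200 shrinking to 100 over 50, ten
#' expansion generations capped at 2,000, 55 sires / 495 dams, 40 validation
#' animals) used for fast property checks.
#'
#' @param ... named overrides of individual preset fields.
#' @return A named list of simulation sizes.
#' @export
full_scale <- function(...) {
  p <- list(hp = historical_spec(1000L, 1000L, 95L, 200L),
            expansion_generations = 20L, offspring_per_dam_expansion = 5L,
            expansion_cap = 10000L,
            n_founder_males = 275L, n_founder_females = 2475L,
            n_recent_generations = 10L,
            n_validation = 200L, tp_generations = 7:9,
            validation_generation = 10L,
            n_qtl = 725L, pool_factor = 2.5, qtl_pool_factor = 2,
            marker_maf_min = 0.1, qtl_maf_min = 0.01)
  utils::modifyList(p, list(...))
}

#' @rdname full_scale
#' @export
reduced_scale <- function(...) {
  p <- list(hp = historical_spec(200L, 200L, 50L, 100L),
            expansion_generations = 10L, offspring_per_dam_expansion = 5L,
            expansion_cap = 2000L,
            n_founder_males = 55L, n_founder_females = 495L,
            n_recent_generations = 10L,
            n_validation = 40L, tp_generations = 7:9,
            validation_generation = 10L,
            n_qtl = 145L, pool_factor = 2.5, qtl_pool_factor = 2,
            marker_maf_min = 0.1, qtl_maf_min = 0.01)
  utils::modifyList(p, list(...))
}

#' Configuration of a scenario grid
#'
#' The grid is the cross of selection method, heritability, marker density,
#' evaluation method (GBLUP or weighted ssGBLUP), training-population size
#' and pedigree-error rate, replicated `replicates` times.  Within a
#' replicate, all cells sharing a (selection, h2, density) coordinate reuse
#' the same simulated population, and all methods at a (coordinate, TP size,
#' PE rate) cell share the same training/validation draw and observed
#' genotypes, so method contrasts are paired.
#'
#' @param selection character vector from `{"phenotype", "ebv"}`.
#' @param h2 numeric vector of heritabilities.
#' @param density integer vector of marker panel sizes (e.g. 10000, 50000).
#' @param tp_sizes integer vector of training-population sizes.
#' @param methods character vector from `{"gblup", "ssgblup_w095",
#'   "ssgblup_w090", "ssgblup_w085", "pblup"}`.
#' @param pe_rates numeric vector of wrong-sire rates (0 = intact pedigree).
#' @param replicates number of simulation replicates.
#' @param master_seed master seed; all stage streams derive from it.
#' @param scale a preset from [full_scale()] or [reduced_scale()].
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(selection = "phenotype", h2 = 0.3,
                            density = 10000L, tp_sizes = 1000L,
                            methods = c("gblup", "ssgblup_w095"),
                            pe_rates = 0, replicates = 1L, master_seed = 1L,
                            scale = reduced_scale()) {
  stopifnot(all(selection %in% c("phenotype", "ebv", "random")))
  known <- c("gblup", "pblup", "ssgblup_w095", "ssgblup_w090", "ssgblup_w085")
  if (!all(methods %in% known))
    stop_bad_arg("unknown methods: ",
                 paste(setdiff(methods, known), collapse = ", "))
  for (h in h2) if (h <= 0 || h >= 1) stop_bad_arg("h2 must be in (0,1)")
  structure(list(selection = selection, h2 = h2,
                 density = as.integer(density),
                 tp_sizes = as.integer(tp_sizes), methods = methods,
                 pe_rates = as.numeric(pe_rates),
                 replicates = check_count(replicates, "replicates", 1),
                 master_seed = as.integer(master_seed), scale = scale),
            class = "scenario_config")
}

method_w <- function(method) {
  switch(method, ssgblup_w095 = 0.95, ssgblup_w090 = 0.90,
         ssgblup_w085 = 0.85, NA_real_)
}

#' Simulate one base population for a scenario coordinate
#'
#' Runs the historical phase on an over-dense candidate map, selects the
#' marker/QTL panels, expands the population, and breeds the recent
#' generations under the requested selection method and heritability.
#' [run_grid()] calls this once per (replicate, density) for the shared
#' historical/expansion stages and once per (replicate, density, selection,
#' h2) for the recent generations.
#'
#' @param n_markers marker panel size.
#' @param selection selection method.
#' @param h2 heritability.
#' @param scale preset from [full_scale()] / [reduced_scale()].
#' @param seed master seed for this simulation.
#' @param expanded optionally, a precomputed expanded pool (with its final
#'   panel genome) to reuse across selection/h2 coordinates.
#' @return A `population`.
#' @export
simulate_population <- function(n_markers, selection = "phenotype", h2 = 0.3,
                                scale = reduced_scale(), seed = 1L,
                                expanded = NULL) {
  if (is.null(expanded)) expanded <- simulate_expanded(n_markers, scale, seed)
  spec <- scheme_spec(
    n_founder_males = scale$n_founder_males,
    n_founder_females = scale$n_founder_females,
    n_generations = scale$n_recent_generations,
    selection_method = selection)
  # one seed for all selection methods: the founder draw, QTL effects and
  # phenotype noise streams coincide, so selection contrasts are paired
  run_recent_generations(expanded, h2, spec, seed = seed)
}

#' @rdname simulate_population
#' @export
simulate_expanded <- function(n_markers, scale = reduced_scale(), seed = 1L) {
  cand <- build_genome_map(ceiling(n_markers * scale$pool_factor),
                           ceiling(scale$n_qtl * scale$qtl_pool_factor),
                           seed = seed_stream(seed, "genome"))
  pool <- simulate_historical(scale$hp, cand,
                              seed = seed_stream(seed, "historical"))
  panel <- select_panels(pool, cand, n_markers, scale$n_qtl,
                         marker_maf_min = scale$marker_maf_min,
                         qtl_maf_min = scale$qtl_maf_min,
                         seed = seed_stream(seed, "panels"))
  base <- finalize_pool(pool, panel)
  expand_population(base, n_generations = scale$expansion_generations,
                    offspring_per_dam = scale$offspring_per_dam_expansion,
                    target_size = scale$expansion_cap,
                    seed = seed_stream(seed, "expansion"))
}

#' Run a full scenario grid
#'
#' @param config a [scenario_config()].
#' @param verbose print per-stage progress to stderr.
#' @return An object of class `scenario_report`: `cells` (one row per
#'   evaluated cell and replicate), `summary` (mean and SD of the mean
#'   validation accuracy over replicates) and provenance.
#' @export
run_grid <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  sc <- config$scale
  say <- function(...) if (verbose) message(sprintf(...))
  cells <- list()
  for (rep in seq_len(config$replicates)) {
    for (dens in config$density) {
      sim_seed <- seed_stream(config$master_seed,
                              paste0("sim-", rep, "-", dens))
      say("replicate %d density %d: base simulation", rep, dens)
      t0 <- proc.time()[3]
      expanded <- simulate_expanded(dens, sc, sim_seed)
      say("  base done in %.1fs", proc.time()[3] - t0)
      for (sel in config$selection) for (h2 in config$h2) {
        say("  coordinate selection=%s h2=%.2f", sel, h2)
        pop <- simulate_population(dens, sel, h2, sc, sim_seed,
                                   expanded = expanded)
        for (pe in config$pe_rates) {
          pop_pe <- if (pe > 0)
            inject_sire_errors(pop, error_spec(
              pe, seq_len(sc$n_recent_generations),
              seed = seed_stream(sim_seed, paste0("pe-", sel, "-", h2, "-", pe))))
          else pop
          for (tp in config$tp_sizes) {
            design <- evaluation_design(
              tp, sc$n_validation, sc$tp_generations,
              sc$validation_generation,
              seed = seed_stream(sim_seed, paste0("design-", sel, "-", h2,
                                                  "-", tp)))
            sets <- tryCatch(draw_design(pop_pe, design), error = function(e)
              stop_bad_arg("infeasible cell (selection=", sel, ", h2=", h2,
                           ", density=", dens, ", tp=", tp, "): ",
                           conditionMessage(e)))
            M <- get_genotypes(pop_pe, c(sets$tp, sets$validation))
            for (method in config$methods) {
              t1 <- proc.time()[3]
              res <- switch(
                method,
                gblup = run_gblup(pop_pe, design, genotypes = M),
                pblup = run_pblup(pop_pe, design),
                run_ssgblup(pop_pe, design, w = method_w(method),
                            genotypes = M))
              cells[[length(cells) + 1]] <- tibble::tibble(
                selection = sel, h2 = h2, density = dens, method = method,
                w = method_w(method), tp_size = tp, pe_rate = pe,
                replicate = rep,
                mean_validation_accuracy = res$mean_validation_accuracy)
              say("    %s tp=%d pe=%.2f: acc=%.4f (%.1fs)", method, tp, pe,
                  res$mean_validation_accuracy, proc.time()[3] - t1)
            }
          }
        }
      }
    }
  }
  cells <- do.call(rbind, cells)
  key <- c("selection", "h2", "density", "method", "w", "tp_size", "pe_rate")
  agg <- aggregate(cells$mean_validation_accuracy, cells[key],
                   function(x) c(mean = mean(x), sd = sd(x), n = length(x)))
  summary <- tibble::as_tibble(cbind(agg[key], as.data.frame(agg$x)))
  structure(list(cells = tibble::as_tibble(cells), summary = summary,
                 config = config,
                 version = as.character(utils::packageVersion("gblupsim"))),
            class = "scenario_report")
}

#' @exportS3Method base::print
print.scenario_report <- function(x, ...) {
  cat("<scenario_report> ", nrow(x$cells), " cells (",
      x$config$replicates, " replicate(s))\n", sep = "")
  print(x$summary, n = 20)
  invisible(x)
}

fmt_num <- function(x, digits) formatC(round(x, digits), format = "f",
                                       digits = digits)

#' Render accuracy tables from a scenario report
#'
#' Writes tab-separated tables mirroring the reference layouts: a
#' phenotypic-selection table (rows h2 x TP size, columns density x
#' {GBLUP, ssGBLUP_0.95}), one EBV-selection table per density (columns
#' GBLUP and the three ssGBLUP weights) and a pedigree-error table (rows
#' weight x error rate, columns TP size, 4 decimals).  Only tables whose
#' cells the report contains are written; a table with some but not all of
#' its cells present raises an error.
#'
#' @param report a `scenario_report`.
#' @param dir output directory.
#' @param digits decimals for the accuracy tables (the pedigree-error table
#'   always uses 4).
#' @return Invisibly, the paths written.
#' @export
render_tables <- function(report, dir = ".", digits = 3) {
  stopifnot(inherits(report, "scenario_report"))
  s <- report$summary
  if (is.null(s) || nrow(s) == 0) stop_bad_arg("report contains no cells")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  cell_mean <- function(sel, h2, dens, method, tp, pe = 0) {
    r <- s[s$selection == sel & s$h2 == h2 & s$density == dens &
             s$method == method & s$tp_size == tp & s$pe_rate == pe, ]
    if (nrow(r) != 1) stop_bad_arg("missing cell: ", sel, " h2=", h2,
                                   " density=", dens, " ", method, " tp=", tp,
                                   " pe=", pe)
    r$mean
  }
  h2s <- sort(unique(s$h2))
  tps <- sort(unique(s$tp_size))

  # phenotypic-selection table (GBLUP / ssGBLUP_0.95 per density)
  if (any(s$selection == "phenotype")) {
    dens_all <- sort(unique(s$density[s$selection == "phenotype"]))
    rows <- expand.grid(tp_size = tps, h2 = h2s)[, 2:1]
    out <- rows
    for (d in dens_all) for (m in c("gblup", "ssgblup_w095")) {
      out[[sprintf("%s_%dK", ifelse(m == "gblup", "GBLUP", "ssGBLUP_0.95"),
                   round(d / 1000))]] <-
        fmt_num(mapply(function(h, tp) cell_mean("phenotype", h, d, m, tp),
                       rows$h2, rows$tp_size), digits)
    }
    p <- file.path(dir, "accuracy_phenotypic_selection.tsv")
    write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }

  # EBV-selection tables, one per density
  if (any(s$selection == "ebv" & s$pe_rate == 0)) {
    for (d in sort(unique(s$density[s$selection == "ebv"]))) {
      rows <- expand.grid(tp_size = tps, h2 = h2s)[, 2:1]
      out <- rows
      for (m in c("gblup", "ssgblup_w095", "ssgblup_w090", "ssgblup_w085")) {
        if (!any(s$selection == "ebv" & s$method == m)) next
        lbl <- if (m == "gblup") "GBLUP" else
          sprintf("ssGBLUP_%.2f", method_w(m))
        out[[lbl]] <- fmt_num(
          mapply(function(h, tp) cell_mean("ebv", h, d, m, tp),
                 rows$h2, rows$tp_size), digits)
      }
      p <- file.path(dir, sprintf("accuracy_ebv_selection_%dK.tsv",
                                  round(d / 1000)))
      write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
  }

  # pedigree-error table (ssGBLUP weights x error rates, columns TP sizes)
  pe_rates <- sort(unique(s$pe_rate))
  if (length(pe_rates) > 1) {
    ws <- c("ssgblup_w095", "ssgblup_w090", "ssgblup_w085")
    ws <- ws[ws %in% s$method]
    d <- sort(unique(s$density[s$selection == "ebv"]))[1]
    h <- sort(unique(s$h2[s$selection == "ebv"]))[1]
    rows <- expand.grid(error_pct = pe_rates * 100, weight = vapply(ws, method_w, 0))[, 2:1]
    out <- rows
    for (tp in tps)
      out[[sprintf("TP_%d", tp)]] <- fmt_num(
        mapply(function(w, pe) cell_mean("ebv", h, d,
                                         ws[match(w, vapply(ws, method_w, 0))],
                                         tp, pe / 100),
               rows$weight, rows$error_pct), 4)
    p <- file.path(dir, "accuracy_pedigree_error.tsv")
    write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (length(paths) == 0)
    stop_bad_arg("report contains no renderable table")
  invisible(paths)
}
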