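#' Write a genome map as TSV
#'
#' Columns `chrom`, `pos_cM`, `locus_id`, `type`, `n_alleles`.
#'
#' @param genome a `genome_map`.
#' @param path output file.
#' @export
write_genome_map_tsv <- function(genome, path) {
  write.table(as.data.frame(genome$loci[, c("chrom", "pos_cM", "locus_id",
                                            "type", "n_alleles")]),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pedigree as TSV
#'
#' Columns `animal_id`, `sire_id`, `dam_id` (0 = unknown), `sex`,
#' `generation`.
#'
#' @param pop a `population`.
#' @param path output file.
#' @param which `"recorded"` or `"true"`.
#' @export
write_pedigree_tsv <- function(pop, path, which = c("recorded", "true")) {
  p <- pedigree(pop, match.arg(which))
  names(p) <- c("animal_id", "sire_id", "dam_id", "sex", "generation")
  write.table(as.data.frame(p), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write phenotypes as TSV
#'
#' Columns `animal_id`, `generation`, `sex`, `phenotype`, `tbv`; `tbv` is
#' simulation truth and must be excluded from evaluation inputs.
#'
#' @param pop a `population`.
#' @param path output file.
#' @export
write_phenotypes_tsv <- function(pop, path) {
  p <- phenotypes(pop)[, c("id", "generation", "sex", "phenotype", "tbv")]
  names(p)[1] <- "animal_id"
  write.table(as.data.frame(p), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write marker dosages in PLINK .raw-style text
#'
#' Header `FID IID PAT MAT SEX PHENOTYPE` followed by one 0/1/2 dosage
#' column per marker (`NA` for missing calls).
#'
#' @param pop a `population`.
#' @param ids animals to export.
#' @param path output file.
#' @export
write_genotypes_raw <- function(pop, ids, path) {
  M <- get_genotypes(pop, ids)
  ped <- pop$ped[match(ids, pop$ped$id), ]
  out <- data.frame(FID = 1L, IID = ids, PAT = ped$rec_sire,
                    MAT = ped$rec_dam, SEX = ifelse(ped$sex == "M", 1L, 2L),
                    PHENOTYPE = ped$phenotype)
  out <- cbind(out, as.data.frame(M))
  write.table(out, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sparse matrix in coordinate format
#'
#' Tab-separated `i`, `j`, `value` triples of the non-zero entries (upper
#' triangle for symmetric matrices).
#'
#' @param m a (sparse) matrix, e.g. from [build_A_inverse()].
#' @param path output file.
#' @export
write_matrix_coord <- function(m, path) {
  tm <- as(as(m, "CsparseMatrix"), "TsparseMatrix")
  df <- data.frame(i = tm@i + 1L, j = tm@j + 1L, value = tm@x)
  df <- df[df$i <= df$j, ]
  df <- df[order(df$i, df$j), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write scenario results as TSV
#'
#' One row per evaluated cell and replicate: `method`, `w`, `selection`,
#' `h2`, `density`, `tp_size`, `pe_rate`, `replicate`,
#' `mean_validation_accuracy`.
#'
#' @param report a `scenario_report`.
#' @param path output file.
#' @export
write_results_tsv <- function(report, path) {
  cols <- c("method", "w", "selection", "h2", "density", "tp_size",
            "pe_rate", "replicate", "mean_validation_accuracy")
  write.table(as.data.frame(report$cells[, cols]), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
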