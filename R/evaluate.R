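#' Solve Henderson's mixed-model equations for an animal model
#'
#' Model: `y = 1 mu + Z g + e`, `g ~ N(0, K sigma2_g)`,
#' `e ~ N(0, I sigma2_e)`.  The coefficient matrix is
#' `[n 1'Z; Z'1 Z'Z + K^{-1} lambda]` with `lambda = sigma2_e / sigma2_g`;
#' variance components are treated as known.  The animal-block diagonal of
#' the coefficient-matrix inverse is returned for the requested animals, from
#' which `PEV_i = sigma2_e * Cinv_ii`.
#'
#' @param y phenotype vector.
#' @param record_animal animal id of each record (each record maps to exactly
#'   one animal effect).
#' @param animals vector of all animal ids carrying effects (model levels).
#' @param K_inverse inverse covariance structure among `animals`: a dense or
#'   sparse matrix, or an `H_inverse` object.
#' @param lambda variance ratio `sigma2_e / sigma2_g` (> 0).
#' @param pev_ids animals for which the inverse diagonal is required
#'   (default none; use `animals` for all).
#' @param fit_mean estimate the overall mean (default); with `FALSE` the
#'   mean is taken as known and equal to 0 and only the animal block is
#'   solved.
#' @return List with `mu`, `g` (named by animal), and `Cii` (named inverse
#'   diagonal entries for `pev_ids`).
#' @export
solve_mme <- function(y, record_animal, animals, K_inverse, lambda,
                      pev_ids = NULL, fit_mean = TRUE) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0)
    stop_bad_arg("lambda must be a positive scalar")
  n_rec <- length(y)
  if (n_rec == 0) stop_bad_arg("at least one phenotyped record is required")
  lev <- match(record_animal, animals)
  if (anyNA(lev)) stop_bad_arg("every record must map to a modelled animal")
  q <- length(animals)
  zcount <- tabulate(lev, nbins = q)
  zty <- numeric(q)
  tmp <- rowsum(y, lev)
  zty[as.integer(rownames(tmp))] <- tmp[, 1]
  rhs <- c(sum(y), zty)

  off <- if (fit_mean) 1L else 0L
  if (!fit_mean) rhs <- zty
  sparse <- inherits(K_inverse, "H_inverse") || is(K_inverse, "sparseMatrix")
  if (!sparse) {
    K_inverse <- as.matrix(K_inverse)
    if (!all(dim(K_inverse) == q)) stop_bad_arg("K_inverse dimension mismatch")
    Cg <- K_inverse * lambda
    diag(Cg) <- diag(Cg) + zcount
    C <- if (fit_mean) rbind(c(n_rec, zcount), cbind(zcount, Cg)) else Cg
    ch <- tryCatch(chol(C), error = function(e)
      stop_bad_arg("singular mixed-model equations: ", conditionMessage(e)))
    sol <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
    Cii <- NULL
    if (!is.null(pev_ids)) {
      cols <- match(pev_ids, animals) + off
      E <- matrix(0, q + off, length(cols))
      E[cbind(cols, seq_along(cols))] <- 1
      U <- backsolve(ch, E, transpose = TRUE)
      Cii <- setNames(colSums(U^2), pev_ids)
    }
  } else {
    Ki <- if (inherits(K_inverse, "H_inverse")) as_matrix(K_inverse) else
      forceSymmetric(as(K_inverse, "CsparseMatrix"))
    if (!all(dim(Ki) == q)) stop_bad_arg("K_inverse dimension mismatch")
    Cg <- Ki * lambda + Diagonal(q, zcount)
    C <- if (fit_mean) rbind(
      cbind(Matrix::Matrix(n_rec, 1, 1, sparse = TRUE),
            Matrix::Matrix(zcount, 1, q, sparse = TRUE)),
      cbind(Matrix::Matrix(zcount, q, 1, sparse = TRUE), Cg)) else Cg
    C <- as(C, "CsparseMatrix")
    ch <- tryCatch(Matrix::Cholesky(forceSymmetric(C), LDL = FALSE, perm = TRUE),
                   error = function(e)
                     stop_bad_arg("singular mixed-model equations: ",
                                  conditionMessage(e)))
    sol <- as.vector(Matrix::solve(ch, rhs, system = "A"))
    Cii <- NULL
    if (!is.null(pev_ids)) {
      cols <- match(pev_ids, animals) + off
      E <- sparseMatrix(i = cols, j = seq_along(cols), x = 1,
                        dims = c(q + off, length(cols)))
      S <- Matrix::solve(ch, E, system = "A")
      Cii <- setNames(Matrix::colSums(E * S), pev_ids)
    }
  }
  list(mu = if (fit_mean) sol[1] else 0,
       g = setNames(if (fit_mean) sol[-1] else sol, animals), Cii = Cii)
}

#' Prediction accuracy from prediction error variance
#'
#' `r = sqrt(1 - PEV / sigma2_g)` (the reliability is `1 - PEV/sigma2_g`).
#' Values of PEV exceeding `sigma2_g` -- possible numerically for animals
#' with above-average relationship diagonals -- are clipped to accuracy 0
#' with a warning.  The non-root reliability is available via
#' `square = TRUE`.
#'
#' @param pev prediction error variance(s), non-negative.
#' @param sigma2_g additive genetic variance (> 0).
#' @param square return the reliability `1 - PEV/sigma2_g` instead of its
#'   square root.
#' @return Accuracy values in `[0, 1]`.
#' @export
accuracy_from_pev <- function(pev, sigma2_g, square = FALSE) {
  if (!is.numeric(sigma2_g) || length(sigma2_g) != 1 || sigma2_g <= 0)
    stop_bad_arg("sigma2_g must be a positive scalar")
  if (any(pev < 0)) stop_bad_arg("pev must be non-negative")
  rel <- 1 - pev / sigma2_g
  if (any(rel < 0)) {
    warning("PEV exceeds sigma2_g for ", sum(rel < 0),
            " animal(s); accuracy clipped to 0", call. = FALSE)
    rel <- pmax(rel, 0)
  }
  if (square) rel else sqrt(rel)
}

#' Design of a genomic evaluation
#'
#' The training population (TP) is drawn at random from `tp_generations` and
#' the validation set from `validation_generation`; the two sets are disjoint
#' by construction and validation phenotypes are always withheld.
#'
#' @param tp_size number of training animals (1,000-5,000 in the full-scale
#'   study).
#' @param n_validation number of validation animals (200).
#' @param tp_generations generations the TP is drawn from (7-9).
#' @param validation_generation generation of the validation animals (10).
#' @param seed seed for both draws (shared across methods so that method
#'   contrasts are paired).
#' @return An object of class `evaluation_design`.
#' @export
evaluation_design <- function(tp_size, n_validation = 200L,
                              tp_generations = 7:9,
                              validation_generation = 10L, seed = 1L) {
  structure(list(tp_size = check_count(tp_size, "tp_size", 1),
                 n_validation = check_count(n_validation, "n_validation", 1),
                 tp_generations = as.integer(tp_generations),
                 validation_generation = check_count(validation_generation,
                                                     "validation_generation"),
                 seed = as.integer(seed)),
            class = "evaluation_design")
}

# Draw the TP and validation ids for a design.
draw_design <- function(pop, design) {
  cand <- pop$ped$id[pop$ped$generation %in% design$tp_generations]
  vcand <- pop$ped$id[pop$ped$generation == design$validation_generation]
  if (length(intersect(design$tp_generations, design$validation_generation)))
    stop_bad_arg("training and validation generations overlap")
  if (length(cand) < design$tp_size)
    stop_bad_arg("tp_size ", design$tp_size, " exceeds the ", length(cand),
                 " candidates in generations ",
                 paste(range(design$tp_generations), collapse = "-"))
  if (length(vcand) < design$n_validation)
    stop_bad_arg("n_validation exceeds the validation generation size")
  with_seed(design$seed, list(tp = sort(sample(cand, design$tp_size)),
                              validation = sort(sample(vcand, design$n_validation))))
}

new_evaluation_result <- function(tab, method, w, design, trait, mu) {
  structure(list(animals = tab, method = method, w = w, design = design,
                 sigma2_g = trait$sigma2_g, sigma2_e = trait$sigma2_e,
                 mu = mu,
                 mean_validation_accuracy =
                   mean(tab$accuracy[tab$set == "validation"])),
            class = "evaluation_result")
}

#' @exportS3Method base::print
print.evaluation_result <- function(x, ...) {
  cat("<evaluation_result> ", x$method,
      if (!is.na(x$w)) paste0(" (w = ", x$w, ")"), ": ",
      sum(x$animals$set == "training"), " training, ",
      sum(x$animals$set == "validation"), " validation animals\n",
      "mean validation accuracy: ",
      format(x$mean_validation_accuracy, digits = 4), "\n", sep = "")
  invisible(x)
}

# pedigree-BLUP evaluator closure for EBV selection
pblup_evaluator <- function(trait) {
  lambda <- trait$sigma2_e / trait$sigma2_g
  function(pop) {
    ped <- pedigree(pop, "recorded")
    Ainv <- build_A_inverse(ped)
    has_y <- !is.na(pop$ped$phenotype)
    fit <- solve_mme(pop$ped$phenotype[has_y], pop$ped$id[has_y],
                     ped$id, Ainv, lambda)
    fit$g
  }
}

#' Pedigree BLUP evaluation
#'
#' Animal-model BLUP on the recorded pedigree with the known variance ratio;
#' the baseline that [run_ssgblup()] reduces to when no animals are
#' genotyped.
#'
#' @param pop a `population`.
#' @param design an [evaluation_design()].
#' @param trait trait model (default `pop$trait`).
#' @return An `evaluation_result`.
#' @export
run_pblup <- function(pop, design, trait = pop$trait) {
  sets <- draw_design(pop, design)
  ped <- pedigree(pop, "recorded")
  lambda <- trait$sigma2_e / trait$sigma2_g
  use <- !is.na(pop$ped$phenotype) &
    pop$ped$generation < design$validation_generation
  Ainv <- build_A_inverse(ped)
  pev_ids <- sets$validation
  fit <- solve_mme(pop$ped$phenotype[use], pop$ped$id[use], ped$id, Ainv,
                   lambda, pev_ids = pev_ids)
  finish_result(pop, sets, fit, "pblup", NA_real_, design, trait)
}

finish_result <- function(pop, sets, fit, method, w, design, trait) {
  ids <- c(sets$tp, sets$validation)
  pev <- rep(NA_real_, length(ids))
  vi <- match(sets$validation, ids)
  pev[vi] <- trait$sigma2_e * fit$Cii[as.character(sets$validation)]
  acc <- rep(NA_real_, length(ids))
  acc[vi] <- accuracy_from_pev(pev[vi], trait$sigma2_g)
  tab <- tibble::tibble(
    id = ids,
    set = rep(c("training", "validation"),
              c(length(sets$tp), length(sets$validation))),
    gebv = as.numeric(fit$g[as.character(ids)]),
    pev = pev, accuracy = acc,
    tbv = pop$ped$tbv[match(ids, pop$ped$id)])
  new_evaluation_result(tab, method, w, design, trait, fit$mu)
}

#' GBLUP evaluation of a simulated population
#'
#' Fits the genomic animal model on the training phenotypes with the
#' validation animals present as unphenotyped levels.  The covariance among
#' the genotyped animals is the VanRaden `G` built from the observed (noisy)
#' marker dosages of the TP and validation animals; variance components are
#' the known simulation values.  Accuracy is
#' `sqrt(1 - PEV / sigma2_g)` per validation animal.
#'
#' @param pop a `population`.
#' @param design an [evaluation_design()].
#' @param trait trait model (default `pop$trait`).
#' @param genotypes optional precomputed dosage matrix for
#'   `c(tp, validation)` ids (rows named by id), e.g. to share one extraction
#'   across methods.
#' @param blend_identity fraction of an identity matrix blended into `G`
#'   before inversion, `G* = (1 - b) G + b I`.  With allele frequencies
#'   computed from the genotyped animals themselves the centred `G` is
#'   singular by construction (its rows sum to zero), so the genotyped-only
#'   model needs this standard invertibility adjustment; 0.01 is the
#'   conventional value and is interpretable as a small independent residual
#'   polygenic component.
#' @return An `evaluation_result`.
#' @export
run_gblup <- function(pop, design, trait = pop$trait, genotypes = NULL,
                      blend_identity = 0.01) {
  sets <- draw_design(pop, design)
  ids <- c(sets$tp, sets$validation)
  M <- genotypes %||% get_genotypes(pop, ids)
  M <- M[as.character(ids), , drop = FALSE]
  G <- build_G(M)
  if (blend_identity > 0)
    G <- (1 - blend_identity) * G + blend_identity * diag(nrow(G))
  ch <- tryCatch(chol(G), error = function(e)
    stop_bad_arg("G is singular; GBLUP requires an invertible G (",
                 conditionMessage(e), "); increase blend_identity"))
  Ginv <- chol2inv(ch)
  lambda <- trait$sigma2_e / trait$sigma2_g
  y <- pop$ped$phenotype[match(sets$tp, pop$ped$id)]
  fit <- solve_mme(y, sets$tp, ids, Ginv, lambda, pev_ids = sets$validation)
  finish_result(pop, sets, fit, "gblup", NA_real_, design, trait)
}

#' Weighted single-step GBLUP evaluation
#'
#' One evaluation combining genotyped and non-genotyped animals: the
#' relationship inverse is `H^{-1}`, blending the recorded-pedigree `A^{-1}`
#' with the genomic correction `(w G + (1-w) A22)^{-1} - A22^{-1}` on the
#' genotyped block (TP plus validation animals).  All recorded phenotypes up
#' to the generation before validation contribute by default
#' (`phenotype_set = "all"`).
#'
#' @inheritParams run_gblup
#' @param w blending weight (0.95, 0.90, 0.85).
#' @param phenotype_set `"all"` (every recorded phenotype before the
#'   validation generation) or `"tp_only"`.
#' @return An `evaluation_result`.
#' @export
run_ssgblup <- function(pop, design, trait = pop$trait, w = 0.95,
                        phenotype_set = c("all", "tp_only"),
                        genotypes = NULL) {
  phenotype_set <- match.arg(phenotype_set)
  sets <- draw_design(pop, design)
  ids <- c(sets$tp, sets$validation)
  ped <- pedigree(pop, "recorded")
  Ainv <- build_A_inverse(ped)
  M <- genotypes %||% get_genotypes(pop, ids)
  M <- M[as.character(ids), , drop = FALSE]
  G <- build_G(M)
  A22 <- build_A22(ped, ids)
  Hinv <- build_H_inverse(Ainv, A22, G, w)
  lambda <- trait$sigma2_e / trait$sigma2_g
  use <- if (phenotype_set == "all")
    !is.na(pop$ped$phenotype) &
      pop$ped$generation < design$validation_generation
  else pop$ped$id %in% sets$tp
  fit <- solve_mme(pop$ped$phenotype[use], pop$ped$id[use], ped$id, Hinv,
                   lambda, pev_ids = sets$validation)
  finish_result(pop, sets, fit, "ssgblup", w, design, trait)
}
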