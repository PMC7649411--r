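#' @importFrom Matrix sparseMatrix Diagonal crossprod t solve forceSymmetric
NULL

# Validate and normalize a pedigree table: columns id, sire, dam (0 =
# unknown), parents before offspring.  Returns integer positions.
ped_positions <- function(ped) {
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  n <- nrow(ped)
  pos <- match(ped$sire, ped$id, nomatch = 0L)
  pos_d <- match(ped$dam, ped$id, nomatch = 0L)
  if (any(ped$sire != 0 & pos == 0) || any(ped$dam != 0 & pos_d == 0))
    stop_bad_arg("pedigree contains parents without their own record")
  if (any(pos >= seq_len(n)) || any(pos_d >= seq_len(n)))
    stop_bad_arg("pedigree must be sorted parents-before-offspring ",
                 "(a cycle or unsorted record was found)")
  list(sire = pos, dam = pos_d, n = n)
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Dense recursive construction: `a_ij = (a_{j,sire(i)} + a_{j,dam(i)}) / 2`
#' for `j < i` and `a_ii = 1 + a_{sire(i),dam(i)} / 2`.  Intended for
#' pedigrees up to a few thousand animals; larger pedigrees should go through
#' [build_A_inverse()] and [build_A22()], which stay sparse.
#'
#' @param ped data frame with `id`, `sire`, `dam` (0 = unknown), sorted
#'   parents-before-offspring.
#' @return Dense symmetric matrix with `id` dimnames.
#' @export
build_A <- function(ped) {
  p <- ped_positions(ped)
  n <- p$n
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- p$sire[i]; d <- p$dam[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      as_ <- if (s > 0) A[j, s] else 0
      ad_ <- if (d > 0) A[j, d] else 0
      A[j, i] <- A[i, j] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(ped$id, ped$id)
  A
}

# Mendelian-sampling variances d_i given parental inbreeding.
mendelian_d <- function(pos, F) {
  s <- pos$sire; d <- pos$dam
  Fs <- ifelse(s > 0, F[pmax(s, 1)], -1)
  Fd <- ifelse(d > 0, F[pmax(d, 1)], -1)
  0.5 - 0.25 * (Fs + Fd)
}

#' Inbreeding coefficients of a pedigree
#'
#' Meuwissen & Luo recursion (exact, including all inbreeding loops).
#'
#' @inheritParams build_A
#' @return Numeric vector of `F` values aligned with `ped$id`.
#' @export
inbreeding <- function(ped) {
  p <- ped_positions(ped)
  cpp_inbreeding(as.integer(p$sire), as.integer(p$dam))
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with full accounting for inbreeding: each animal
#' contributes `alpha_i = 1 / d_i` to the (animal, parent) block pattern,
#' where `d_i` is the Mendelian-sampling variance given the parents'
#' inbreeding coefficients.
#'
#' @inheritParams build_A
#' @return A `dsCMatrix` sparse symmetric matrix with `id` dimnames.
#' @export
build_A_inverse <- function(ped) {
  p <- ped_positions(ped)
  n <- p$n
  F <- cpp_inbreeding(as.integer(p$sire), as.integer(p$dam))
  alpha <- 1 / mendelian_d(p, F)
  i <- seq_len(n); s <- p$sire; d <- p$dam
  ii <- c(i, s, s, i, d, d, i, s, d)
  jj <- c(i, s, i, s, d, i, d, d, s)
  xx <- c(alpha,
          ifelse(s > 0, alpha / 4, 0),
          rep(ifelse(s > 0, -alpha / 2, 0), 2),
          ifelse(d > 0, alpha / 4, 0),
          rep(ifelse(d > 0, -alpha / 2, 0), 2),
          rep(ifelse(s > 0 & d > 0, alpha / 4, 0), 2))
  keep <- ii > 0 & jj > 0 & xx != 0
  M <- sparseMatrix(i = ii[keep], j = jj[keep], x = xx[keep], dims = c(n, n),
                    dimnames = list(ped$id, ped$id))
  forceSymmetric(M)
}

# (I - P/2) of the gametic flow decomposition A = T D T', lower triangular.
ped_Tmat <- function(pos) {
  n <- pos$n
  i <- c(seq_len(n), seq_len(n), seq_len(n))
  j <- c(seq_len(n), pos$sire, pos$dam)
  x <- c(rep(1, n), rep(-0.5, 2 * n))
  keep <- j > 0
  sparseMatrix(i = i[keep], j = j[keep], x = x[keep], dims = c(n, n))
}

#' Pedigree relationships among a subset of animals (Colleau's method)
#'
#' Computes the genotyped block `A22` of the numerator relationship matrix
#' without forming the full dense `A`, using the gametic-flow decomposition
#' `A = (I - P/2)^{-1} D (I - P/2)^{-T}` and sparse triangular solves.
#'
#' @inheritParams build_A
#' @param ids animal ids defining the block (order preserved).
#' @return Dense symmetric matrix of relationships among `ids`.
#' @export
build_A22 <- function(ped, ids) {
  p <- ped_positions(ped)
  idx <- match(ids, ped$id)
  if (anyNA(idx)) stop_bad_arg("ids not present in pedigree")
  F <- cpp_inbreeding(as.integer(p$sire), as.integer(p$dam))
  D <- mendelian_d(p, F)
  Tm <- ped_Tmat(p)
  E <- sparseMatrix(i = idx, j = seq_along(idx), x = 1,
                    dims = c(p$n, length(idx)))
  U <- solve(Matrix::t(Tm), E)            # (I-P/2)^-T E
  A22 <- as.matrix(Matrix::crossprod(U, D * U))
  A22 <- (A22 + t(A22)) / 2
  dimnames(A22) <- list(ids, ids)
  A22
}

#' VanRaden genomic relationship matrix
#'
#' `G = (M - P)(M - P)' / (2 * sum_j p_j (1 - p_j))`, where `M` holds 0/1/2
#' dosages of the second allele and column `j` of `P` is `2 p_j`.  Allele
#' frequencies are computed from the genotyped animals themselves
#' (`freq = NULL`) or supplied (e.g. base-population frequencies).  Missing
#' dosages are imputed to the column mean `2 p_j` before centring, and
#' monomorphic columns are dropped (they contribute nothing to either the
#' numerator or the denominator).
#'
#' @param M numeric/integer matrix, animals x markers, dosages 0/1/2 with
#'   `NA` for missing.
#' @param freq optional vector of second-allele frequencies per marker.
#' @return Dense symmetric `G` with attributes `p` (frequencies used) and
#'   `denom`.
#' @export
build_G <- function(M, freq = NULL) {
  if (nrow(M) < 2) stop_bad_arg("G requires at least 2 animals")
  p <- if (is.null(freq)) colMeans(M, na.rm = TRUE) / 2 else freq
  if (length(p) != ncol(M)) stop_bad_arg("freq length must match markers")
  keep <- p > 0 & p < 1 & !is.na(p)
  if (!any(keep)) stop_bad_arg("all markers are monomorphic: G denominator is zero")
  W <- M[, keep, drop = FALSE]
  p <- p[keep]
  if (anyNA(W)) {
    na_idx <- which(is.na(W), arr.ind = TRUE)
    W[na_idx] <- 2 * p[na_idx[, 2]]
  }
  W <- sweep(W, 2, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(W) / denom
  dimnames(G) <- list(rownames(M), rownames(M))
  attr(G, "p") <- p
  attr(G, "denom") <- denom
  G
}

#' Single-step blended relationship inverse
#'
#' `H^{-1} = A^{-1} + [0 0; 0 (w G + (1 - w) A22)^{-1} - A22^{-1}]`, with the
#' correction embedded at the genotyped animals' positions.  The weight `w`
#' acts as a relative polygenic weight and guards the blend against a
#' singular `G`.  No silent regularization is applied: a numerically singular
#' blend raises an error suggesting a smaller `w`.
#'
#' @param Ainv sparse `A^{-1}` over all animals (see [build_A_inverse()]).
#' @param A22 dense pedigree relationships among the genotyped animals.
#' @param G genomic relationship matrix for the same animals, same order.
#' @param w blending weight in `[0, 1]` (0.95, 0.90 or 0.85 typical).
#' @return An object of class `H_inverse`: list with `Ainv`, the dense
#'   genotyped-block `correction`, and `idx`, the genotyped positions within
#'   `Ainv`.  Use [as_matrix()] to materialize.
#' @export
build_H_inverse <- function(Ainv, A22, G, w) {
  check_fraction(w, "w")
  ids <- rownames(A22)
  if (is.null(ids) || is.null(rownames(G)) || !identical(ids, rownames(G)))
    stop_bad_arg("A22 and G must carry identical animal ids (rownames)")
  idx <- match(ids, rownames(Ainv))
  if (anyNA(idx)) stop_bad_arg("genotyped ids missing from Ainv")
  blend <- w * G + (1 - w) * A22
  ch <- tryCatch(chol(blend), error = function(e) NULL)
  if (is.null(ch))
    stop_bad_arg("the blend w*G + (1-w)*A22 is not positive definite; ",
                 "use a smaller w (more pedigree weight) or check G")
  correction <- chol2inv(ch) - chol2inv(chol(A22))
  dimnames(correction) <- list(ids, ids)
  structure(list(Ainv = Ainv, correction = correction, idx = idx),
            class = "H_inverse")
}

#' Materialize a relationship inverse as a sparse matrix
#'
#' @param x an `H_inverse` (or any matrix-like object).
#' @param ... unused.
#' @return A sparse symmetric matrix.
#' @export
as_matrix <- function(x, ...) UseMethod("as_matrix")

#' @rdname as_matrix
#' @export
as_matrix.H_inverse <- function(x, ...) {
  H <- as(x$Ainv, "CsparseMatrix")
  k <- length(x$idx)
  corr <- sparseMatrix(i = rep(x$idx, k), j = rep(x$idx, each = k),
                       x = as.vector(x$correction), dims = dim(H))
  forceSymmetric(H + corr)
}

#' @rdname as_matrix
#' @export
as_matrix.default <- function(x, ...) as(as(x, "CsparseMatrix"), "symmetricMatrix")

#' @exportS3Method base::print
print.H_inverse <- function(x, ...) {
  cat("<H_inverse> ", nrow(x$Ainv), " animals, ", length(x$idx),
      " genotyped\n", sep = "")
  invisible(x)
}
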