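#' Pedigree numerator relationship matrix A
#'
#' Tabular (recursive) method with inbreeding: a_ij of an animal with its
#' contemporaries is the parent average of already-computed rows, and the
#' diagonal is 1 + half the parents' relationship.
#'
#' @param pedigree Pedigree tibble (topologically ordered).
#' @return Dense symmetric matrix with animal ids as dimnames and
#'   attribute `kind = "A"`.
#' @export
build_A <- function(pedigree) {
  ped <- validate_pedigree(pedigree)
  pp <- ped_positions(ped)
  A <- .tabular_A(pp$sire, pp$dam)
  dimnames(A) <- list(as.character(ped$animal), as.character(ped$animal))
  attr(A, "kind") <- "A"
  A
}

#' Inverse of the numerator relationship matrix by Henderson's rules
#'
#' Builds A-inverse directly from the pedigree: each animal contributes
#' 1/d_i to its own diagonal, -1/(2 d_i) to animal-parent cells and
#' 1/(4 d_i) among parents, where d_i = 0.5 - 0.25 (F_s + F_d) is the
#' Mendelian-sampling variance (with the usual adjustment for unknown
#' parents).  Inbreeding coefficients come from [inbreeding()], so the
#' result matches the dense inverse of [build_A()].
#'
#' @param pedigree Pedigree tibble.
#' @return A sparse symmetric [Matrix::Matrix] with animal ids as
#'   dimnames and attribute `kind = "Ainv"`.
#' @export
build_A_inverse <- function(pedigree) {
  ped <- validate_pedigree(pedigree)
  n <- nrow(ped)
  pp <- ped_positions(ped)
  f <- c(-1, .inbreeding_ml(pp$sire, pp$dam)) # index 0 (unknown) -> F = -1
  fs <- f[pp$sire + 1L]
  fd <- f[pp$dam + 1L]
  d <- 0.5 - 0.25 * (fs + fd)
  alpha <- 1 / d

  i <- seq_len(n)
  s <- pp$sire
  dm <- pp$dam
  has_s <- s > 0
  has_d <- dm > 0
  ti <- c(i,
          i[has_s], s[has_s],
          i[has_d], dm[has_d],
          s[has_s], dm[has_d],
          s[has_s & has_d], dm[has_s & has_d])
  tj <- c(i,
          s[has_s], i[has_s],
          dm[has_d], i[has_d],
          s[has_s], dm[has_d],
          dm[has_s & has_d], s[has_s & has_d])
  tx <- c(alpha,
          -alpha[has_s] / 2, -alpha[has_s] / 2,
          -alpha[has_d] / 2, -alpha[has_d] / 2,
          alpha[has_s] / 4, alpha[has_d] / 4,
          alpha[has_s & has_d] / 4, alpha[has_s & has_d] / 4)
  Ainv <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n),
                               dimnames = list(as.character(ped$animal),
                                               as.character(ped$animal)))
  Ainv <- Matrix::forceSymmetric((Ainv + Matrix::t(Ainv)) / 2)
  attr(Ainv, "kind") <- "Ainv"
  Ainv
}

#' Pedigree relationships among a subset of animals (A22)
#'
#' @param pedigree Pedigree tibble.
#' @param ids Animals (typically the genotyped ones) to extract.
#' @return Dense symmetric matrix restricted to `ids`, in their order.
#' @export
build_A22 <- function(pedigree, ids) {
  ids <- as.character(ids)
  A <- build_A(pedigree)
  missing <- setdiff(ids, rownames(A))
  if (length(missing) > 0) {
    rlang::abort("ids not in pedigree", class = "lact_id_mismatch")
  }
  A22 <- A[ids, ids, drop = FALSE]
  attr(A22, "kind") <- "A22"
  A22
}

#' Genomic relationship matrix G
#'
#' Centered cross-product of SNP dosages scaled by the total expected
#' heterozygosity: G = M M' / (2 sum p_j (1 - p_j)), with M the dosage
#' matrix column-centered at twice the allele frequency.
#'
#' @param genotypes Dosage matrix (animals x markers, 0/1/2, no missing
#'   values: impute first with [impute_genotypes()]).
#' @param freq_source `"observed"` (frequencies from the data) or a
#'   numeric vector of allele frequencies, one per marker.
#' @return Dense symmetric matrix with attribute `kind = "G"`.
#' @export
build_G <- function(genotypes, freq_source = "observed") {
  M <- as.matrix(genotypes)
  if (anyNA(M)) {
    rlang::abort("missing dosages: impute before building G",
                 class = "lact_invalid_input")
  }
  if (identical(freq_source, "observed")) {
    p <- colMeans(M) / 2
  } else {
    p <- as.numeric(freq_source)
    if (length(p) != ncol(M)) {
      rlang::abort("one allele frequency per marker required",
                   class = "lact_invalid_input")
    }
  }
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) {
    rlang::abort("monomorphic-only panel: zero scaling denominator",
                 class = "lact_zero_denominator")
  }
  Mc <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Mc) / denom
  dimnames(G) <- list(rownames(M), rownames(M))
  attr(G, "kind") <- "G"
  G
}

#' Blend G with the pedigree relationships of the genotyped animals
#'
#' Weighted average `w * G + (1 - w) * A22` guaranteeing an invertible
#' genomic matrix (default weight 0.95).
#'
#' @param G Genomic relationship matrix.
#' @param A22 Pedigree relationships of the same animals, same order.
#' @param weight Weight on G, in (0, 1].
#' @return Blended matrix.
#' @export
blend_G <- function(G, A22, weight = 0.95) {
  if (!all(dim(G) == dim(A22))) {
    rlang::abort("G and A22 dimensions differ", class = "lact_invalid_input")
  }
  if (weight <= 0 || weight > 1) {
    rlang::abort("weight must be in (0, 1]", class = "lact_invalid_input")
  }
  Gb <- weight * as.matrix(G) + (1 - weight) * as.matrix(A22)
  dimnames(Gb) <- dimnames(as.matrix(G))
  attr(Gb, "kind") <- "G"
  Gb
}

#' Combined pedigree-genomic inverse relationship matrix (single step)
#'
#' Adds the genomic correction (G^-1 - A22^-1) into the genotyped block
#' of A^-1: the standard single-step H-inverse.
#'
#' @param A_inv Inverse pedigree relationship matrix (all animals).
#' @param A22_inv Inverse of the pedigree relationships among genotyped
#'   animals.
#' @param G_inv Inverse of the (blended) genomic matrix, same animal
#'   order as `A22_inv`.
#' @param genotyped_ids Ids of the genotyped animals, in the row order of
#'   `G_inv` / `A22_inv`.
#' @return Sparse symmetric H^-1 with attribute `kind = "Hinv"`.
#' @export
build_H_inverse <- function(A_inv, A22_inv, G_inv, genotyped_ids) {
  genotyped_ids <- as.character(genotyped_ids)
  H <- methods::as(methods::as(A_inv, "generalMatrix"), "CsparseMatrix")
  idx <- match(genotyped_ids, rownames(A_inv))
  if (anyNA(idx)) {
    rlang::abort("genotyped ids not present in A_inv",
                 class = "lact_id_mismatch")
  }
  if (length(genotyped_ids) > 0) {
    corr <- as.matrix(G_inv) - as.matrix(A22_inv)
    if (!all(dim(corr) == c(length(idx), length(idx)))) {
      rlang::abort("G_inv / A22_inv dimensions do not match genotyped ids",
                   class = "lact_id_mismatch")
    }
    H[idx, idx] <- H[idx, idx] + corr
  }
  H <- Matrix::forceSymmetric((H + Matrix::t(H)) / 2)
  attr(H, "kind") <- "Hinv"
  H
}

#' One-call single-step H-inverse from pedigree and genotypes
#'
#' Convenience wrapper: prunes the pedigree to the ancestral closure of
#' the animals of interest, builds A^-1, A22 and the blended G for the
#' genotyped animals, and assembles H^-1.
#'
#' @param pedigree Pedigree tibble (already pruned as desired).
#' @param genotypes QC-passed, imputed dosage matrix with animal ids as
#'   rownames (may cover a subset of the pedigree; `NULL` for a purely
#'   pedigree-based model, in which case H^-1 = A^-1).
#' @param blend_weight Weight on G in the blend with A22 (default 0.95).
#' @return Sparse symmetric H^-1 over all pedigree animals.
#' @export
single_step_H_inverse <- function(pedigree, genotypes = NULL,
                                  blend_weight = 0.95) {
  ped <- validate_pedigree(pedigree)
  A_inv <- build_A_inverse(ped)
  if (is.null(genotypes) || nrow(genotypes) == 0) {
    attr(A_inv, "kind") <- "Hinv"
    return(A_inv)
  }
  ids <- rownames(genotypes)
  A22 <- build_A22(ped, ids)
  G <- build_G(genotypes)
  Gb <- blend_G(G, A22, weight = blend_weight)
  build_H_inverse(A_inv, solve(A22), solve(Gb), ids)
}
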