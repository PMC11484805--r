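#' Validate a pedigree table
#'
#' A pedigree is a tibble with integer columns `animal`, `sire`, `dam`
#' (0 = unknown parent), topologically ordered so that every parent row
#' precedes its offspring.  The ordering also rules out an animal being
#' its own ancestor.
#'
#' @param pedigree A data frame with `animal`, `sire`, `dam`.
#' @return The pedigree, invisibly, after checks.
#' @export
validate_pedigree <- function(pedigree) {
  ped <- tibble::as_tibble(pedigree)
  for (col in c("animal", "sire", "dam")) {
    if (!col %in% names(ped)) {
      rlang::abort(paste0("pedigree lacks column '", col, "'"),
                   class = "lact_invalid_pedigree")
    }
  }
  if (anyDuplicated(ped$animal)) {
    rlang::abort("duplicated animal ids", class = "lact_invalid_pedigree")
  }
  pos <- match(ped$animal, ped$animal)
  spos <- match(ped$sire, ped$animal)
  dpos <- match(ped$dam, ped$animal)
  known_s <- ped$sire != 0
  known_d <- ped$dam != 0
  if (any(known_s & is.na(spos)) || any(known_d & is.na(dpos))) {
    rlang::abort("parent id not present in pedigree",
                 class = "lact_invalid_pedigree")
  }
  if (any(known_s & spos >= pos, na.rm = TRUE) ||
      any(known_d & dpos >= pos, na.rm = TRUE)) {
    rlang::abort("pedigree not topologically ordered (parents must precede offspring)",
                 class = "lact_invalid_pedigree")
  }
  invisible(ped)
}

# 1-based parent positions (0 = unknown) for the C++ kernels
ped_positions <- function(pedigree) {
  spos <- match(pedigree$sire, pedigree$animal)
  dpos <- match(pedigree$dam, pedigree$animal)
  spos[pedigree$sire == 0 | is.na(spos)] <- 0L
  dpos[pedigree$dam == 0 | is.na(dpos)] <- 0L
  list(sire = as.integer(spos), dam = as.integer(dpos))
}

#' Simulate a multi-generation random-mating pedigree
#'
#' Founders (generation 0) have unknown parents; the first half are
#' females, the second half males.  In each later generation every female
#' of the previous generation is mated once to a sire drawn from a limited
#' pool of males (emulating the few widely used AI sires of dairy
#' populations, which creates large paternal half-sib families), and
#' produces `offspring_per_mating` offspring of random sex.  Selfing is
#' impossible because sire and dam have different sexes.
#'
#' @param n_founders Number of founders (>= 2 when `n_generations` > 0).
#' @param n_generations Number of descendant generations (>= 0).
#' @param offspring_per_mating Offspring per dam and generation (default 2,
#'   which keeps the census size roughly constant).
#' @param seed Optional RNG seed.
#' @param n_sires Size of the sire pool per generation (default 25).
#' @return A tibble `animal`, `sire`, `dam`, `sex`, `generation`,
#'   topologically ordered.
#' @export
simulate_pedigree <- function(n_founders, n_generations,
                              offspring_per_mating = 2, seed = NULL,
                              n_sires = 25) {
  if (n_founders < 2 && n_generations > 0) {
    rlang::abort("need at least 2 founders to breed further generations",
                 class = "lact_invalid_configuration")
  }
  if (n_founders < 1 || n_generations < 0 || offspring_per_mating < 1) {
    rlang::abort("invalid pedigree configuration",
                 class = "lact_invalid_configuration")
  }
  if (!is.null(seed)) set.seed(seed)

  n_f <- ceiling(n_founders / 2)
  ped <- tibble::tibble(
    animal = seq_len(n_founders),
    sire = 0L, dam = 0L,
    sex = c(rep("F", n_f), rep("M", n_founders - n_f)),
    generation = 0L
  )
  next_id <- n_founders + 1L
  for (g in seq_len(n_generations)) {
    prev <- ped[ped$generation == g - 1L, ]
    dams <- prev$animal[prev$sex == "F"]
    males <- prev$animal[prev$sex == "M"]
    if (length(dams) == 0 || length(males) == 0) {
      rlang::abort("a generation ended up without both sexes; increase n_founders",
                   class = "lact_invalid_configuration")
    }
    pool <- if (length(males) > n_sires) sample(males, n_sires) else males
    sire_of_dam <- pool[sample.int(length(pool), length(dams), replace = TRUE)]
    n_off <- length(dams) * offspring_per_mating
    off <- tibble::tibble(
      animal = seq.int(next_id, length.out = n_off),
      sire = rep(sire_of_dam, each = offspring_per_mating),
      dam = rep(dams, each = offspring_per_mating),
      sex = ifelse(stats::runif(n_off) < 0.5, "F", "M"),
      generation = g
    )
    next_id <- next_id + n_off
    ped <- dplyr::bind_rows(ped, off)
  }
  validate_pedigree(ped)
  ped
}

#' Restrict a pedigree to the ancestral closure of a set of animals
#'
#' Keeps the given animals plus their ancestors up to `generations`
#' meioses back (default 3, the depth typically used when setting up the
#' pedigree relationship matrix); parents beyond the cut are set unknown.
#'
#' @param pedigree Pedigree tibble.
#' @param ids Animals whose ancestry to keep.
#' @param generations Ancestral depth (Inf keeps all ancestors).
#' @return The pruned pedigree, still topologically ordered.
#' @export
prune_pedigree <- function(pedigree, ids, generations = 3) {
  ped <- validate_pedigree(pedigree)
  keep <- ped$animal %in% ids
  if (!any(keep)) {
    rlang::abort("none of the requested ids are in the pedigree",
                 class = "lact_invalid_input")
  }
  frontier <- ped$animal[keep]
  depth <- 0
  while (length(frontier) > 0 && depth < generations) {
    rows <- ped[ped$animal %in% frontier, ]
    parents <- setdiff(unique(c(rows$sire, rows$dam)), 0L)
    frontier <- setdiff(parents, ped$animal[keep])
    keep <- keep | ped$animal %in% parents
    depth <- depth + 1
  }
  out <- ped[keep, , drop = FALSE]
  out$sire[!(out$sire %in% out$animal)] <- 0L
  out$dam[!(out$dam %in% out$animal)] <- 0L
  out
}

#' Inbreeding coefficients
#'
#' Meuwissen & Luo (1992) algorithm: F_i is accumulated from the
#' generalized Cholesky factorization of the numerator relationship
#' matrix without forming it.
#'
#' @param pedigree Pedigree tibble.
#' @return Named numeric vector of F coefficients (>= 0).
#' @export
inbreeding <- function(pedigree) {
  ped <- validate_pedigree(pedigree)
  pp <- ped_positions(ped)
  f <- .inbreeding_ml(pp$sire, pp$dam)
  names(f) <- as.character(ped$animal)
  f
}

#' Simulate SNP genotypes by gene dropping
#'
#' Founder haplotypes are drawn at Hardy-Weinberg equilibrium with
#' per-marker allele frequencies uniform on `maf_range`; descendants
#' inherit one allele from each parent by Mendelian sampling,
#' independently per marker (no linkage).
#'
#' @param pedigree Pedigree tibble (non-empty, ordered).
#' @param n_snp Number of markers (>= 1).
#' @param maf_range Length-2 numeric in (0, 0.5]; a single value fixes
#'   all frequencies.
#' @param seed Optional RNG seed.
#' @param missing_rate Fraction of dosages set missing (default 0).
#' @return Integer dosage matrix (animals x markers, values 0/1/2, NA for
#'   missing) with animal ids as rownames and an `allele_freq` attribute
#'   holding the founder frequencies.
#' @export
simulate_genotypes <- function(pedigree, n_snp, maf_range = c(0.05, 0.5),
                               seed = NULL, missing_rate = 0) {
  ped <- tibble::as_tibble(pedigree)
  if (nrow(ped) == 0) {
    rlang::abort("empty pedigree", class = "lact_invalid_input")
  }
  validate_pedigree(ped)
  if (n_snp < 1) rlang::abort("n_snp must be >= 1", class = "lact_invalid_input")
  if (length(maf_range) == 1) maf_range <- rep(maf_range, 2)
  if (any(maf_range <= 0) || any(maf_range > 0.5) || maf_range[1] > maf_range[2]) {
    rlang::abort("maf_range must lie in (0, 0.5]", class = "lact_invalid_input")
  }
  if (!is.null(seed)) set.seed(seed)
  freq <- stats::runif(n_snp, maf_range[1], maf_range[2])
  pp <- ped_positions(ped)
  dos <- .gene_drop(pp$sire, pp$dam, freq)
  if (missing_rate > 0) {
    miss <- which(stats::runif(length(dos)) < missing_rate)
    dos[miss] <- NA_integer_
  }
  rownames(dos) <- as.character(ped$animal)
  colnames(dos) <- sprintf("snp%05d", seq_len(n_snp))
  attr(dos, "allele_freq") <- freq
  dos
}
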