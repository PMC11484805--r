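#' Write / read a pedigree as CSV
#'
#' Columns `animal,sire,dam` (plus `sex`, `generation` when present);
#' 0 marks an unknown parent.
#'
#' @param pedigree Pedigree tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pedigree_csv <- function(pedigree, path) {
  utils::write.csv(as.data.frame(pedigree), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree_csv
#' @export
read_pedigree_csv <- function(path) {
  ped <- tibble::as_tibble(utils::read.csv(path))
  validate_pedigree(ped)
  ped
}

#' Write / read a phenotype table as CSV
#'
#' @param phenotypes Phenotype tibble (see [simulate_phenotypes()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_phenotypes_csv <- function(phenotypes, path) {
  utils::write.csv(as.data.frame(phenotypes), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Write / read a dosage matrix as CSV
#'
#' First column `animal`, then one 0/1/2 column per marker (empty cells
#' for missing dosages).
#'
#' @param genotypes Dosage matrix with animal rownames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes_csv <- function(genotypes, path) {
  df <- data.frame(animal = rownames(genotypes), genotypes,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_genotypes_csv
#' @export
read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df$animal)
  m
}

#' Write genotypes in PLINK text PED/MAP format
#'
#' Dosages are expanded to allele pairs (`A A`, `A B`, `B B`; `0 0` for
#' missing); the MAP file places markers on chromosome 1 at consecutive
#' positions.
#'
#' @param genotypes Dosage matrix with animal rownames.
#' @param prefix Path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return The two paths, invisibly.
#' @export
write_genotypes_plink <- function(genotypes, prefix) {
  M <- as.matrix(genotypes)
  allele <- function(d) {
    c("0 0", "A A", "A B", "B B")[ifelse(is.na(d), 1L, d + 2L)]
  }
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  lines <- vapply(seq_len(nrow(M)), function(i) {
    paste(c("FAM", rownames(M)[i], "0", "0", "0", "-9",
            allele(M[i, ])), collapse = " ")
  }, character(1))
  writeLines(lines, ped_path)
  map <- data.frame(chr = 1, id = colnames(M), cm = 0,
                    bp = seq_len(ncol(M)) * 1000)
  utils::write.table(map, map_path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE, sep = "\t")
  invisible(c(ped_path, map_path))
}

#' Write a relationship matrix in coordinate (i, j, value) text form
#'
#' Upper triangle including the diagonal, with a header line mapping
#' indices to animal ids.
#'
#' @param K A (possibly sparse) relationship matrix with dimnames.
#' @param path Output file.
#' @param tol Entries with `|value| <= tol` are omitted.
#' @return `path`, invisibly.
#' @export
write_kinship_triplets <- function(K, path, tol = 0) {
  Kt <- methods::as(methods::as(Matrix::Matrix(K, sparse = TRUE),
                                "generalMatrix"), "TsparseMatrix")
  keep <- Kt@i <= Kt@j & abs(Kt@x) > tol
  df <- data.frame(i = Kt@i[keep] + 1L, j = Kt@j[keep] + 1L,
                   value = Kt@x[keep])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ids: ", paste(rownames(K), collapse = ",")), con)
  utils::write.table(df, con, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_kinship_triplets
#' @export
read_kinship_triplets <- function(path) {
  header <- readLines(path, n = 1)
  ids <- strsplit(sub("^# ids: ", "", header), ",")[[1]]
  df <- utils::read.table(path, skip = 1, header = TRUE, sep = "\t")
  K <- Matrix::sparseMatrix(i = df$i, j = df$j, x = df$value,
                            dims = c(length(ids), length(ids)),
                            dimnames = list(ids, ids), symmetric = TRUE)
  K
}

#' Write a ground truth (or any parameter list) as JSON
#'
#' @param truth A `lact_ground_truth`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  x <- list(
    traits = truth$traits,
    lambda = truth$lambda,
    sigma_g = truth$sigma_g,
    sigma_h = truth$sigma_h,
    sigma_e = truth$sigma_e,
    dim_effects = truth$dim_effects,
    parity_effects = truth$parity_effects,
    h2 = truth$h2
  )
  jsonlite::write_json(x, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Export a DAG or averaged network in DOT format
#'
#' @param x A `lact_dag` or `lact_avg_network` (retained edges are
#'   annotated with strength/direction).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dot <- function(x, path) {
  lines <- c("digraph traits {")
  if (inherits(x, "lact_avg_network")) {
    e <- tidy(x)
    e <- e[e$retained, , drop = FALSE]
    for (k in seq_len(nrow(e))) {
      lines <- c(lines, sprintf(
        "  %s -> %s [label=\"%.2f (%.2f)\"];",
        e$from[k], e$to[k], e$strength[k], e$direction[k]))
    }
  } else if (inherits(x, "lact_dag")) {
    idx <- which(x$amat, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      lines <- c(lines, sprintf("  %s -> %s;",
                                x$nodes[idx[k, 1]], x$nodes[idx[k, 2]]))
    }
  } else {
    rlang::abort("x must be a lact_dag or lact_avg_network",
                 class = "lact_invalid_input")
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
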