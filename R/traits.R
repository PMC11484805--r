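#' Net energy of lactation from milk composition
#'
#' Milk energy density as a linear combination of fat, protein and lactose
#' percentages with their heats of combustion.  The published coefficients
#' (0.3887, 0.2301, 0.1653) already yield megajoules per kilogram: applied
#' to typical Holstein composition they give around 3.0 MJ/kg, which times
#' a typical daily yield reproduces the reported ~100 MJ/d energy output.
#' They equal the classical Mcal/kg coefficients multiplied by 4.184, so an
#' optional `unit = "Mcal"` divides the result by 4.184 for users who want
#' the Mcal reading of the same formula.
#'
#' @param fat_pct,protein_pct,lactose_pct Milk components in percent
#'   (non-negative, vectorised).
#' @param unit `"MJ"` (default) or `"Mcal"`.
#' @return Energy density per kg of milk, same length as the inputs.
#' @examples
#' compute_nel(3.70, 3.43, 4.86)
#' @export
compute_nel <- function(fat_pct, protein_pct, lactose_pct, unit = c("MJ", "Mcal")) {
  unit <- match.arg(unit)
  if (any(fat_pct < 0, na.rm = TRUE) || any(protein_pct < 0, na.rm = TRUE) ||
      any(lactose_pct < 0, na.rm = TRUE)) {
    rlang::abort("milk components must be non-negative", class = "lact_invalid_input")
  }
  nel <- 0.3887 * fat_pct + 0.2301 * protein_pct + 0.1653 * lactose_pct
  if (unit == "Mcal") nel <- nel / 4.184
  nel
}

#' Daily milk energy output
#'
#' Energy density of the milk times the daily milk yield.
#'
#' @param nel Energy density (MJ/kg), non-negative.
#' @param milk_yield Daily milk yield (kg/d), non-negative.
#' @return Energy output in MJ/d.
#' @examples
#' compute_dmeo(compute_nel(3.70, 3.43, 4.86), 33.39)
#' @export
compute_dmeo <- function(nel, milk_yield) {
  if (any(nel < 0, na.rm = TRUE) || any(milk_yield < 0, na.rm = TRUE)) {
    rlang::abort("nel and milk_yield must be non-negative", class = "lact_invalid_input")
  }
  nel * milk_yield
}

#' Days-in-milk class
#'
#' 30-day bins: class k covers DIM in (30(k-1), 30k], with class 12
#' open-ended (DIM > 330).
#'
#' @param dim Days in milk, positive integer-valued.
#' @return Integer class in 1..12.
#' @export
dim_class <- function(dim) {
  if (any(dim < 1, na.rm = TRUE)) {
    rlang::abort("DIM must be >= 1", class = "lact_invalid_input")
  }
  pmin(as.integer(ceiling(dim / 30)), 12L)
}

#' Parity class
#'
#' Parities 1, 2, 3 kept as-is; 4 and above pooled into class 4.
#'
#' @param parity Lactation number, positive integer-valued.
#' @return Integer class in 1..4.
#' @export
parity_class <- function(parity) {
  if (any(parity < 1, na.rm = TRUE)) {
    rlang::abort("parity must be >= 1", class = "lact_invalid_input")
  }
  pmin(as.integer(parity), 4L)
}

#' Build the analysis table for the multi-trait and structural models
#'
#' Takes a per-cow phenotype table (one record per cow) with milk yield and
#' composition, the five blood metabolites, DIM, parity and herd-date, and
#' returns the modelling table: daily milk energy output derived from
#' composition, all six traits standardized to mean 0 / SD 1, DIM and
#' parity collapsed to their fixed-effect classes.  Scaling constants are
#' kept as an attribute so standardized results can be mapped back to trait
#' units.  Cows absent from `pedigree` (when given) are dropped and
#' counted.
#'
#' @param phenotypes A data frame with columns `animal`, `herd_date`,
#'   `parity`, `dim`, `milk_yield`, `fat_pct`, `protein_pct`,
#'   `lactose_pct`, `glucose`, `CHOL`, `NEFA`, `BHB`, `urea`.  A `dMEO`
#'   column is recomputed from composition if absent.
#' @param pedigree Optional pedigree tibble (see [simulate_pedigree()]);
#'   rows whose `animal` is not registered are removed.
#' @param scaling `"standardize"` (default) or `"none"`.
#' @return A tibble of class `lact_analysis_table` with the six
#'   standardized traits, `dim_class`, `parity_class`, `herd_date`, and
#'   attributes `scaling` (tibble of per-trait mean/sd) and `n_dropped`.
#' @export
build_analysis_table <- function(phenotypes, pedigree = NULL,
                                 scaling = c("standardize", "none")) {
  scaling <- match.arg(scaling)
  ph <- tibble::as_tibble(phenotypes)
  needed <- c("animal", "herd_date", "parity", "dim",
              "glucose", "CHOL", "NEFA", "BHB", "urea")
  missing_cols <- setdiff(needed, names(ph))
  if (length(missing_cols) > 0) {
    rlang::abort(paste("missing columns:", paste(missing_cols, collapse = ", ")),
                 class = "lact_invalid_input")
  }
  if (!"dMEO" %in% names(ph)) {
    ph$dMEO <- compute_dmeo(
      compute_nel(ph$fat_pct, ph$protein_pct, ph$lactose_pct),
      ph$milk_yield
    )
  }
  n_dropped <- 0L
  if (!is.null(pedigree)) {
    keep <- ph$animal %in% pedigree$animal
    n_dropped <- sum(!keep)
    ph <- ph[keep, , drop = FALSE]
  }
  cc <- stats::complete.cases(ph[, c(lact_traits(), "herd_date", "parity", "dim")])
  n_dropped <- n_dropped + sum(!cc)
  ph <- ph[cc, , drop = FALSE]
  if (nrow(ph) == 0) {
    rlang::abort("no complete records left", class = "lact_invalid_input")
  }

  out <- tibble::tibble(
    animal = ph$animal,
    herd_date = factor(ph$herd_date),
    dim_class = factor(dim_class(ph$dim), levels = 1:12),
    parity_class = factor(parity_class(ph$parity), levels = 1:4)
  )
  traits <- lact_traits()
  if (scaling == "standardize") {
    scl <- tibble::tibble(
      trait = traits,
      mean = vapply(traits, function(t) mean(ph[[t]]), numeric(1)),
      sd = vapply(traits, function(t) stats::sd(ph[[t]]), numeric(1))
    )
    if (any(scl$sd <= 0)) {
      rlang::abort("constant trait column cannot be standardized",
                   class = "lact_invalid_input")
    }
    for (t in traits) {
      m <- scl$mean[scl$trait == t]
      s <- scl$sd[scl$trait == t]
      out[[t]] <- (ph[[t]] - m) / s
    }
  } else {
    scl <- tibble::tibble(trait = traits, mean = 0, sd = 1)
    for (t in traits) out[[t]] <- ph[[t]]
  }
  attr(out, "scaling") <- scl
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("lact_analysis_table", class(out))
  out
}

#' Map standardized trait values back to trait units
#'
#' @param x Standardized values.
#' @param trait Trait name present in `scaling`.
#' @param scaling A scaling tibble (`trait`, `mean`, `sd`), e.g. the
#'   `scaling` attribute of [build_analysis_table()].
#' @return Values in original trait units.
#' @export
unstandardize <- function(x, trait, scaling) {
  i <- match(trait, scaling$trait)
  if (is.na(i)) rlang::abort("unknown trait", class = "lact_invalid_input")
  x * scaling$sd[i] + scaling$mean[i]
}

#' Express a standardized structural coefficient in trait units
#'
#' A structural coefficient on the standardized scale is the SD-change in
#' the child trait per 1-SD change in the parent.  Multiplying by the
#' child's raw-scale SD gives the child-unit change per 1 parent-SD; the
#' parent SD is carried along so the statement "1 sigma of parent
#' (`sd_parent` units) moves the child by `effect` units" is complete.
#'
#' @param lambda Structural coefficient(s), standardized scale.
#' @param sd_parent,sd_child Raw-scale standard deviations (positive).
#' @return A tibble with columns `lambda`, `sd_parent`, `sd_child`,
#'   `effect` (child units per 1 SD of parent).
#' @examples
#' unstandardize_path(-0.550, sd_parent = 0.45, sd_child = 0.21)
#' @export
unstandardize_path <- function(lambda, sd_parent, sd_child) {
  if (any(sd_parent <= 0) || any(sd_child <= 0)) {
    rlang::abort("standard deviations must be positive",
                 class = "lact_invalid_input")
  }
  tibble::tibble(
    lambda = lambda,
    sd_parent = sd_parent,
    sd_child = sd_child,
    effect = lambda * sd_child
  )
}
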