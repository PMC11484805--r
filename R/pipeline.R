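#' Configuration of the end-to-end analysis pipeline
#'
#' Collects everything the pipeline stages need: output directory,
#' global seed (fanned out deterministically to the stages), herd size,
#' QC thresholds, chain and bootstrap settings, and the set of stages to
#' run.  The `"full"` profile switches chains to the full-scale
#' protocol (500,000 / 50,000 / 100 and 50,000 bootstrap replicates);
#' the default `"desk"` profile uses chain lengths suited to a
#' workstation.
#'
#' @param outdir Output directory.
#' @param seed Global seed (integer).
#' @param n_cows,n_snp,n_genotyped Synthetic-herd size parameters
#'   (see [simulate_herd()]).
#' @param truth Generative ground truth (default
#'   [default_ground_truth()]).
#' @param qc List of QC thresholds for [qc_genotypes()].
#' @param mtm_config,sem_config [chain_config()] objects.
#' @param n_boot,strength_threshold Bootstrap settings for
#'   [bootstrap_network()].
#' @param stages Stages to run, in dependency order.
#' @param resume Skip stages whose artifacts already exist.
#' @param profile `"desk"` or `"full"`.
#' @return A list of class `lact_pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, n_cows = 600, n_snp = 500,
                            n_genotyped = 150,
                            truth = default_ground_truth(),
                            qc = list(maf_min = 0.05, hwe_p_min = 1e-5,
                                      call_rate_min = 0.95),
                            mtm_config = NULL, sem_config = NULL,
                            n_boot = 1000, strength_threshold = 0.95,
                            stages = c("simulate", "derive", "kinship",
                                       "mtm", "network", "sem", "report"),
                            resume = FALSE,
                            profile = c("desk", "full")) {
  profile <- match.arg(profile)
  if (profile == "full") {
    mtm_config <- chain_config(profile = "full")
    sem_config <- chain_config(profile = "full")
    n_boot <- 50000
  }
  if (is.null(mtm_config)) mtm_config <- chain_config(n_iter = 6000, burn_in = 1000, thin = 5)
  if (is.null(sem_config)) sem_config <- chain_config(n_iter = 6000, burn_in = 1000, thin = 5)
  structure(list(
    outdir = outdir, seed = as.integer(seed), n_cows = n_cows,
    n_snp = n_snp, n_genotyped = n_genotyped, truth = truth, qc = qc,
    mtm_config = mtm_config, sem_config = sem_config, n_boot = n_boot,
    strength_threshold = strength_threshold, stages = stages,
    resume = resume, profile = profile
  ), class = "lact_pipeline_config")
}

stage_files <- function(outdir) {
  list(
    simulate = file.path(outdir, c("pedigree.csv", "phenotypes.csv",
                                   "genotypes.csv", "truth.json")),
    derive = file.path(outdir, c("analysis_table.csv", "scaling.csv")),
    kinship = file.path(outdir, c("hinv.txt", "qc_report.json")),
    mtm = file.path(outdir, c("mtm_summary.csv", "residuals.csv",
                              "mtm_meta.json")),
    network = file.path(outdir, c("network_edges.csv", "network.dot")),
    sem = file.path(outdir, c("sem_summary.csv", "sem_paths.csv",
                              "sem_meta.json")),
    report = file.path(outdir, "report", "report.json")
  )
}

#' Run the full pipeline: simulate, derive, kinship, MTM, network, SEM,
#' report
#'
#' Stages run in dependency order, each writing its artifacts under
#' `config$outdir`.  With `resume = TRUE` a stage whose artifacts are
#' all present is skipped and its outputs reloaded from disk, so
#' deleting one stage's files and resuming reruns only that stage and
#' its dependents.  Per-stage seeds are derived from the global seed
#' (`seed + fixed offset per stage`) so any stage is reproducible in
#' isolation.
#'
#' @param config A [pipeline_config()].
#' @return List with `manifest` (tibble `file`, `md5`), `ran` (stages
#'   executed) and the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "lact_pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- stage_files(outdir)
  seeds <- config$seed + c(simulate = 0L, mtm = 11L, network = 22L,
                           sem = 33L)
  st <- list()
  ran <- character(0)

  need <- function(stage) {
    stage %in% config$stages &&
      (!config$resume || !all(file.exists(files[[stage]])))
  }

  # --- simulate ---
  if (need("simulate")) {
    herd <- simulate_herd(n_cows = config$n_cows, n_snp = config$n_snp,
                          n_genotyped = config$n_genotyped,
                          truth = config$truth, seed = seeds["simulate"])
    write_pedigree_csv(herd$pedigree, files$simulate[1])
    write_phenotypes_csv(herd$phenotypes, files$simulate[2])
    write_genotypes_csv(herd$genotypes, files$simulate[3])
    write_ground_truth_json(herd$truth, files$simulate[4])
    st$herd <- herd
    ran <- c(ran, "simulate")
  } else if (any(c("derive", "kinship") %in% config$stages)) {
    st$herd <- list(
      pedigree = read_pedigree_csv(files$simulate[1]),
      phenotypes = read_phenotypes_csv(files$simulate[2]),
      genotypes = read_genotypes_csv(files$simulate[3]),
      truth = config$truth
    )
  }

  # --- derive ---
  if (need("derive")) {
    at <- build_analysis_table(st$herd$phenotypes, pedigree = st$herd$pedigree)
    utils::write.csv(as.data.frame(at), files$derive[1], row.names = FALSE)
    utils::write.csv(as.data.frame(attr(at, "scaling")), files$derive[2],
                     row.names = FALSE)
    st$analysis_table <- at
    ran <- c(ran, "derive")
  } else if ("derive" %in% config$stages) {
    at <- tibble::as_tibble(utils::read.csv(files$derive[1]))
    at$herd_date <- factor(at$herd_date)
    at$dim_class <- factor(at$dim_class, levels = 1:12)
    at$parity_class <- factor(at$parity_class, levels = 1:4)
    attr(at, "scaling") <- tibble::as_tibble(utils::read.csv(files$derive[2]))
    class(at) <- c("lact_analysis_table", class(at))
    st$analysis_table <- at
  }

  # --- kinship ---
  if (need("kinship")) {
    ped <- prune_pedigree(st$herd$pedigree, st$analysis_table$animal,
                          generations = 3)
    geno <- st$herd$genotypes
    qc <- NULL
    if (!is.null(geno) && nrow(geno) > 0) {
      qcres <- qc_genotypes(geno, maf_min = config$qc$maf_min,
                            hwe_p_min = config$qc$hwe_p_min,
                            call_rate_min = config$qc$call_rate_min)
      qc <- qcres$report
      geno <- impute_genotypes(qcres$genotypes)
      geno <- geno[rownames(geno) %in% as.character(ped$animal), , drop = FALSE]
    }
    H_inv <- single_step_H_inverse(ped, geno)
    write_kinship_triplets(H_inv, files$kinship[1])
    jsonlite::write_json(unclass(qc), files$kinship[2], auto_unbox = TRUE,
                         digits = NA, null = "null")
    st$H_inv <- H_inv
    st$qc_report <- qc
    ran <- c(ran, "kinship")
  } else if ("kinship" %in% config$stages) {
    st$H_inv <- read_kinship_triplets(files$kinship[1])
  }

  # --- mtm ---
  if (need("mtm")) {
    cfg <- config$mtm_config
    cfg$seed <- seeds["mtm"]
    fit <- run_mtm(st$analysis_table, st$H_inv, config = cfg)
    utils::write.csv(as.data.frame(tidy(fit)), files$mtm[1], row.names = FALSE)
    res <- extract_residuals(fit)
    utils::write.csv(data.frame(animal = rownames(res), res,
                                check.names = FALSE),
                     files$mtm[2], row.names = FALSE)
    jsonlite::write_json(c(glance(fit), list(seed = unname(cfg$seed))),
                         files$mtm[3], auto_unbox = TRUE, digits = NA)
    st$mtm_fit <- fit
    ran <- c(ran, "mtm")
  }
  if (is.null(st$mtm_fit) && any(c("network", "report") %in% config$stages) &&
      file.exists(files$mtm[2])) {
    df <- utils::read.csv(files$mtm[2], check.names = FALSE)
    st$residuals <- as.matrix(df[, -1])
    rownames(st$residuals) <- df$animal
  } else if (!is.null(st$mtm_fit)) {
    st$residuals <- extract_residuals(st$mtm_fit)
  }

  # --- network ---
  if (need("network")) {
    net <- bootstrap_network(st$residuals, n_boot = config$n_boot,
                             strength_threshold = config$strength_threshold,
                             seed = seeds["network"])
    utils::write.csv(as.data.frame(tidy(net)), files$network[1],
                     row.names = FALSE)
    if (!is.null(net$retained)) write_dot(net, files$network[2])
    st$network <- net
    ran <- c(ran, "network")
  } else if ("network" %in% config$stages && file.exists(files$network[1])) {
    edges <- tibble::as_tibble(utils::read.csv(files$network[1]))
    kept <- edges[edges$retained, c("from", "to")]
    st$retained_edges <- kept
  }

  # --- sem ---
  if (need("sem")) {
    struct <- if (!is.null(st[["network"]])) {
      to_causal_structure(st[["network"]])
    } else {
      to_causal_structure(st[["retained_edges"]])
    }
    cfg <- config$sem_config
    cfg$seed <- seeds["sem"]
    fit <- run_sem(st$analysis_table, st$H_inv, struct, config = cfg)
    utils::write.csv(as.data.frame(tidy(fit)), files$sem[1], row.names = FALSE)
    utils::write.csv(as.data.frame(tidy(fit, parameter = "path")),
                     files$sem[2], row.names = FALSE)
    jsonlite::write_json(c(glance(fit), list(seed = unname(cfg$seed))),
                         files$sem[3], auto_unbox = TRUE, digits = NA)
    st$sem_fit <- fit
    ran <- c(ran, "sem")
  }

  # --- report ---
  # the report is regenerated whenever any upstream stage ran, so a
  # resumed partial rerun refreshes it
  if (need("report") || ("report" %in% config$stages && length(ran) > 0)) {
    rep <- suppressWarnings(
      assemble_report(st[["mtm_fit"]], st[["sem_fit"]], st[["network"]])
    )
    write_report(rep, file.path(outdir, "report"))
    st$report <- rep
    ran <- c(ran, "report")
  }

  all_files <- unlist(files)
  all_files <- all_files[file.exists(all_files)]
  manifest <- tibble::tibble(
    file = all_files,
    md5 = unname(tools::md5sum(all_files))
  )
  utils::write.csv(as.data.frame(manifest), file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  c(st, list(manifest = manifest, ran = ran))
}
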