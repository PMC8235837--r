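#' Run the end-to-end estimation pipeline
#'
#' Orchestrates a full run: either simulate a dataset (when `sim` is given)
#' or read pedigree / genotype / marker-map files, estimate recombination
#' rates and sex-specific maps, apply the quality filters, build parental
#' phenotype records and landscape summaries, and write everything (plus a
#' manifest with the configuration, seed and package version) to an output
#' directory. Identical configuration and seed produce byte-identical
#' outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param pedigree_file,genotype_file,map_file input paths (data mode).
#' @param sim a [sim_config()] (simulation mode; inputs are generated and
#'   also written to `out_dir`).
#' @param params a [peeling_params()].
#' @param n_map_iterations,init_length see [estimate_recombination()].
#' @param outlier_threshold cM/Mb screen for [filter_outliers()].
#' @param seed integer seed recorded in the manifest; in simulation mode it
#'   overrides `sim$seed`.
#' @return invisibly, a list with the fit, retained ids, phenotype table,
#'   accuracy metrics (simulation mode) and the output paths.
#' @export
run_pipeline <- function(out_dir, pedigree_file = NULL, genotype_file = NULL,
                         map_file = NULL, sim = NULL,
                         params = peeling_params(), n_map_iterations = 4L,
                         init_length = 100, outlier_threshold = 5,
                         seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  truth <- NULL
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    sim$seed <- as.integer(seed)
    ds <- simulate_dataset(sim)
    ped <- ds$pedigree
    mm <- ds$marker_map
    calls <- ds$genotypes
    truth <- ds$truth
    paths$pedigree <- write_pedigree(ped, file.path(out_dir, "pedigree.txt"))
    paths$genotypes <- write_genotypes(calls,
                                       file.path(out_dir, "genotypes.txt"))
    paths$map <- write_marker_map(mm, file.path(out_dir, "markers.txt"))
    tr <- truth$counts
    utils::write.table(tr, file.path(out_dir, "truth_counts.tsv"),
                       quote = FALSE, sep = "\t", row.names = FALSE)
    paths$truth <- file.path(out_dir, "truth_counts.tsv")
  } else {
    for (f in c(pedigree_file, genotype_file, map_file)) {
      if (is.null(f) || !file.exists(f)) {
        stop("pipeline input file missing: ",
             if (is.null(f)) "(not given)" else f)
      }
    }
    ped <- read_pedigree(pedigree_file)
    mm <- read_marker_map(map_file)
    calls <- read_genotypes(genotype_file, mm, pedigree = ped)
  }

  fit <- estimate_recombination(ped, calls, mm, params = params,
                                n_map_iterations = n_map_iterations,
                                init_length = init_length)

  panel <- classify_panels(.align_genotypes(ped, calls))
  genotyped <- names(panel)[panel != "ungenotyped"]
  keep <- filter_informative(ped, genotyped)
  if (!length(keep)) keep <- unique(fit$estimates$id)
  est_keep <- fit$estimates[fit$estimates$id %in% keep, , drop = FALSE]
  avg_rate <- tapply(est_keep$rate_cM_per_Mb, est_keep$id, mean)
  keep <- filter_outliers(avg_rate, outlier_threshold)
  est_keep <- est_keep[est_keep$id %in% keep, , drop = FALSE]
  pheno <- gametes_to_parent_phenotypes(est_keep, ped)

  paths$estimates <- write_estimates(est_keep,
                                     file.path(out_dir, "estimates.tsv"))
  paths$map_female <- write_genetic_map(fit$map_female,
                                        file.path(out_dir, "map_female.tsv"))
  paths$map_male <- write_genetic_map(fit$map_male,
                                      file.path(out_dir, "map_male.tsv"))
  utils::write.table(pheno, file.path(out_dir, "phenotypes.tsv"),
                     quote = FALSE, sep = "\t", row.names = FALSE)
  paths$phenotypes <- file.path(out_dir, "phenotypes.tsv")
  land <- do.call(rbind, lapply(names(fit$map_female), function(ch) {
    rbind(cbind(windowed_landscape(fit$map_female[[ch]]), sex = "F"),
          cbind(windowed_landscape(fit$map_male[[ch]]), sex = "M"))
  }))
  utils::write.table(land, file.path(out_dir, "landscape.tsv"),
                     quote = FALSE, sep = "\t", row.names = FALSE)
  paths$landscape <- file.path(out_dir, "landscape.tsv")

  acc <- NULL
  if (!is.null(truth)) {
    exc <- rbind(do.call(cbind, fit$exc_pat), do.call(cbind, fit$exc_mat))
    acc <- accuracy_metrics(truth, est_keep,
                            exc_by_interval = exc, ids = keep)
    utils::write.table(
      data.frame(metric = c("r_dams", "r_sires", "r_landscape_raw",
                            "r_landscape_smoothed"),
                 value = c(acc$per_individual, acc$landscape)),
      file.path(out_dir, "accuracy.tsv"),
      quote = FALSE, sep = "\t", row.names = FALSE)
    paths$accuracy <- file.path(out_dir, "accuracy.tsv")
  }

  manifest <- list(
    package = "peelrec",
    version = as.character(utils::packageVersion("peelrec")),
    seed = as.integer(seed),
    params = unclass(params),
    n_map_iterations = n_map_iterations,
    init_length = init_length,
    outlier_threshold = outlier_threshold,
    simulation = if (!is.null(sim)) unclass(sim) else NULL,
    inputs = list(pedigree = pedigree_file, genotypes = genotype_file,
                  map = map_file),
    outputs = paths
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)

  invisible(list(fit = fit, retained = keep, phenotypes = pheno,
                 accuracy = acc, paths = paths, manifest = manifest))
}
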