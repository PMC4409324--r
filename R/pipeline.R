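#' Assemble a pipeline configuration
#'
#' Collects the thresholds and inputs that drive [run_pipeline()]: either
#' paths to phenotype/block/annotation TSVs or a [sim_config()] to
#' synthesize them, the scan and correlation significance levels, the
#' co-location threshold, the deep-root depth cutoff, and the enrichment
#' window population size.
#'
#' @param simulation A [sim_config()], or `NULL` when reading from files.
#' @param phenotype_path,blocks_path,annotations_path Input TSV paths
#'   (ignored when `simulation` is given).
#' @param alpha_scan Association-scan significance cutoff (default 0.001).
#' @param alpha_corr Correlation significance cutoff (default 0.05).
#' @param min_traits Co-location depth threshold for hot spots (default 5).
#' @param deep_root_cutoff_cm Depth cutoff for % deep roots (default 20).
#' @param population_total Window population for enrichment (default 3680).
#' @param imputation_rank Rank for missing-cell imputation (default 2).
#' @param out_dir Output directory.
#' @param seed Integer seed for the synthetic stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = NULL,
                            phenotype_path = NULL, blocks_path = NULL,
                            annotations_path = NULL,
                            alpha_scan = 0.001, alpha_corr = 0.05,
                            min_traits = 5, deep_root_cutoff_cm = 20,
                            population_total = 3680,
                            imputation_rank = 2,
                            out_dir = tempfile("gxescan_run_"),
                            seed = 1L) {
  stopifnot(alpha_scan > 0, alpha_scan <= 1, alpha_corr > 0, alpha_corr <= 1,
            deep_root_cutoff_cm > 0, min_traits >= 1)
  if (is.null(simulation) &&
      (is.null(phenotype_path) || is.null(blocks_path))) {
    stop("either a simulation config or phenotype + blocks paths required",
         call. = FALSE)
  }
  structure(list(simulation = simulation,
                 phenotype_path = phenotype_path,
                 blocks_path = blocks_path,
                 annotations_path = annotations_path,
                 alpha_scan = alpha_scan, alpha_corr = alpha_corr,
                 min_traits = min_traits,
                 deep_root_cutoff_cm = deep_root_cutoff_cm,
                 population_total = population_total,
                 imputation_rank = imputation_rank,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror the [pipeline_config()] arguments,
#'   with an optional `simulation:` block mirroring [sim_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    sa <- y$simulation
    if (!is.null(sa$causal_windows)) {
      sa$causal_windows <- dplyr::bind_rows(lapply(sa$causal_windows,
                                                   tibble::as_tibble))
    }
    sim <- do.call(sim_config, sa)
  }
  y$simulation <- NULL
  do.call(pipeline_config, c(list(simulation = sim), y))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — synthesize or load inputs, least-squares
#' genotype means, missing-cell imputation, AMMI and GGE decompositions,
#' cross-experiment correlations, per-experiment introgression-block
#' association scan, significance filtering and region merging, hot-spot
#' detection, and QTL enrichment of each hot spot — writing every stage
#' output plus a run manifest (seed, stage record counts, file list) to
#' `config$out_dir`.  Runs are idempotent for a fixed seed.
#'
#' @param config A `pipeline_config`.
#' @param annotations Optional annotation tibble overriding the configured
#'   path (convenient for synthetic runs).
#' @return The manifest (list); stage results are attached as attribute
#'   `"results"`.
#' @export
run_pipeline <- function(config, annotations = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  if (!is.null(config$simulation)) {
    sim <- sim_phenotypes(config$simulation)
    obs <- sim$observations
    blocks <- sim_blocks(config$simulation)
    pheno <- ls_means(obs)
  } else {
    if (!file.exists(config$phenotype_path)) {
      stop("stage load: phenotype file not found: ", config$phenotype_path,
           call. = FALSE)
    }
    if (!file.exists(config$blocks_path)) {
      stop("stage load: blocks file not found: ", config$blocks_path,
           call. = FALSE)
    }
    pheno <- read_phenotype_tsv(config$phenotype_path)
    blocks <- read_blocks_tsv(config$blocks_path)
    obs <- NULL
  }
  if (is.null(annotations) && !is.null(config$annotations_path)) {
    annotations <- read_annotations_tsv(config$annotations_path)
  }
  write_phenotype_tsv(pheno, file.path(config$out_dir, "ls_means.tsv"))
  write_blocks_tsv(blocks, file.path(config$out_dir, "blocks.tsv"))
  counts$genotypes <- nrow(pheno)
  counts$environments <- ncol(pheno) - 1L
  counts$windows <- nrow(blocks)

  filled <- if (anyNA(pheno_values(pheno))) {
    impute_missing(pheno, rank = config$imputation_rank)
  } else pheno
  ammi <- ammi_decompose(filled)
  gge <- gge_decompose(filled)
  partition <- ss_partition_percent(ammi)
  readr::write_tsv(tidy(ammi), file.path(config$out_dir, "biplot_ammi.tsv"))
  readr::write_tsv(tidy(gge), file.path(config$out_dir, "biplot_gge.tsv"))
  readr::write_tsv(ammi$ss, file.path(config$out_dir, "ss_table.tsv"))
  readr::write_tsv(partition, file.path(config$out_dir, "ss_percent.tsv"))
  for (axis in c("genotypes", "environments")) {
    tr <- cluster_dendrogram(filled, axis)
    write_newick(tr, file.path(config$out_dir,
                               paste0("dendrogram_", axis, ".nwk")))
  }

  cm <- pairwise_correlations(pheno)
  readr::write_tsv(tibble::as_tibble(cm),
                   file.path(config$out_dir, "correlations.tsv"))
  sig_counts <- count_significant(cm, alpha = config$alpha_corr,
                                  sign_split = TRUE)
  readr::write_tsv(sig_counts,
                   file.path(config$out_dir, "correlation_counts.tsv"))
  counts$correlation_pairs <- sum(!is.na(cm$r) & cm$exp1 < cm$exp2)

  experiments <- setdiff(names(pheno), "genotype")
  records <- dplyr::bind_rows(lapply(experiments, function(ex)
    block_association(blocks, pheno, ex)))
  readr::write_tsv(records, file.path(config$out_dir, "associations.tsv"))
  counts$associations_tested <- nrow(records)
  sig <- suppressMessages(filter_significant(records,
                                             alpha = config$alpha_scan))
  counts$significant_blocks <- nrow(sig)
  regions <- merge_regions(sig)
  counts$regions <- nrow(regions)
  if (nrow(regions) > 0) {
    write_bed(regions, file.path(config$out_dir, "regions.bed"))
  }
  hotspots <- detect_hotspots(regions, min_traits = config$min_traits)
  counts$hotspots <- nrow(hotspots)
  if (nrow(hotspots) > 0) {
    write_bed(hotspots, file.path(config$out_dir, "hotspots.bed"))
  }

  enrichment <- NULL
  if (!is.null(annotations) && nrow(hotspots) > 0) {
    win_of <- function(ch, s, e) {
      i <- blocks$chrom == ch & blocks$start >= s & blocks$end <= e
      blocks$window[i]
    }
    enrichment <- dplyr::bind_rows(lapply(seq_len(nrow(hotspots)),
      function(i) {
        rec <- enrich_region(win_of(hotspots$chrom[i], hotspots$start[i],
                                    hotspots$end[i]),
                             annotations, config$population_total)
        rec$hotspot <- sprintf("%s:%d-%d", hotspots$chrom[i],
                               hotspots$start[i], hotspots$end[i])
        rec
      }))
    readr::write_tsv(enrichment, file.path(config$out_dir, "enrichment.tsv"))
    counts$enrichment_records <- nrow(enrichment)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gxescan")),
    seed = config$seed,
    parameters = list(alpha_scan = config$alpha_scan,
                      alpha_corr = config$alpha_corr,
                      min_traits = config$min_traits,
                      population_total = config$population_total),
    counts = counts,
    files = sort(list.files(config$out_dir))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results <- list(pheno = pheno, blocks = blocks, ammi = ammi, gge = gge,
                  partition = partition, correlations = cm,
                  associations = records, significant = sig,
                  regions = regions, hotspots = hotspots,
                  enrichment = enrichment)
  structure(manifest, results = results)
}
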