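#' Pipeline run configuration
#'
#' Collects the input paths and every stage parameter with defaults
#' matching the analysis conventions the package implements: rarefaction
#' depth 50,000 reads, rare-ASV cut 0.01%, pair zero filter 50%,
#' prevalence filter 20 non-zero samples, 100 bootstrap resamples at
#' alpha 0.05, hub thresholds 1% of edges and betweenness 0.1,
#' collinearity screen at 0.5, and 10 subsamples of 1% of rows for the
#' GLM robustness check.
#'
#' @param abundance,metadata,fasta Paths to the three inputs.
#' @param taxonomy Optional taxonomy TSV path.
#' @param out_dir Output directory for stage tables and the manifest.
#' @param orientation Abundance TSV orientation (see [read_abundance()]).
#' @param depth Rarefaction depth; `NULL` skips rarefaction.
#' @param min_rel_abund Rare-ASV threshold.
#' @param max_zero_frac,zero_mode Pair zero-filter settings.
#' @param scope Pair grouping unit.
#' @param gd_model Genetic-distance model.
#' @param min_nonzero,n_boot,alpha,rho_threshold,network_fdr Network
#'   stage settings.
#' @param hub_degree_frac,hub_betweenness Hub criteria.
#' @param collinearity_threshold GLM collinearity screen threshold.
#' @param glm_pairs `"all"` or `"significant"`.
#' @param subsample_frac,subsample_reps GLM robustness settings.
#' @param seed Root seed; all stage randomness derives from it.
#' @return A `run_config` list.
#' @export
run_config <- function(abundance, metadata, fasta, taxonomy = NULL,
                       out_dir = tempfile("microcooc_run_"),
                       orientation = "samples_as_rows",
                       depth = 50000, min_rel_abund = 1e-4,
                       max_zero_frac = 0.5, zero_mode = "pooled",
                       scope = "treatment", gd_model = "p",
                       min_nonzero = 20, n_boot = 100, alpha = 0.05,
                       rho_threshold = 0, network_fdr = FALSE,
                       hub_degree_frac = 0.01, hub_betweenness = 0.1,
                       collinearity_threshold = 0.5, glm_pairs = "all",
                       subsample_frac = 0.01, subsample_reps = 10,
                       seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Run the full pipeline on files
#'
#' Executes preprocess, genetic distance, diversity, co-occurrence,
#' network, and GLM stages in order, writing every stage table (TSV), the
#' network (GraphML), and a JSON manifest recording parameters, the seed,
#' and per-stage row counts. Identical configurations and seeds produce
#' byte-identical outputs. A stage failure aborts with the stage name and
#' cause.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(parameters = config_params(config), stages = list())
  results <- list()

  stage <- function(name, expr) {
    message(sprintf("[%s] running", name))
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  results$inputs <- stage("read_inputs", {
    abundance <- read_abundance(config$abundance, orientation = config$orientation)
    metadata <- read_metadata(config$metadata)
    seqs <- read_aligned_fasta(config$fasta)
    taxonomy <- if (!is.null(config$taxonomy)) read_taxonomy(config$taxonomy) else NULL
    validate_inputs(abundance, metadata, seqs, taxonomy)
    list(abundance = abundance, metadata = metadata, seqs = seqs, taxonomy = taxonomy)
  })
  inp <- results$inputs

  counts <- stage("preprocess", {
    x <- remove_singletons(inp$abundance)
    if (!is.null(config$depth)) x <- rarefy(x, depth = config$depth, seed = seed_for(config$seed, "rarefy"))
    filter_rare_asvs(x, min_rel_abund = config$min_rel_abund)
  })
  manifest$stages$preprocess <- list(n_samples = nrow(counts), n_asvs = length(asv_ids(counts)))

  dist <- stage("gendist", {
    distance_matrix(inp$seqs[intersect(names(inp$seqs), asv_ids(counts))],
                    model = config$gd_model)
  })
  write_distance_matrix(dist, file.path(config$out_dir, "distances.tsv"))
  manifest$stages$gendist <- list(n_asvs = nrow(dist),
                                  n_undefined = length(attr(dist, "undefined_pairs")))

  diversity <- stage("diversity", {
    list(samples = sample_diversity(counts),
         treatments = treatment_diversity_table(counts, inp$metadata))
  })
  readr::write_tsv(diversity$samples, file.path(config$out_dir, "diversity_samples.tsv"), progress = FALSE)
  readr::write_tsv(diversity$treatments, file.path(config$out_dir, "diversity_treatments.tsv"), progress = FALSE)
  manifest$stages$diversity <- list(n_samples = nrow(diversity$samples),
                                    n_treatments = nrow(diversity$treatments))

  pairs <- stage("cooccur", {
    rel <- to_relative(counts)
    pair_table(rel, inp$metadata, dist, scope = config$scope,
               max_zero_frac = config$max_zero_frac, zero_mode = config$zero_mode)
  })
  write_pair_table(pairs, file.path(config$out_dir, "pairs.tsv"))
  manifest$stages$cooccur <- list(n_pairs = nrow(pairs),
                                  n_groups = length(unique(pairs$group_id)),
                                  dropped_missing_gd = attr(pairs, "dropped_missing_gd"))

  network <- stage("network", {
    build_network(counts, taxonomy = inp$taxonomy,
                  min_nonzero = config$min_nonzero, n_boot = config$n_boot,
                  alpha = config$alpha, seed = seed_for(config$seed, "bootstrap"),
                  rho_threshold = config$rho_threshold,
                  network_fdr = config$network_fdr,
                  hub_degree_frac = config$hub_degree_frac,
                  hub_betweenness = config$hub_betweenness)
  })
  write_edge_list(network, file.path(config$out_dir, "edges.tsv"))
  readr::write_tsv(network$nodes, file.path(config$out_dir, "nodes.tsv"), progress = FALSE)
  write_graphml(network, file.path(config$out_dir, "network.graphml"))
  manifest$stages$network <- as.list(glance(network))

  glm_res <- stage("glm", {
    lm_fits <- fit_lm(pairs)
    design <- build_glm_design(pairs, inp$metadata, diversity$treatments,
                               pairs_filter = config$glm_pairs,
                               threshold = config$collinearity_threshold)
    best <- select_model(design)
    robustness <- tryCatch(
      subsample_robustness(design, frac = config$subsample_frac,
                           reps = config$subsample_reps,
                           seed = seed_for(config$seed, "subsample"),
                           terms = best$terms),
      error = function(e) {
        warn(sprintf("subsample robustness skipped: %s", conditionMessage(e)))
        NULL
      }
    )
    list(lm_fits = lm_fits, design = design, best = best, robustness = robustness)
  })
  readr::write_tsv(glm_res$lm_fits, file.path(config$out_dir, "lm_by_experiment.tsv"), progress = FALSE)
  readr::write_tsv(tidy(glm_res$best), file.path(config$out_dir, "glm_coefficients.tsv"), progress = FALSE)
  readr::write_tsv(glm_res$best$trace, file.path(config$out_dir, "glm_trace.tsv"), progress = FALSE)
  if (!is.null(glm_res$robustness)) {
    readr::write_tsv(glm_res$robustness$summary, file.path(config$out_dir, "glm_robustness.tsv"), progress = FALSE)
  }
  manifest$stages$glm <- list(
    n_design_rows = nrow(glm_res$design),
    selected_formula = glm_res$best$formula,
    aic = AIC(glm_res$best$fit),
    robustness_reps = if (is.null(glm_res$robustness)) 0L else config$subsample_reps
  )

  manifest$n_stages_completed <- length(manifest$stages)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$counts <- counts
  results$distances <- dist
  results$diversity <- diversity
  results$pairs <- pairs
  results$network <- network
  results$glm <- glm_res
  results$manifest <- manifest
  invisible(results)
}

config_params <- function(config) {
  keep <- setdiff(names(config), c("abundance", "metadata", "fasta", "taxonomy", "out_dir"))
  p <- unclass(config)[keep]
  p[!vapply(p, is.null, logical(1))]
}

#' Taxon composition and prevalence summaries
#'
#' Per-taxon mean relative abundance (mean of per-sample proportions) and
#' prevalence (fraction of samples where the taxon is present). Without a
#' taxonomy the table is produced at ASV level with a warning.
#'
#' @param table Wide abundance tibble of counts.
#' @param taxonomy Optional taxonomy tibble.
#' @param rank Rank to aggregate at (default `"genus"`).
#' @param min_prevalence,min_abund Optional cutoffs applied to the
#'   `filtered` table in the result.
#' @return A list with `composition` (all taxa) and `filtered` (taxa
#'   passing the cutoffs), each `(taxon, mean_rel_abund, prevalence)`.
#' @export
summary_tables <- function(table, taxonomy = NULL, rank = "genus",
                           min_prevalence = 0, min_abund = 0) {
  check_abundance(table)
  m <- as_count_matrix(to_relative(table))
  if (is.null(taxonomy)) {
    warn("no taxonomy provided; summarising at ASV level")
    taxon <- colnames(m)
  } else {
    tx <- taxonomy[[rank]][match(colnames(m), taxonomy$asv_id)]
    taxon <- ifelse(is.na(tx) | tx == "", "Unassigned", tx)
  }
  groups <- split(seq_len(ncol(m)), taxon)
  composition <- purrr::map_dfr(names(groups), function(g) {
    sub <- m[, groups[[g]], drop = FALSE]
    per_sample <- rowSums(sub)
    tibble::tibble(
      taxon = g,
      mean_rel_abund = mean(per_sample),
      prevalence = mean(per_sample > 0)
    )
  }) |> dplyr::arrange(dplyr::desc(.data$mean_rel_abund))
  filtered <- composition[composition$prevalence >= min_prevalence &
                            composition$mean_rel_abund >= min_abund, , drop = FALSE]
  list(composition = composition, filtered = filtered)
}
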