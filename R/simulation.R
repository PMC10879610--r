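#' Run the full analysis on an in-memory study bundle
#'
#' Convenience wrapper chaining the pipeline stages on a study bundle as
#' returned by [generate_study()] (or assembled from [read_abundance()],
#' [read_metadata()], [read_aligned_fasta()]): singleton removal, optional
#' rarefaction, rare-ASV filtering, genetic distances, relative
#' abundances, the per-group pair table, treatment diversity, the GLM
#' design with collinearity screen, the full Gaussian GLM, exhaustive AIC
#' selection, and per-experiment linear fits of rho on genetic distance.
#'
#' @param study List with elements `abundance`, `metadata`, `seqs`.
#' @param depth Rarefaction depth, or `NULL` to skip rarefaction (samples
#'   already at a common depth).
#' @param min_rel_abund Rare-ASV threshold (default 1e-4).
#' @param gd_model Distance model, `"p"` or `"jc69"`.
#' @param scope Pair grouping, `"treatment"` or `"experiment"`.
#' @param glm_pairs `"all"` or `"significant"` (FDR-filtered) pairs for
#'   the GLM.
#' @param max_zero_frac,zero_mode Pair zero-filter settings.
#' @param select Run exhaustive AIC selection (default `TRUE`).
#' @return A list: `pairs`, `diversity`, `design`, `full_fit`,
#'   `best_fit` (when `select`), `lm_fits`, `distances`.
#' @export
run_study_analysis <- function(study, depth = NULL, min_rel_abund = 1e-4,
                               gd_model = c("p", "jc69"),
                               scope = c("treatment", "experiment"),
                               glm_pairs = c("all", "significant"),
                               max_zero_frac = 0.5,
                               zero_mode = c("pooled", "either"),
                               select = TRUE) {
  gd_model <- match.arg(gd_model)
  scope <- match.arg(scope)
  glm_pairs <- match.arg(glm_pairs)
  zero_mode <- match.arg(zero_mode)

  counts <- remove_singletons(study$abundance)
  if (!is.null(depth)) counts <- rarefy(counts, depth = depth, seed = 1L)
  counts <- filter_rare_asvs(counts, min_rel_abund = min_rel_abund)
  dist <- distance_matrix(study$seqs[intersect(names(study$seqs), asv_ids(counts))],
                          model = gd_model)
  rel <- to_relative(counts)
  pairs <- pair_table(rel, study$metadata, dist, scope = scope,
                      max_zero_frac = max_zero_frac, zero_mode = zero_mode)
  diversity <- treatment_diversity_table(counts, study$metadata)
  design <- build_glm_design(pairs, study$metadata, diversity,
                             pairs_filter = glm_pairs)
  full_fit <- fit_glm(design)
  best_fit <- if (select) select_model(design) else NULL
  lm_fits <- fit_lm(pairs)
  list(pairs = pairs, diversity = diversity, design = design,
       full_fit = full_fit, best_fit = best_fit, lm_fits = lm_fits,
       distances = dist)
}

#' Sign-recovery simulation study
#'
#' Generates `n_reps` independent synthetic studies from `config` (varying
#' only the seed), runs the full analysis on each, and records whether the
#' AIC-selected GLM reproduces all five known coefficient signs and
#' whether every per-experiment linear slope of co-occurrence on genetic
#' distance is negative.
#'
#' @param n_reps Number of replicate studies (default 50).
#' @param config A [synth_config()]; its effect signs define the truth.
#' @param seed Root seed for the replicate seeds.
#' @return Tibble with one row per replicate: `rep`, `signs_ok`,
#'   `n_experiments`, `n_negative_slopes`, `all_slopes_negative`,
#'   `gd_p_full` (full-model p-value of the `gd` term).
#' @export
replicate_sign_recovery <- function(n_reps = 50, config = synth_config(),
                                    seed = 1L) {
  truth_terms <- c("gd", "shannon", "n_voles", "diet_grass", "contact_yes")
  purrr::map_dfr(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- seed_for(seed, sprintf("rep_%04d", r))
    study <- generate_study(cfg)
    res <- run_study_analysis(study)
    truth_signs <- study$truth$effect_signs[truth_terms]
    est <- tidy(res$best_fit)
    est <- est[est$term %in% truth_terms, ]
    signs_ok <- all(truth_terms %in% est$term) &&
      all(sign(est$estimate[match(truth_terms, est$term)]) == truth_signs)
    full <- tidy(res$full_fit)
    gd_p <- full$p_value[full$term == "gd"]
    tibble::tibble(
      rep = r,
      signs_ok = signs_ok,
      n_experiments = nrow(res$lm_fits),
      n_negative_slopes = sum(res$lm_fits$slope < 0),
      all_slopes_negative = all(res$lm_fits$slope < 0),
      gd_p_full = if (length(gd_p) == 1) gd_p else NA_real_
    )
  })
}

#' Null (type-I) simulation for the GLM
#'
#' Runs the pipeline on studies generated with all effect sizes set to
#' zero, so the genetic-distance term has no true effect, and returns the
#' full-model p-value of the `gd` coefficient for each replicate. Under a
#' calibrated test about 5% of the p-values fall below 0.05.
#'
#' @param n_reps Number of replicates (default 200).
#' @param config Base configuration; its effect sizes and the ambient
#'   coupling (`baseline_cor`) are zeroed, making ASV pairs exchangeable.
#' @param seed Root seed.
#' @return Tibble `(rep, gd_p)`.
#' @export
replicate_null_gd <- function(n_reps = 200, config = synth_config(),
                              seed = 1L) {
  config$beta_gd <- 0
  config$beta_shannon <- 0
  config$beta_n <- 0
  config$beta_diet <- 0
  config$beta_contact <- 0
  config$baseline_cor <- 0
  purrr::map_dfr(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- seed_for(seed, sprintf("null_%04d", r))
    study <- generate_study(cfg)
    res <- run_study_analysis(study, select = FALSE)
    full <- tidy(res$full_fit)
    tibble::tibble(rep = r, gd_p = full$p_value[full$term == "gd"])
  })
}

#' Bootstrap edge retention under independent noise
#'
#' Simulates a community of mutually independent ASVs (identity latent
#' correlation), applies the network bootstrap, and reports the fraction
#' of candidate pairs retained at `alpha` - an estimate of the network's
#' per-edge type-I rate.
#'
#' @param n_asvs,n_samples Size of the noise community.
#' @param n_boot,alpha Bootstrap settings (defaults 100 and 0.05).
#' @param seed Integer seed.
#' @param depth Sequencing depth per sample.
#' @return A list with `retention` (proportion kept), `n_pairs`, and the
#'   edge tibble.
#' @export
null_edge_retention <- function(n_asvs = 46, n_samples = 60, n_boot = 100,
                                alpha = 0.05, seed = 1L, depth = 5000) {
  cfg <- synth_config(
    n_asvs = n_asvs, depth = depth,
    treatments = tibble::tibble(
      treatment_id = "T1", diet = "chow", contact = "no",
      n_voles = 1L, n_samples = as.integer(n_samples), diversity = 0.8
    ),
    beta_gd = 0, beta_shannon = 0, beta_n = 0, beta_diet = 0,
    beta_contact = 0, baseline_cor = 0, seed = as.integer(seed)
  )
  corr <- diag(n_asvs)
  colnames(corr) <- rownames(corr) <- sprintf("ASV_%03d", seq_len(n_asvs))
  counts <- simulate_counts(corr, n_samples, cfg,
                            seed = seed_for(seed, "null_edges"))
  counts$sample_id <- sprintf("ns%03d", seq_len(n_samples))
  rel <- column_normalize(counts)
  edges <- bootstrap_edges(rel, n_boot = n_boot, alpha = alpha,
                           seed = seed_for(seed, "null_boot"))
  list(retention = mean(edges$keep), n_pairs = nrow(edges), edges = edges)
}
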