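#' Configuration for the synthetic study generator
#'
#' Defines the data-generating structure the analysis assumes: ASV
#' sequences related by a pure-birth tree, per-treatment latent Gaussian
#' copulas whose pairwise correlation is a linear function of genetic
#' relatedness and the treatment covariates, and multinomial sequencing
#' noise at fixed depth.
#'
#' Effect sizes are expressed on the latent-correlation scale. `beta_gd`
#' multiplies genetic *relatedness* `1 - d/d_max`, so a positive `beta_gd`
#' makes co-occurrence decay with genetic distance (a negative GLM
#' coefficient for `gd`); `beta_n` multiplies the scaled group size;
#' `beta_diet`/`beta_contact` shift grass-fed and physical-contact
#' treatments. Each treatment carries a `diversity` level in `[0, 1]` that
#' sets its community's richness and evenness (hence realised Shannon,
#' Simpson, and Chao1 diversity) and, through `beta_shannon`, its baseline
#' co-occurrence.
#'
#' The pairwise (genetic-distance) structure is drawn through a Gaussian
#' copula with the target correlations of [build_target_correlation()].
#' Treatment-level effects additionally drive the spread of a shared
#' environmental-response axis: a block of dominant responder taxa moves
#' jointly along a bounded, graded per-sample gradient, which couples the
#' relative abundances of all other taxa through the compositional
#' denominator. This second channel exists because relative-abundance data
#' are compositional: a uniform additive shift of the latent correlation
#' matrix is removed by closure and would otherwise be unobservable.
#'
#' @param n_asvs Number of ASVs (tree tips).
#' @param seq_length Alignment width in sites.
#' @param birth_rate Pure-birth (Yule) speciation rate.
#' @param subst_rate Expected substitutions per site per unit branch
#'   length (Jukes-Cantor); 0 gives identical sequences.
#' @param treatments Tibble with one row per treatment: `treatment_id`,
#'   `diet`, `contact`, `n_voles`, `n_samples`, `diversity`.
#' @param baseline_cor Baseline latent correlation shared by all pairs.
#' @param beta_gd,beta_shannon,beta_n,beta_diet,beta_contact Effect sizes.
#' @param depth Sequencing depth per sample (multinomial total).
#' @param latent_sd Standard deviation of the latent per-sample noise.
#' @param mu_scale Scale of the dominance hierarchy among present taxa; a
#'   treatment with diversity `e` sharpens log-abundance differences in
#'   proportion to `(1 - e) * mu_scale`. Low-diversity treatments also
#'   lose the bottom quantile of taxa outright (nested absence).
#' @param stress_scale Coupling strength of the shared environmental
#'   response: per-factor loadings have standard deviation
#'   `stress_scale * sqrt(max(shift, 0))`, where `shift` is the
#'   treatment-level part of the target-correlation formula. Relative
#'   abundances are compositional, so a uniform additive shift of the
#'   latent correlation matrix is unobservable after closure; the shared
#'   response of the responder taxa is what carries treatment-level
#'   co-occurrence onto the observed scale.
#' @param n_stress_factors Number of independent shared-response factors.
#' @param responders_per_factor Responder taxa per factor (disjoint sets).
#' @param responder_bonus Log-abundance bonus making responder taxa
#'   dominant enough to move the compositional denominator.
#' @param seed Root seed; all randomness derives from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_asvs = 40, seq_length = 250, birth_rate = 1,
                         subst_rate = 0.05, treatments = default_treatments(),
                         baseline_cor = 0.2, beta_gd = 0.6, beta_shannon = 0.35,
                         beta_n = -0.2, beta_diet = 0.12, beta_contact = -0.12,
                         depth = 5000, latent_sd = 0.6, mu_scale = 8,
                         stress_scale = 1.45, n_stress_factors = 4,
                         responders_per_factor = 5, responder_bonus = 0.3,
                         seed = 1L) {
  if (n_asvs < 2) abort("n_asvs must be at least 2")
  stopifnot(all(c("treatment_id", "diet", "contact", "n_voles", "n_samples",
                  "diversity") %in% names(treatments)))
  if (any(treatments$n_samples < 1) || any(treatments$n_voles < 1)) {
    abort("treatment sample and vole counts must be positive")
  }
  n_responders <- n_stress_factors * responders_per_factor
  if (n_responders >= n_asvs) abort("too many responder taxa for n_asvs")
  structure(list(
    n_asvs = n_asvs, seq_length = seq_length, birth_rate = birth_rate,
    subst_rate = subst_rate, treatments = tibble::as_tibble(treatments),
    baseline_cor = baseline_cor, beta_gd = beta_gd,
    beta_shannon = beta_shannon, beta_n = beta_n, beta_diet = beta_diet,
    beta_contact = beta_contact, depth = depth, latent_sd = latent_sd,
    mu_scale = mu_scale, stress_scale = stress_scale,
    n_stress_factors = n_stress_factors,
    responders_per_factor = responders_per_factor,
    responder_bonus = responder_bonus, seed = as.integer(seed)
  ), class = "synth_config")
}

#' Default synthetic treatment layout
#'
#' Twenty-four treatment groups of 20 samples, emulating a multi-treatment
#' vole study. Diet and contact are balanced and mutually orthogonal,
#' group sizes (2/4/8) are balanced within each diet, and the diversity
#' levels are spread so that no treatment-level predictor is strongly
#' confounded with another. Identifying four treatment-level covariate
#' effects from group means needs the treatment-level design to keep
#' ample residual degrees of freedom, which a handful of groups cannot
#' provide.
#'
#' @return A tibble with one row per treatment.
#' @export
default_treatments <- function() {
  tibble::tibble(
    treatment_id = sprintf("T%02d", 1:24),
    diet = rep(c("grass", "chow"), each = 12),
    contact = rep(c("no", "yes"), 12),
    n_voles = rep(c(2L, 8L, 4L), 8),
    n_samples = rep(20L, 24),
    diversity = c(0.85, 0.75, 0.3, 0.6, 0.5, 0.9, 0.4, 0.25, 0.65, 0.95, 0.8, 0.55,
                  0.45, 0.3, 0.7, 0.95, 0.85, 0.5, 0.35, 0.6, 0.25, 0.8, 0.9, 0.55)
  )
}

#' Simulate a tree and aligned ASV sequences
#'
#' Grows a pure-birth tree on `n_asvs` tips, draws a uniform root
#' sequence, and evolves it along the branches under Jukes-Cantor at
#' `subst_rate` substitutions per site per unit branch length. Returns the
#' aligned sequences together with the tree and the realised pairwise
#' p-distances.
#'
#' @param config A [synth_config()].
#' @return A list with `seqs` (named character vector), `tree`
#'   (`ape::phylo`), and `distances` (p-distance matrix).
#' @export
simulate_tree_and_seqs <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  ids <- sprintf("ASV_%03d", seq_len(config$n_asvs))
  res <- withr::with_seed(seed_for(config$seed, "tree_and_seqs"), {
    tree <- ape::rphylo(config$n_asvs, birth = config$birth_rate, death = 0)
    tree$tip.label <- ids
    if (config$subst_rate == 0) {
      root <- sample(c("A", "C", "G", "T"), config$seq_length, replace = TRUE)
      seqs <- setNames(rep(paste(root, collapse = ""), config$n_asvs), ids)
    } else {
      sim <- phangorn::simSeq(tree, l = config$seq_length,
                              rate = config$subst_rate, type = "DNA")
      chars <- toupper(as.character(sim))
      seqs <- setNames(apply(chars, 1, paste, collapse = ""), rownames(chars))
      seqs <- seqs[ids]
    }
    list(seqs = seqs, tree = tree)
  })
  distances <- distance_matrix(res$seqs, model = "p")
  list(seqs = res$seqs, tree = res$tree, distances = distances)
}

#' Per-treatment target correlation matrix
#'
#' Builds the latent correlation matrix for one treatment:
#' `rho_ij = clip(baseline + beta_gd * (1 - d_ij/d_max) + beta_shannon * e
#' + beta_n * n/n_max + beta_diet * [grass] + beta_contact * [contact])`,
#' clipped to `[-0.95, 0.95]`, then repaired to the nearest valid
#' correlation matrix by clipping eigenvalues at 1e-6 and re-unitising the
#' diagonal.
#'
#' @param distances Pairwise genetic-distance matrix.
#' @param treatment One row of the config's treatment tibble.
#' @param config A [synth_config()].
#' @return A positive semi-definite correlation matrix.
#' @export
build_target_correlation <- function(distances, treatment, config) {
  stopifnot(inherits(config, "synth_config"))
  d_max <- max(distances, na.rm = TRUE)
  relatedness <- if (d_max > 0) 1 - distances / d_max else matrix(1, nrow(distances), ncol(distances))
  rho <- treatment_shift(treatment, config) + config$beta_gd * relatedness
  rho <- pmin(pmax(rho, -0.95), 0.95)
  diag(rho) <- 1
  repair_correlation(rho)
}

# Treatment-level part of the target-correlation formula: the covariate
# effects shared by all pairs of a treatment.
treatment_shift <- function(treatment, config) {
  n_max <- max(config$treatments$n_voles)
  config$baseline_cor +
    config$beta_shannon * treatment$diversity +
    config$beta_n * treatment$n_voles / n_max +
    config$beta_diet * as.numeric(treatment$diet == "grass") +
    config$beta_contact * as.numeric(treatment$contact == "yes")
}

# Nearest-PSD repair: clip eigenvalues at 1e-6, rebuild, rescale diagonal.
repair_correlation <- function(R) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= 1e-6) return(R)
  vals <- pmax(e$values, 1e-6)
  A <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(A))
  A <- A / tcrossprod(d)
  diag(A) <- 1
  A <- (A + t(A)) / 2
  dimnames(A) <- dimnames(R)
  A
}

#' Simulate a count table for one treatment
#'
#' Latent multivariate-normal draws with the treatment's target
#' correlation are exponentiated, normalised to proportions, and sampled
#' multinomially at the configured depth.
#'
#' @param correlation Valid correlation matrix (ASVs x ASVs).
#' @param n_samples Number of samples to draw.
#' @param config A [synth_config()].
#' @param mu Per-ASV latent log-mean vector (default all zero).
#' @param seed Integer seed for this treatment's draws.
#' @param stress_sd Standard deviation of the shared environmental
#'   response factors (default 0: none).
#' @param responder_sets List of integer index vectors: the taxa loading
#'   on each shared-response factor.
#' @param idio_sd Standard deviation of extra idiosyncratic latent noise
#'   (attenuates all pairwise association; default 0).
#' @return A wide abundance tibble (`sample_id` left blank for the caller
#'   to fill) with `n_samples` rows.
#' @export
simulate_counts <- function(correlation, n_samples, config, mu = NULL,
                            seed = 1L, stress_sd = 0, responder_sets = list(),
                            idio_sd = 0) {
  stopifnot(inherits(config, "synth_config"))
  k <- nrow(correlation)
  if (is.null(mu)) mu <- rep(0, k)
  L <- chol(correlation)
  counts <- withr::with_seed(as.integer(seed), {
    Z <- matrix(rnorm(n_samples * k), n_samples, k)
    latent <- sweep(config$latent_sd * (Z %*% L), 2, mu, `+`)
    if (idio_sd > 0) {
      latent <- latent + idio_sd * matrix(rnorm(n_samples * k), n_samples, k)
    }
    if (stress_sd > 0 && length(responder_sets) > 0) {
      # graded environmental axis: samples occupy fixed symmetric quantile
      # positions (unit variance, bounded), scaled by the treatment's
      # coupling strength and randomly assigned to samples. The bounded
      # symmetric spread moves the responder share without shifting its
      # mean, so coupling strength barely perturbs mean diversity, and the
      # realised spread is exact rather than a noisy draw.
      grid <- sqrt(3) * (2 * (seq_len(n_samples) - 0.5) / n_samples - 1)
      for (set in responder_sets) {
        eta <- stress_sd * sample(grid)
        latent[, set] <- latent[, set] + eta
      }
    }
    t(apply(latent, 1, function(x) {
      p <- exp(x - max(x))
      rmultinom(1, size = config$depth, prob = p / sum(p))[, 1]
    }))
  })
  colnames(counts) <- colnames(correlation)
  rownames(counts) <- sprintf("s%03d", seq_len(n_samples))
  count_matrix_to_tibble(counts)
}

#' Generate a complete synthetic study
#'
#' Composes tree/sequence simulation, per-treatment correlation targets,
#' and count simulation into a full input bundle, optionally writing the
#' three input files (abundance TSV, metadata TSV, aligned FASTA) to a
#' directory. Identical seeds produce byte-identical bundles.
#'
#' @param config A [synth_config()].
#' @param dir Optional output directory; created if needed.
#' @return A list: `abundance`, `metadata`, `seqs`, `truth` (tree,
#'   distances, per-treatment target correlations, expected GLM
#'   coefficient signs), `config`, and `paths` (when `dir` is given).
#' @export
generate_study <- function(config = synth_config(), dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  sim <- simulate_tree_and_seqs(config)
  ids <- names(sim$seqs)
  # Diversity acts on the rare flank only: taxa with negative heterogeneity
  # scores sink as the treatment's diversity level drops, while the
  # dominant flank keeps the same profile in every treatment. This keeps
  # the strength of compositional closure (driven by the dominant taxa)
  # comparable across treatments, so diversity moves Shannon without also
  # moving the baseline co-occurrence of relative abundances.
  # stratified heterogeneity scores (normal quantiles, randomly assigned)
  # keep the community profile identical across studies; only which taxa
  # take which role varies. Low diversity removes the bottom quantile of
  # taxa outright (nested richness loss - the Shannon/Chao1 channel) and
  # mildly sharpens the dominance hierarchy of the remainder (the Simpson
  # channel), so the alpha-diversity indices covary as in real data while
  # the taxa that are present stay well-sampled.
  h_grid <- stats::qnorm((seq_along(ids) - 0.5) / length(ids))
  h <- withr::with_seed(seed_for(config$seed, "heterogeneity"), sample(h_grid))
  mu <- 0.1 * pmax(h + 0.5, 0)
  n_resp <- config$n_stress_factors * config$responders_per_factor
  # responder taxa are drawn at random so the shared environmental response
  # is unrelated to phylogeny (tip order follows the tree's clades)
  responder_idx <- withr::with_seed(seed_for(config$seed, "responders"),
                                    sample.int(config$n_asvs, n_resp))
  responder_sets <- split(responder_idx,
                          rep(seq_len(config$n_stress_factors),
                              each = config$responders_per_factor))
  treatments <- config$treatments
  tables <- vector("list", nrow(treatments))
  metas <- vector("list", nrow(treatments))
  correlations <- vector("list", nrow(treatments))
  for (i in seq_len(nrow(treatments))) {
    tr <- treatments[i, ]
    corr <- build_target_correlation(sim$distances, tr, config)
    correlations[[i]] <- corr
    mu_t <- (1 - tr$diversity) * config$mu_scale * mu
    mu_t[responder_idx] <- mu_t[responder_idx] + config$responder_bonus
    # nested absence: a treatment at diversity e is missing the lowest
    # 0.5*(1-e) quantile of taxa (responders always persist); absent taxa
    # are constant zero, carry no rank information, and drop out of that
    # treatment's pair set
    absent <- h < stats::qnorm(0.5 * (1 - tr$diversity))
    absent[responder_idx] <- FALSE
    mu_t[absent] <- -30
    stress_sd <- config$stress_scale * sqrt(max(treatment_shift(tr, config), 0))
    tbl <- simulate_counts(corr, tr$n_samples, config, mu = mu_t,
                           seed = seed_for(config$seed, paste0("counts_", tr$treatment_id)),
                           stress_sd = stress_sd, responder_sets = responder_sets)
    tbl$sample_id <- paste(tr$treatment_id, tbl$sample_id, sep = "_")
    tables[[i]] <- tbl
    metas[[i]] <- tibble::tibble(
      sample_id = tbl$sample_id,
      treatment_id = tr$treatment_id,
      experiment_id = paste0("Exp_", tr$treatment_id),
      diet = tr$diet, contact = tr$contact, n_voles = tr$n_voles
    )
  }
  abundance <- dplyr::bind_rows(tables)
  metadata <- dplyr::bind_rows(metas)
  names(correlations) <- treatments$treatment_id
  truth <- list(
    tree = sim$tree,
    distances = sim$distances,
    target_correlations = correlations,
    effect_signs = c(
      gd = -sign(config$beta_gd),
      shannon = sign(config$beta_shannon),
      n_voles = sign(config$beta_n),
      diet_grass = sign(config$beta_diet),
      contact_yes = sign(config$beta_contact)
    ),
    effect_sizes = c(
      gd = config$beta_gd, shannon = config$beta_shannon,
      n_voles = config$beta_n, diet = config$beta_diet,
      contact = config$beta_contact
    )
  )
  out <- list(abundance = abundance, metadata = metadata, seqs = sim$seqs,
              truth = truth, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      abundance = file.path(dir, "abundance.tsv"),
      metadata = file.path(dir, "metadata.tsv"),
      fasta = file.path(dir, "sequences.fasta")
    )
    write_abundance(abundance, paths$abundance)
    readr::write_tsv(metadata, paths$metadata, progress = FALSE)
    write_aligned_fasta(sim$seqs, paths$fasta)
    out$paths <- paths
  }
  out
}
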