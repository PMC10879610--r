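test_that("zero substitution rate gives identical sequences and zero distances", {
  cfg <- tiny_config()
  cfg$subst_rate <- 0
  sim <- simulate_tree_and_seqs(cfg)
  expect_equal(length(unique(sim$seqs)), 1L)
  expect_true(all(sim$distances == 0))
  expect_equal(ape::Ntip(sim$tree), cfg$n_asvs)
})

test_that("sequence simulation is deterministic and distances are valid", {
  cfg <- tiny_config(seed = 5)
  s1 <- simulate_tree_and_seqs(cfg)
  s2 <- simulate_tree_and_seqs(cfg)
  expect_identical(s1$seqs, s2$seqs)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_true(all(s1$distances >= 0 & s1$distances <= 1))
  expect_equal(s1$distances, t(s1$distances))
})

test_that("long branches saturate towards the JC expectation of 0.75", {
  cfg <- synth_config(n_asvs = 2, seq_length = 2000, subst_rate = 40,
                      n_stress_factors = 1, responders_per_factor = 1,
                      treatments = tiny_config()$treatments, seed = 3)
  sim <- simulate_tree_and_seqs(cfg)
  p <- sim$distances[1, 2]
  # Monte-Carlo-level tolerance: sd of mean mismatch at 2000 sites
  expect_lt(abs(p - 0.75), 4 * sqrt(0.75 * 0.25 / 2000) + 0.02)
})

test_that("target correlation follows the covariate formula before repair", {
  cfg <- tiny_config()
  sim <- simulate_tree_and_seqs(cfg)
  # with all effects zero and baseline zero the matrix is the identity
  cfg0 <- cfg
  cfg0$baseline_cor <- 0; cfg0$beta_gd <- 0; cfg0$beta_shannon <- 0
  cfg0$beta_n <- 0; cfg0$beta_diet <- 0; cfg0$beta_contact <- 0
  corr0 <- build_target_correlation(sim$distances, cfg0$treatments[1, ], cfg0)
  expect_equal(corr0, diag(nrow(sim$distances)), ignore_attr = TRUE)

  # a positive beta_gd makes the (pre-repair) target decrease with distance
  corr <- build_target_correlation(sim$distances, cfg$treatments[1, ], cfg)
  idx <- which(upper.tri(corr), arr.ind = TRUE)
  ord <- order(sim$distances[idx])
  rho_by_dist <- corr[idx][ord]
  expect_lt(cor(seq_along(rho_by_dist), rho_by_dist, method = "spearman"), 0)

  # repaired matrix is positive semi-definite with unit diagonal
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  expect_equal(unname(diag(corr)), rep(1, nrow(corr)))
})

test_that("simulated counts respect depth and the latent correlation", {
  cfg <- tiny_config()
  ids <- c("A", "B", "C")
  corr <- diag(3); dimnames(corr) <- list(ids, ids)
  cnt <- simulate_counts(corr, 50, cfg, seed = 8)
  m <- as.matrix(cnt[-1])
  expect_true(all(rowSums(m) == cfg$depth))
  expect_equal(dim(m), c(50L, 3L))

  # depth 1: every sample is a single read
  cfg1 <- cfg; cfg1$depth <- 1
  one <- as.matrix(simulate_counts(corr, 30, cfg1, seed = 8)[-1])
  expect_true(all(rowSums(one) == 1))

  # a strongly correlated pair, embedded in a larger community so that
  # compositional closure stays weak, shows strong rank correlation
  k <- 10
  corr2 <- diag(k)
  corr2[1, 2] <- corr2[2, 1] <- 0.95
  dimnames(corr2) <- list(LETTERS[1:k], LETTERS[1:k])
  cfg2 <- cfg; cfg2$depth <- 10000
  big <- as.matrix(simulate_counts(corr2, 200, cfg2, seed = 9)[-1])
  expect_gt(cor(big[, 1], big[, 2], method = "spearman"), 0.6)

  # identity correlation: observed correlations sit near the closure
  # expectation of -1/(k-1), i.e. near zero for a community of 30
  corr3 <- diag(30)
  dimnames(corr3) <- list(sprintf("t%02d", 1:30), sprintf("t%02d", 1:30))
  cfg3 <- cfg; cfg3$depth <- 20000
  z <- as.matrix(simulate_counts(corr3, 800, cfg3, seed = 10)[-1])
  R <- cor(apply(z, 2, rank))
  expect_lt(max(abs(R[upper.tri(R)])), 0.15)
  expect_lt(abs(mean(R[upper.tri(R)]) + 1 / 29), 0.02)
})

test_that("generate_study writes byte-identical bundles under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- write_tiny_study(d1, seed = 21)
  s2 <- write_tiny_study(d2, seed = 21)
  for (f in c("abundance.tsv", "metadata.tsv", "sequences.fasta")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  s3 <- generate_study(tiny_config(seed = 22))
  expect_false(identical(s1$abundance, s3$abundance))
})

test_that("generated bundles pass joint validation and carry the truth", {
  dir <- withr::local_tempdir()
  study <- write_tiny_study(dir)
  abundance <- read_abundance(study$paths$abundance)
  metadata <- read_metadata(study$paths$metadata)
  seqs <- read_aligned_fasta(study$paths$fasta)
  info <- validate_inputs(abundance, metadata, seqs)
  expect_equal(info$n_samples, nrow(study$abundance))

  expect_equal(unname(study$truth$effect_signs),
               c(-1, 1, -1, 1, -1))
  expect_equal(names(study$truth$target_correlations),
               tiny_config()$treatments$treatment_id)
  # every per-treatment target is a valid correlation matrix
  for (corr in study$truth$target_correlations) {
    expect_gte(min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("diversity levels shape realised alpha diversity", {
  study <- generate_study(tiny_config(seed = 31, n_samples = 12L))
  div <- treatment_diversity_table(study$abundance, study$metadata)
  cfg <- tiny_config()
  e <- cfg$treatments$diversity[match(div$treatment_id, cfg$treatments$treatment_id)]
  expect_gt(cor(e, div$shannon), 0)
  # the most and least diverse treatments are ordered correctly
  expect_gt(div$shannon[which.max(e)], div$shannon[which.min(e)])
})
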