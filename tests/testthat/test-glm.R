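test_that("min-max normalisation maps onto [0,1] and rejects constants", {
  expect_equal(minmax(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax(c(0, 0.3, 1)), c(0, 0.3, 1))
  expect_error(minmax(c(5, 5, 5)), "constant")
  set.seed(3)
  x <- rnorm(50)
  expect_true(all(minmax(x) >= 0 & minmax(x) <= 1))
})

test_that("collinearity screen keeps one variable per linked component", {
  set.seed(21)
  shannon <- rnorm(200)
  simpson <- shannon + rnorm(200, sd = 0.3)      # strongly linked
  n_voles <- rnorm(200)                          # independent
  res <- collinearity_screen(data.frame(shannon, simpson, n_voles))
  expect_setequal(res$retained, c("shannon", "n_voles"))
  expect_equal(res$dropped, "simpson")

  # transitive closure: a-b and b-c linked, a-c not -> single component
  a <- rnorm(300); b <- a + rnorm(300, sd = 0.6); c <- b + rnorm(300, sd = 0.6)
  res2 <- collinearity_screen(data.frame(a, b, c), keep_priority = "b")
  if (abs(cor(a, c, method = "spearman")) <= 0.5) {
    expect_equal(res2$retained, "b")
  }

  # below threshold nothing is dropped
  res3 <- collinearity_screen(data.frame(x = rnorm(100), y = rnorm(100)))
  expect_equal(length(res3$retained), 2L)
  expect_equal(nrow(res3$cor_table), 1L)
})

test_that("per-experiment linear fits recover exact and null relations", {
  gd <- runif(50)
  exact <- tibble::tibble(rho = 1 - gd, gd = gd, experiment_id = "E1")
  fit <- fit_lm(exact)
  expect_equal(fit$slope, -1, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r, -1, tolerance = 1e-10)

  set.seed(99)
  null <- tibble::tibble(rho = rnorm(10000), gd = runif(10000), experiment_id = "E2")
  nf <- fit_lm(null)
  se <- summary(lm(rho ~ gd, data = null))$coefficients["gd", "Std. Error"]
  expect_lt(abs(nf$slope), 3 * se)

  # 2 pairs or constant gd -> skipped with warning
  small <- tibble::tibble(rho = c(1, 2), gd = c(0.1, 0.2), experiment_id = "E3")
  expect_warning(out <- fit_lm(dplyr::bind_rows(exact, small)), "skipped")
  expect_false("E3" %in% out$experiment_id)
})

test_that("Gaussian GLM recovers exact coefficients and flags aliasing", {
  set.seed(4)
  n <- 400
  design <- tibble::tibble(
    gd = runif(n), shannon = runif(n),
    diet_grass = rbinom(n, 1, 0.5), contact_yes = rbinom(n, 1, 0.5)
  )
  design$rho <- 0.5 - 0.06 * design$gd + 0.03 * design$shannon +
    0.02 * design$diet_grass - 0.01 * design$contact_yes
  attr(design, "terms") <- setdiff(names(design), "rho")
  fit <- fit_glm(design)
  est <- tidy(fit)
  expect_equal(est$estimate[est$term == "gd"], -0.06, tolerance = 1e-8)
  expect_equal(est$estimate[est$term == "(Intercept)"], 0.5, tolerance = 1e-8)
  expect_equal(glance(fit)$n, n)

  dup <- design
  dup$gd2 <- dup$gd
  attr(dup, "terms") <- setdiff(names(dup), "rho")
  expect_error(fit_glm(dup), "aliased.*gd2")
})

test_that("GLM estimates recover simulated effects within 3 SE", {
  set.seed(14)
  n <- 5000
  design <- tibble::tibble(gd = runif(n))
  design$rho <- 0.5 - 0.06 * design$gd + rnorm(n, sd = 0.01)
  attr(design, "terms") <- "gd"
  est <- tidy(fit_glm(design))
  gd_row <- est[est$term == "gd", ]
  expect_lt(abs(gd_row$estimate - (-0.06)), 3 * gd_row$std_error)
  expect_lt(gd_row$estimate, 0)
})

test_that("normalised and raw designs give identical predictions", {
  set.seed(6)
  n <- 300
  raw <- tibble::tibble(gd = runif(n, 0.1, 0.6), shannon = runif(n, 2, 4))
  raw$rho <- 0.4 - 0.3 * raw$gd + 0.1 * raw$shannon + rnorm(n, sd = 0.05)
  norm <- raw
  norm$gd <- minmax(raw$gd); norm$shannon <- minmax(raw$shannon)
  attr(raw, "terms") <- attr(norm, "terms") <- c("gd", "shannon")
  f1 <- fit_glm(raw); f2 <- fit_glm(norm)
  expect_equal(unname(fitted(f1$fit)), unname(fitted(f2$fit)), tolerance = 1e-8)
})

test_that("AIC selection prefers true terms over noise and records a trace", {
  set.seed(23)
  hits <- 0
  for (i in 1:60) {
    n <- 150
    design <- tibble::tibble(signal = runif(n), noise = runif(n))
    design$rho <- 0.2 + 0.5 * design$signal + rnorm(n, sd = 0.1)
    attr(design, "terms") <- c("signal", "noise")
    best <- select_model(design)
    expect_true("signal" %in% best$terms)
    if (!"noise" %in% best$terms) hits <- hits + 1
  }
  expect_gte(hits / 60, 0.6)

  # intercept-only wins on pure noise (on average); trace covers all subsets
  design <- tibble::tibble(x = runif(100))
  design$rho <- rnorm(100)
  attr(design, "terms") <- "x"
  best <- select_model(design)
  expect_equal(nrow(best$trace), 2L)
  expect_equal(best$trace$delta_aic[1], 0)
})

test_that("intercept-only model wins most pure-noise simulations", {
  set.seed(31)
  wins <- 0
  for (i in 1:40) {
    design <- tibble::tibble(x = runif(120), z = runif(120))
    design$rho <- rnorm(120)
    attr(design, "terms") <- c("x", "z")
    if (length(select_model(design)$terms) == 0) wins <- wins + 1
  }
  expect_gte(wins / 40, 0.5)
})

test_that("subsample robustness is deterministic and sign-stable on strong signals", {
  set.seed(41)
  n <- 3000
  design <- tibble::tibble(gd = runif(n))
  design$rho <- 0.5 - 0.3 * design$gd + rnorm(n, sd = 0.05)
  attr(design, "terms") <- "gd"
  r1 <- subsample_robustness(design, frac = 0.05, reps = 10, seed = 7)
  r2 <- subsample_robustness(design, frac = 0.05, reps = 10, seed = 7)
  expect_identical(r1, r2)
  expect_equal(r1$summary$sign_agreement[r1$summary$term == "gd"], 1)
  expect_equal(nrow(r1$estimates), 10 * 2)

  single <- subsample_robustness(design, frac = 0.05, reps = 1, seed = 7)
  expect_equal(unique(single$estimates$rep), 1L)

  expect_error(subsample_robustness(design, frac = 0.001, reps = 2, seed = 1),
               "increase frac")
})

test_that("design builder normalises, screens, and encodes reference levels", {
  study <- write_tiny_study(withr::local_tempdir())
  rel <- to_relative(study$abundance)
  dist <- distance_matrix(study$seqs)
  pairs <- suppressWarnings(pair_table(rel, study$metadata, dist))
  div <- treatment_diversity_table(study$abundance, study$metadata)
  design <- suppressWarnings(build_glm_design(pairs, study$metadata, div))

  expect_true(all(design$rho >= 0 & design$rho <= 1))
  expect_true(all(design$gd >= 0 & design$gd <= 1))
  expect_true(all(design$diet_grass %in% c(0, 1)))
  expect_true(all(design$contact_yes %in% c(0, 1)))
  expect_true(all(attr(design, "terms") %in% names(design)))
  # grass rows carry the indicator, chow is the reference
  grass_groups <- unique(study$metadata$treatment_id[study$metadata$diet == "grass"])
  expect_true(all(design$diet_grass[pairs$group_id %in% grass_groups] == 1))

  sig <- suppressWarnings(build_glm_design(pairs, study$metadata, div,
                                           pairs_filter = "significant",
                                           fdr_alpha = 0.5))
  expect_lte(nrow(sig), nrow(design))
})
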