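test_that("prevalence filter applies a strict boundary at min_nonzero", {
  m <- matrix(0, nrow = 21, ncol = 3)
  m[1:19, 1] <- 1   # present in 19 samples -> removed at threshold 20
  m[1:20, 2] <- 1   # present in 20 -> kept
  m[, 3] <- 1
  tbl <- make_counts(m)
  out <- prevalence_filter(tbl, min_nonzero = 20)
  expect_equal(asv_ids(out), c("ASV_002", "ASV_003"))
  expect_equal(prevalence_filter(tbl, min_nonzero = 0), tbl)
})

test_that("depth normalisation yields unit sample sums and drops empty samples", {
  tbl <- make_counts(rbind(c(2, 2), c(1, 3), c(0, 0)))
  expect_warning(out <- column_normalize(tbl), "all-zero")
  m <- as.matrix(out[-1])
  expect_equal(nrow(m), 2L)
  expect_equal(unname(rowSums(m)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(m[1, ]), c(0.5, 0.5))
  expect_equal(unname(m[2, ]), c(0.25, 0.75))
})

test_that("bootstrap keeps perfectly monotone pairs and none at alpha = 0", {
  set.seed(2)
  base <- sort(runif(12))
  tbl <- make_counts(cbind(base, base * 2, rev(base), runif(12)))
  rel <- column_normalize(tbl)
  boot <- bootstrap_edges(rel, n_boot = 50, seed = 9)
  mono <- boot[boot$asv_a == "ASV_001" & boot$asv_b == "ASV_002", ]
  expect_equal(mono$p_boot, 0)
  expect_true(mono$keep)
  anti <- boot[boot$asv_a == "ASV_001" & boot$asv_b == "ASV_003", ]
  expect_equal(anti$p_boot, 0)

  none <- bootstrap_edges(rel, n_boot = 50, seed = 9, alpha = 0)
  expect_false(any(none$keep & none$p_boot > 0))
  expect_error(bootstrap_edges(rel[1:4, ], n_boot = 10), "at least 5")
})

test_that("bootstrap is bit-reproducible under a fixed seed", {
  study <- write_tiny_study(withr::local_tempdir())
  rel <- column_normalize(study$abundance)
  b1 <- bootstrap_edges(rel, n_boot = 40, seed = 123)
  b2 <- bootstrap_edges(rel, n_boot = 40, seed = 123)
  expect_identical(b1, b2)
  b3 <- bootstrap_edges(rel, n_boot = 40, seed = 124)
  expect_false(identical(b1$p_boot, b3$p_boot))

  # alpha = 1 keeps every candidate pair
  all_in <- bootstrap_edges(rel, n_boot = 20, seed = 1, alpha = 1)
  expect_true(all(all_in$keep[!is.na(all_in$p_boot)]))
})

test_that("node metrics match hand-enumerated path and triangle graphs", {
  mk_net <- function(edges_df, ids) {
    structure(list(
      nodes = tibble::tibble(asv_id = ids, phylum = "Unassigned"),
      edges = edges_df, params = list()
    ), class = "cooc_network")
  }
  # path a - b - c
  path <- mk_net(tibble::tibble(asv_a = c("a", "b"), asv_b = c("b", "c"),
                                rho = c(0.5, -0.5), p_boot = 0,
                                sign = c("+", "-")), c("a", "b", "c"))
  path <- node_metrics(path)
  expect_equal(path$nodes$degree, c(1, 2, 1))
  expect_equal(path$nodes$pos_degree, c(1, 1, 0))
  expect_equal(path$nodes$neg_degree, c(0, 1, 1))
  expect_equal(path$nodes$betweenness, c(0, 1, 0))

  # triangle: no betweenness anywhere
  tri <- mk_net(tibble::tibble(asv_a = c("a", "a", "b"), asv_b = c("b", "c", "c"),
                               rho = 1, p_boot = 0, sign = "+"), c("a", "b", "c"))
  tri <- node_metrics(tri)
  expect_equal(tri$nodes$betweenness, c(0, 0, 0))
  expect_equal(tri$nodes$degree, c(2, 2, 2))

  # isolated node stays at zero
  iso <- mk_net(tibble::tibble(asv_a = "a", asv_b = "b", rho = 1,
                               p_boot = 0, sign = "+"), c("a", "b", "z"))
  iso <- node_metrics(iso)
  expect_equal(iso$nodes$degree[iso$nodes$asv_id == "z"], 0)
  expect_equal(iso$nodes$betweenness[iso$nodes$asv_id == "z"], 0)
})

test_that("degree invariants hold on bootstrap-built networks", {
  study <- write_tiny_study(withr::local_tempdir())
  net <- build_network(study$abundance, min_nonzero = 5, n_boot = 40, seed = 5)
  expect_equal(sum(net$nodes$degree), 2 * nrow(net$edges))
  expect_equal(net$nodes$pos_degree + net$nodes$neg_degree, net$nodes$degree)
  expect_equal(sum(net$nodes$pos_degree), 2 * sum(net$edges$sign == "+"))
  expect_equal(sum(net$nodes$neg_degree), 2 * sum(net$edges$sign == "-"))
  expect_false(any(net$edges$asv_a == net$edges$asv_b))
  expect_false(any(duplicated(net$edges[c("asv_a", "asv_b")])))
})

test_that("hub criteria use strict inequalities on degree and betweenness", {
  net <- structure(list(
    nodes = tibble::tibble(
      asv_id = c("a", "b", "c"),
      degree = c(3, 2, 5),
      betweenness = c(0.15, 0.5, 0.1)
    ),
    edges = tibble::tibble(asv_a = character(200), asv_b = character(200))
  ), class = "cooc_network")
  # 200 edges -> degree cut 2: a (3 > 2, btw .15 > .1) is a hub;
  # b fails degree (2 !> 2); c fails betweenness (0.1 !> 0.1)
  expect_equal(hub_nodes(net), "a")
})

test_that("taxon degree table groups unassigned nodes and conserves counts", {
  study <- write_tiny_study(withr::local_tempdir())
  tax <- tibble::tibble(
    asv_id = names(study$seqs)[1:6],
    phylum = c("Firmicutes", "Firmicutes", "Bacteroidota", "", "Bacteroidota", "Firmicutes")
  )
  net <- build_network(study$abundance, taxonomy = tax, min_nonzero = 5,
                       n_boot = 30, seed = 5)
  tab <- degree_by_taxon(net, tax)
  expect_equal(nrow(tab), nrow(net$nodes))
  expect_true(all(c("Firmicutes", "Bacteroidota", "Unassigned") %in% tab$taxon))
  expect_equal(sum(tab$degree), sum(net$nodes$degree))
})

test_that("planted correlated block is enriched over independent noise", {
  # 6 strongly coupled ASVs + 14 independent ones
  set.seed(77)
  n <- 40
  common <- rnorm(n)
  block <- sapply(1:6, function(i) common + rnorm(n, sd = 0.4))
  noise <- matrix(rnorm(n * 14), n)
  # the planted block is kept at low abundance so that the compositional
  # denominator is dominated by the independent taxa
  counts <- round(cbind(exp(block) * 10, exp(noise) * 200))
  tbl <- make_counts(counts)
  net <- build_network(tbl, min_nonzero = 5, n_boot = 100, seed = 31)
  inside <- net$edges$asv_a %in% sprintf("ASV_%03d", 1:6) &
    net$edges$asv_b %in% sprintf("ASV_%03d", 1:6)
  rate_in <- sum(inside) / choose(6, 2)
  rate_out <- max(sum(!inside), 0.5) / (choose(20, 2) - choose(6, 2))
  expect_gte(rate_in / rate_out, 10)
})

test_that("network accessors summarise edges and sizes", {
  study <- write_tiny_study(withr::local_tempdir())
  net <- build_network(study$abundance, min_nonzero = 5, n_boot = 30, seed = 5)
  gl <- glance(net)
  expect_equal(gl$n_edges, nrow(net$edges))
  expect_equal(gl$n_positive + gl$n_negative, gl$n_edges)
  expect_equal(nrow(tidy(net)), nrow(net$edges))
  expect_output(print(net), "cooc_network")
})
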