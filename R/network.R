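#' Prevalence filter for network candidates
#'
#' Removes ASVs with a non-zero count in fewer than `min_nonzero` samples
#' (strict `<`; the default 20 suppresses sparse taxa whose correlations
#' are driven by zeros).
#'
#' @param table Wide abundance tibble.
#' @param min_nonzero Minimum number of samples with a non-zero count.
#' @return The filtered abundance tibble.
#' @export
prevalence_filter <- function(table, min_nonzero = 20) {
  check_abundance(table)
  m <- as_count_matrix(table)
  keep <- colSums(m > 0) >= min_nonzero
  count_matrix_to_tibble(m[, keep, drop = FALSE])
}

#' Depth normalisation before network inference
#'
#' Divides each entry by the total of its sample so that every sample sums
#' to 1, removing sequencing-depth differences that would otherwise induce
#' spurious associations. All-zero samples are dropped with a warning.
#'
#' @param table Wide abundance tibble.
#' @return A tibble of proportions; each retained sample sums to 1.
#' @export
column_normalize <- function(table) {
  check_abundance(table)
  m <- as_count_matrix(table)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    warn(sprintf("dropping %d all-zero sample(s): %s", sum(totals == 0),
                 paste(head(rownames(m)[totals == 0], 5), collapse = ", ")))
    m <- m[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  count_matrix_to_tibble(m / totals)
}

#' Bootstrap edge significance
#'
#' For every candidate ASV pair, the observed Spearman rho on the full
#' data is tested by resampling samples with replacement `n_boot` times
#' and recomputing rho. The two-sided p-value is the sign-crossing
#' fraction `2 * min(#{rho_b <= 0}, #{rho_b >= 0}) / n_valid`, capped at 1;
#' resamples in which a member of the pair is constant contribute nothing
#' (they are excluded from the denominator and counted in `n_null`).
#' Edges with `p_boot <= alpha` are flagged `keep`.
#'
#' @param rel Depth-normalised abundance tibble (see [column_normalize()]).
#' @param n_boot Number of bootstrap resamples (default 100).
#' @param alpha Retention threshold on `p_boot` (default 0.05).
#' @param seed Integer seed; results are bit-reproducible given the seed.
#' @param rho_threshold Optional pre-filter: only pairs with observed
#'   `|rho| >= rho_threshold` are tested (default 0, i.e. all pairs).
#' @return Tibble with columns `asv_a`, `asv_b`, `rho`, `p_boot`,
#'   `n_valid`, `n_null`, `keep`.
#' @export
bootstrap_edges <- function(rel, n_boot = 100, alpha = 0.05, seed = 1L,
                            rho_threshold = 0) {
  check_abundance(rel)
  m <- as_count_matrix(rel)
  n <- nrow(m)
  if (n < 5) abort("need at least 5 samples for bootstrap edge testing")
  if (n_boot < 1) abort("n_boot must be positive")

  obs <- suppressWarnings(cor(m, method = "spearman"))
  idx <- which(upper.tri(obs), arr.ind = TRUE)
  rho <- obs[idx]
  candidate <- !is.na(rho) & abs(rho) >= rho_threshold
  idx <- idx[candidate, , drop = FALSE]
  rho <- rho[candidate]

  n_pos <- numeric(length(rho))
  n_neg <- numeric(length(rho))
  n_valid <- numeric(length(rho))
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_boot)) {
      rows <- sample.int(n, n, replace = TRUE)
      Rb <- suppressWarnings(cor(m[rows, , drop = FALSE], method = "spearman"))
      rb <- Rb[idx]
      ok <- !is.na(rb)
      n_valid <- n_valid + ok
      n_pos <- n_pos + (ok & rb >= 0)
      n_neg <- n_neg + (ok & rb <= 0)
    }
  })
  p_boot <- ifelse(n_valid > 0, pmin(1, 2 * pmin(n_pos, n_neg) / n_valid), NA_real_)
  a <- colnames(m)[idx[, 1]]
  b <- colnames(m)[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  tibble::tibble(
    asv_a = a, asv_b = b, rho = rho, p_boot = p_boot,
    n_valid = n_valid, n_null = n_boot - n_valid,
    keep = !is.na(p_boot) & p_boot <= alpha
  ) |> dplyr::arrange(.data$asv_a, .data$asv_b)
}

#' Build a co-occurrence network
#'
#' Runs the network stage end to end: prevalence filter, depth
#' normalisation, bootstrap edge significance, node metrics, and hub
#' flags. Nodes are all ASVs passing the prevalence filter (isolated nodes
#' keep degree 0); edges are pairs whose bootstrap p-value passes `alpha`
#' (optionally after a Benjamini-Hochberg adjustment over all candidate
#' pairs with `network_fdr = TRUE`), signed by the sign of rho.
#'
#' @param table Wide abundance tibble of counts.
#' @param taxonomy Optional taxonomy tibble (`asv_id`, `phylum`, ...).
#' @param min_nonzero Prevalence threshold (default 20).
#' @param n_boot,alpha,seed,rho_threshold Passed to [bootstrap_edges()].
#' @param network_fdr Apply BH adjustment to bootstrap p-values before the
#'   `alpha` cut (default `FALSE`).
#' @param hub_degree_frac,hub_betweenness Hub criteria, see [hub_nodes()].
#' @return A `cooc_network` object: a list with tibbles `nodes` and
#'   `edges` plus the filtering parameters.
#' @export
build_network <- function(table, taxonomy = NULL, min_nonzero = 20,
                          n_boot = 100, alpha = 0.05, seed = 1L,
                          rho_threshold = 0, network_fdr = FALSE,
                          hub_degree_frac = 0.01, hub_betweenness = 0.1) {
  filtered <- prevalence_filter(table, min_nonzero = min_nonzero)
  if (length(asv_ids(filtered)) < 2) abort("fewer than 2 ASVs pass the prevalence filter")
  rel <- column_normalize(filtered)
  boot <- bootstrap_edges(rel, n_boot = n_boot, alpha = alpha, seed = seed,
                          rho_threshold = rho_threshold)
  if (network_fdr) {
    boot$fdr <- fdr_adjust(boot$p_boot)
    boot$keep <- !is.na(boot$fdr) & boot$fdr <= alpha
  }
  edges <- boot[boot$keep, , drop = FALSE]
  edges$sign <- ifelse(edges$rho >= 0, "+", "-")
  nodes <- tibble::tibble(asv_id = asv_ids(filtered))
  if (!is.null(taxonomy)) {
    phyla <- taxonomy$phylum[match(nodes$asv_id, taxonomy$asv_id)]
    nodes$phylum <- ifelse(is.na(phyla) | phyla == "", "Unassigned", phyla)
  } else {
    nodes$phylum <- "Unassigned"
  }
  net <- structure(
    list(nodes = nodes, edges = edges,
         params = list(min_nonzero = min_nonzero, n_boot = n_boot,
                       alpha = alpha, seed = seed, network_fdr = network_fdr)),
    class = "cooc_network"
  )
  net <- node_metrics(net)
  hubs <- hub_nodes(net, degree_frac = hub_degree_frac,
                    min_betweenness = hub_betweenness)
  net$nodes$is_hub <- net$nodes$asv_id %in% hubs
  net
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("<cooc_network> %d nodes, %d edges (%d positive, %d negative), %d hub(s)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "+"), sum(x$edges$sign == "-"),
              sum(x$nodes$is_hub %||% FALSE)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_igraph <- function(network) {
  vertices <- as.data.frame(network$nodes)
  names(vertices)[1] <- "name"
  edges <- network$edges
  el <- data.frame(from = edges$asv_a, to = edges$asv_b,
                   weight = edges$rho, p = edges$p_boot, sign = edges$sign)
  igraph::graph_from_data_frame(el, directed = FALSE, vertices = vertices)
}

#' Node metrics: degree splits and betweenness
#'
#' Computes per-node degree, positive and negative degree (split by edge
#' sign), and normalised shortest-path betweenness on the unweighted
#' undirected graph. Isolated nodes score 0 throughout.
#'
#' @param network A `cooc_network` object.
#' @return The network with columns `degree`, `pos_degree`, `neg_degree`,
#'   `betweenness` added to (or refreshed in) `nodes`.
#' @export
node_metrics <- function(network) {
  stopifnot(inherits(network, "cooc_network"))
  nodes <- network$nodes
  edges <- network$edges
  ids <- nodes$asv_id
  deg_of <- function(which_edges) {
    tab <- table(factor(c(which_edges$asv_a, which_edges$asv_b), levels = ids))
    as.numeric(tab)
  }
  nodes$degree <- deg_of(edges)
  nodes$pos_degree <- deg_of(edges[edges$sign == "+", , drop = FALSE])
  nodes$neg_degree <- deg_of(edges[edges$sign == "-", , drop = FALSE])
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges$asv_a, to = edges$asv_b),
      directed = FALSE,
      vertices = data.frame(name = ids)
    )
    btw <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
    nodes$betweenness <- as.numeric(btw[ids])
  } else {
    nodes$betweenness <- 0
  }
  network$nodes <- nodes
  network
}

#' Hub nodes
#'
#' A node is a hub when its degree strictly exceeds `degree_frac` of the
#' total number of edges *and* its normalised betweenness strictly exceeds
#' `min_betweenness`. "1% of total volume" is read as 1% of the edge
#' count.
#'
#' @param network A `cooc_network` with metrics computed.
#' @param degree_frac Fraction of total edges (default 0.01).
#' @param min_betweenness Betweenness threshold (default 0.1).
#' @return Character vector of hub ASV ids.
#' @export
hub_nodes <- function(network, degree_frac = 0.01, min_betweenness = 0.1) {
  stopifnot(inherits(network, "cooc_network"))
  nodes <- network$nodes
  if (!"degree" %in% names(nodes)) abort("run node_metrics() first")
  cut <- degree_frac * nrow(network$edges)
  nodes$asv_id[nodes$degree > cut & nodes$betweenness > min_betweenness]
}

#' Degree distributions by taxon
#'
#' @param network A `cooc_network` with metrics computed.
#' @param taxonomy Taxonomy tibble (`asv_id` + rank columns); nodes
#'   without an assignment are grouped as `"Unassigned"`.
#' @param rank Taxonomic rank to group by (default `"phylum"`).
#' @return Tibble `(taxon, asv_id, degree, pos_degree, neg_degree)`.
#' @export
degree_by_taxon <- function(network, taxonomy = NULL, rank = "phylum") {
  stopifnot(inherits(network, "cooc_network"))
  nodes <- network$nodes
  if (!"degree" %in% names(nodes)) abort("run node_metrics() first")
  taxon <- if (!is.null(taxonomy) && rank %in% names(taxonomy)) {
    tx <- taxonomy[[rank]][match(nodes$asv_id, taxonomy$asv_id)]
    ifelse(is.na(tx) | tx == "", "Unassigned", tx)
  } else if (rank == "phylum" && "phylum" %in% names(nodes)) {
    nodes$phylum
  } else {
    rep("Unassigned", nrow(nodes))
  }
  tibble::tibble(
    taxon = taxon, asv_id = nodes$asv_id,
    degree = nodes$degree, pos_degree = nodes$pos_degree,
    neg_degree = nodes$neg_degree
  ) |> dplyr::arrange(.data$taxon, .data$asv_id)
}

#' @method tidy cooc_network
#' @export
tidy.cooc_network <- function(x, ...) {
  tibble::as_tibble(x$edges)
}

#' @method glance cooc_network
#' @export
glance.cooc_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_connected = sum(x$nodes$degree > 0),
    n_edges = nrow(x$edges),
    n_positive = sum(x$edges$sign == "+"),
    n_negative = sum(x$edges$sign == "-"),
    n_hubs = sum(x$nodes$is_hub %||% FALSE)
  )
}
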