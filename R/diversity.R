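#' Alpha-diversity indices
#'
#' `shannon()` returns the Shannon entropy in nats, `simpson()` the
#' Gini-Simpson index `1 - sum(p^2)`, and `chao1()` the bias-corrected
#' Chao1 richness estimate `S_obs + F1*(F1-1) / (2*(F2+1))`, where `F1` and
#' `F2` are the numbers of singleton and doubleton ASVs.
#'
#' @param counts Non-negative numeric vector with at least one positive
#'   entry (integer counts for `chao1`).
#' @return A single numeric value.
#' @examples
#' shannon(c(5, 5, 5, 5))   # log(4)
#' simpson(c(1, 1, 1, 1))   # 0.75
#' chao1(c(1, 1))           # 3
#' @export
shannon <- function(counts) {
  check_counts(counts)
  as.numeric(vegan::diversity(counts, index = "shannon"))
}

#' @rdname shannon
#' @export
simpson <- function(counts) {
  check_counts(counts)
  as.numeric(vegan::diversity(counts, index = "simpson"))
}

#' @rdname shannon
#' @export
chao1 <- function(counts) {
  check_counts(counts)
  if (any(!is_whole(counts))) abort("chao1 requires integer counts")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

check_counts <- function(counts) {
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0)) {
    abort("counts must be finite and non-negative")
  }
  if (sum(counts) == 0) abort("all counts are zero; diversity is undefined")
  invisible(counts)
}

#' Per-sample diversity table
#'
#' @param table Wide abundance tibble.
#' @return Tibble with columns `sample_id`, `observed`, `shannon`,
#'   `simpson`, `chao1`.
#' @export
sample_diversity <- function(table) {
  check_abundance(table)
  m <- as_count_matrix(table)
  tibble::tibble(
    sample_id = rownames(m),
    observed = unname(apply(m, 1, function(x) sum(x > 0))),
    shannon = unname(apply(m, 1, shannon)),
    simpson = unname(apply(m, 1, simpson)),
    chao1 = unname(apply(m, 1, chao1))
  )
}

#' Treatment-level diversity
#'
#' Aggregates per-sample alpha diversity within treatment groups; the GLM
#' stage uses one diversity value per treatment. `agg = "pooled"` instead
#' computes the metric on the treatment's summed counts.
#'
#' @param table Wide abundance tibble.
#' @param metadata Sample metadata tibble (must cover every sample).
#' @param metric One of `"shannon"`, `"simpson"`, `"chao1"`, `"observed"`.
#' @param agg Aggregation: `"mean"` (default), `"median"`, or `"pooled"`.
#' @return Tibble with columns `treatment_id`, `n_samples`, `value`.
#' @export
treatment_diversity <- function(table, metadata,
                                metric = c("shannon", "simpson", "chao1", "observed"),
                                agg = c("mean", "median", "pooled")) {
  metric <- match.arg(metric)
  agg <- match.arg(agg)
  check_abundance(table)
  missing <- setdiff(table$sample_id, metadata$sample_id)
  if (length(missing) > 0) abort(sprintf("sample(s) without metadata: %s", paste(head(missing, 5), collapse = ", ")))
  metric_fun <- switch(metric,
    shannon = shannon, simpson = simpson, chao1 = chao1,
    observed = function(x) sum(x > 0)
  )
  m <- as_count_matrix(table)
  groups <- metadata$treatment_id[match(rownames(m), metadata$sample_id)]
  if (any(table(groups) == 0)) abort("empty treatment group")
  split_idx <- split(seq_len(nrow(m)), groups)
  purrr::map_dfr(names(split_idx), function(g) {
    rows <- split_idx[[g]]
    value <- if (agg == "pooled") {
      metric_fun(colSums(m[rows, , drop = FALSE]))
    } else {
      vals <- apply(m[rows, , drop = FALSE], 1, metric_fun)
      if (agg == "mean") mean(vals) else median(vals)
    }
    tibble::tibble(treatment_id = g, n_samples = length(rows), value = value)
  })
}

#' All four treatment-level diversity metrics in one table
#'
#' @inheritParams treatment_diversity
#' @return Tibble with columns `treatment_id`, `n_samples`, `observed`,
#'   `shannon`, `simpson`, `chao1`.
#' @export
treatment_diversity_table <- function(table, metadata, agg = c("mean", "median", "pooled")) {
  agg <- match.arg(agg)
  metrics <- c("observed", "shannon", "simpson", "chao1")
  out <- purrr::map(metrics, function(mt) {
    treatment_diversity(table, metadata, metric = mt, agg = agg) |>
      dplyr::rename(!!mt := "value")
  })
  purrr::reduce(out, dplyr::left_join, by = c("treatment_id", "n_samples"))
}
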