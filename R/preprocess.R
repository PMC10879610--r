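#' Rarefy samples to a common sequencing depth
#'
#' Randomly subsamples each sample's reads without replacement to a fixed
#' depth so that sequencing-depth differences do not bias downstream
#' correlations. Samples whose total is below `depth` are dropped with a
#' warning. Each sample draws from its own RNG stream derived from
#' `(seed, sample_id)`, so sample order never changes the result.
#'
#' @param table Wide abundance tibble (`sample_id` + ASV columns).
#' @param depth Target reads per sample (positive integer).
#' @param seed Integer root seed.
#' @return A rarefied abundance tibble; every retained sample sums to `depth`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  check_abundance(table)
  if (!is.numeric(depth) || length(depth) != 1 || depth <= 0 || !is_whole(depth)) {
    abort("depth must be a positive integer")
  }
  m <- as_count_matrix(table)
  totals <- rowSums(m)
  low <- totals < depth
  if (any(low)) {
    warn(sprintf("dropping %d sample(s) below depth %d: %s",
                 sum(low), as.integer(depth),
                 paste(head(rownames(m)[low], 5), collapse = ", ")))
    m <- m[!low, , drop = FALSE]
    totals <- totals[!low]
  }
  for (i in seq_len(nrow(m))) {
    if (totals[i] == depth) next
    row <- m[i, ]
    withr::with_seed(seed_for(seed, rownames(m)[i]), {
      # rrarefy warns about count magnitudes when handed a bare vector;
      # the subsample itself is the standard without-replacement draw
      m[i, ] <- suppressWarnings(as.numeric(vegan::rrarefy(row, depth)))
    })
  }
  count_matrix_to_tibble(m)
}

#' Remove ASVs below an overall relative-abundance threshold
#'
#' Drops ASVs whose pooled relative abundance (ASV total divided by the
#' grand total) is strictly below `min_rel_abund`; the default 1e-4 is the
#' usual 0.01% cut for suppressing error sequences and excess zeros.
#'
#' @param table Wide abundance tibble.
#' @param min_rel_abund Threshold in (0, 1); ASVs exactly at the threshold
#'   are retained.
#' @param mode `"pooled"` (default) compares each ASV's share of the grand
#'   total; `"per_sample_mean"` compares the mean of its per-sample
#'   relative abundances.
#' @return The filtered abundance tibble, ASV order preserved.
#' @export
filter_rare_asvs <- function(table, min_rel_abund = 1e-4,
                             mode = c("pooled", "per_sample_mean")) {
  mode <- match.arg(mode)
  check_abundance(table)
  if (!is.numeric(min_rel_abund) || min_rel_abund <= 0 || min_rel_abund >= 1) {
    abort("min_rel_abund must lie strictly between 0 and 1")
  }
  m <- as_count_matrix(table)
  rel <- switch(mode,
    pooled = colSums(m) / sum(m),
    per_sample_mean = {
      rows <- rowSums(m)
      rows[rows == 0] <- 1
      colMeans(m / rows)
    }
  )
  keep <- rel >= min_rel_abund
  count_matrix_to_tibble(m[, keep, drop = FALSE])
}

#' Remove singleton ASVs
#'
#' Drops ASVs whose total count across all samples is exactly 1.
#'
#' @param table Wide abundance tibble.
#' @return The filtered tibble (may have zero ASV columns).
#' @export
remove_singletons <- function(table) {
  check_abundance(table)
  m <- as_count_matrix(table)
  count_matrix_to_tibble(m[, colSums(m) != 1, drop = FALSE])
}

#' Convert counts to per-sample relative abundances
#'
#' Divides each sample's counts by its total; an all-zero sample maps to an
#' all-zero row.
#'
#' @param table Wide abundance tibble.
#' @return A tibble of the same shape with rows summing to 1 (or 0).
#' @export
to_relative <- function(table) {
  check_abundance(table)
  m <- as_count_matrix(table)
  totals <- rowSums(m)
  totals[totals == 0] <- 1
  count_matrix_to_tibble(m / totals)
}
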