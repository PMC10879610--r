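#' Spearman rank correlation with large-sample p-value
#'
#' The co-occurrence index between two ASVs: the Pearson correlation of
#' mid-ranks (ties receive average ranks). The two-sided p-value uses the
#' t approximation `t = rho * sqrt((n-2) / (1-rho^2))` on `n - 2` degrees
#' of freedom; `|rho| = 1` maps to `p = 0`. With `exact = TRUE` and
#' `n <= 8` an exact permutation p-value is computed instead.
#'
#' @param x,y Numeric vectors of equal length `>= 3`, neither constant.
#' @param exact Use the exact permutation null (only for `n <= 8`).
#' @return A list with elements `rho`, `p`, and `n`.
#' @export
spearman <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (length(y) != n) abort("x and y must have equal length")
  if (n < 3) abort("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) abort("constant vector: Spearman correlation undefined")
  rho <- cor(x, y, method = "spearman")
  if (exact) {
    if (n > 8) abort("exact permutation p-value only supported for n <= 8")
    perms <- permutations_of(n)
    rx <- rank(x)
    ry <- rank(y)
    null_rho <- apply(perms, 1, function(pp) cor(rx, ry[pp]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else {
    p <- spearman_p(rho, n)
  }
  list(rho = rho, p = p, n = n)
}

# Two-sided t-approximation p for a Spearman rho (vectorised).
spearman_p <- function(rho, n) {
  p <- rep(0, length(rho))
  inside <- abs(rho) < 1
  tval <- rho[inside] * sqrt((n - 2) / (1 - rho[inside]^2))
  p[inside] <- 2 * pt(-abs(tval), df = n - 2)
  p
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Zero filter for an ASV pair
#'
#' Excess zeros distort rank correlations, so pairs dominated by zeros are
#' removed before computing the co-occurrence index. In the default
#' `"pooled"` mode the zeros of both vectors are pooled: the pair is kept
#' iff `#zeros / (2n) <= max_zero_frac` (strictly more than the threshold
#' triggers removal). Mode `"either"` instead counts samples where either
#' value is zero against a denominator of `n`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param max_zero_frac Maximum tolerated zero fraction (default 0.5).
#' @param mode `"pooled"` or `"either"`.
#' @return `TRUE` to keep the pair, `FALSE` to drop it.
#' @export
zero_filter <- function(x, y, max_zero_frac = 0.5, mode = c("pooled", "either")) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  frac <- switch(mode,
    pooled = (sum(x == 0) + sum(y == 0)) / (2 * n),
    either = sum(x == 0 | y == 0) / n
  )
  frac <= max_zero_frac
}

#' Benjamini-Hochberg FDR adjustment
#'
#' `fdr_adjust()` implements the step-up procedure: raw quotients
#' `p * N / rank` (N = number of tests, rank = position in ascending order)
#' are made monotone by a cumulative minimum from the largest rank and
#' capped at 1; the output matches the input order. `fdr_quotient()`
#' returns the raw, uncorrected quotients (average ranks for ties) that
#' the step-up procedure starts from.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (or raw quotients) in input order.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  n <- length(p)
  desc <- order(p, decreasing = TRUE)
  back <- order(desc)
  pmin(1, cummin(n / seq(n, 1) * p[desc]))[back]
}

#' @rdname fdr_adjust
#' @export
fdr_quotient <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p * length(p) / rank(p, ties.method = "average")
}

#' Pairwise co-occurrence table
#'
#' For each treatment group (or experiment, with `scope = "experiment"`):
#' applies the pair zero filter, computes Spearman's correlation of
#' relative abundances for every surviving ASV pair, adjusts p-values by
#' Benjamini-Hochberg within the group's pair family, and joins the
#' pairwise genetic distance.
#'
#' Groups with fewer than `min_samples` samples are skipped with a
#' warning; pairs with a constant member are skipped; pairs whose ASVs are
#' missing from the distance matrix are dropped and counted in the
#' `"dropped_missing_gd"` attribute.
#'
#' @param rel Relative-abundance tibble (see [to_relative()]).
#' @param metadata Sample metadata tibble.
#' @param dist Symmetric genetic-distance matrix (or `NULL` to skip the
#'   distance join).
#' @param scope Grouping unit: `"treatment"` (default) or `"experiment"`.
#' @param max_zero_frac,zero_mode Passed to [zero_filter()].
#' @param min_samples Minimum group size (default 3).
#' @return Tibble with columns `asv_a`, `asv_b`, `group_id`,
#'   `experiment_id`, `n_samples`, `rho`, `p_raw`, `fdr_quotient`, `fdr`,
#'   `gd`.
#' @export
pair_table <- function(rel, metadata, dist = NULL,
                       scope = c("treatment", "experiment"),
                       max_zero_frac = 0.5, zero_mode = c("pooled", "either"),
                       min_samples = 3) {
  scope <- match.arg(scope)
  zero_mode <- match.arg(zero_mode)
  check_abundance(rel)
  missing <- setdiff(rel$sample_id, metadata$sample_id)
  if (length(missing) > 0) abort(sprintf("sample(s) without metadata: %s", paste(head(missing, 5), collapse = ", ")))

  m <- as_count_matrix(rel)
  if (!is.null(dist)) {
    in_dist <- colnames(m) %in% rownames(dist)
    n_missing_gd <- sum(!in_dist)
    m <- m[, in_dist, drop = FALSE]
  } else {
    n_missing_gd <- 0L
  }

  meta_idx <- match(rownames(m), metadata$sample_id)
  group_col <- if (scope == "treatment") "treatment_id" else "experiment_id"
  groups <- metadata[[group_col]][meta_idx]
  exp_of_sample <- metadata$experiment_id[meta_idx]

  split_rows <- split(seq_len(nrow(m)), groups)
  skipped <- character(0)
  out <- purrr::map(names(split_rows), function(g) {
    rows <- split_rows[[g]]
    n <- length(rows)
    if (n < min_samples) {
      skipped <<- c(skipped, g)
      return(NULL)
    }
    X <- m[rows, , drop = FALSE]
    R <- suppressWarnings(cor(X, method = "spearman"))
    idx <- which(upper.tri(R), arr.ind = TRUE)
    a <- colnames(X)[idx[, 1]]
    b <- colnames(X)[idx[, 2]]
    rho <- R[idx]
    nz <- colSums(X == 0)
    keep <- if (zero_mode == "pooled") {
      (nz[idx[, 1]] + nz[idx[, 2]]) / (2 * n) <= max_zero_frac
    } else {
      both_pos <- crossprod(X > 0)
      (n - both_pos[idx]) / n <= max_zero_frac
    }
    keep <- keep & !is.na(rho)
    if (!any(keep)) return(NULL)
    a <- a[keep]; b <- b[keep]; rho <- rho[keep]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    p_raw <- spearman_p(rho, n)
    tibble::tibble(
      asv_a = a, asv_b = b, group_id = g,
      experiment_id = unique(exp_of_sample[rows])[1],
      n_samples = n, rho = rho, p_raw = p_raw,
      fdr_quotient = fdr_quotient(p_raw), fdr = fdr_adjust(p_raw)
    ) |>
      dplyr::arrange(.data$asv_a, .data$asv_b)
  })
  if (length(skipped) > 0) {
    warn(sprintf("skipped %d group(s) with fewer than %d samples: %s",
                 length(skipped), min_samples, paste(head(skipped, 5), collapse = ", ")))
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(
      asv_a = character(0), asv_b = character(0), group_id = character(0),
      experiment_id = character(0), n_samples = integer(0), rho = numeric(0),
      p_raw = numeric(0), fdr_quotient = numeric(0), fdr = numeric(0)
    )
  }
  if (!is.null(dist)) {
    res$gd <- dist[cbind(match(res$asv_a, rownames(dist)), match(res$asv_b, colnames(dist)))]
  } else {
    res$gd <- NA_real_
  }
  attr(res, "dropped_missing_gd") <- n_missing_gd
  attr(res, "skipped_groups") <- skipped
  res
}
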