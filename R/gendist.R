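#' Pairwise p-distance between two aligned sequences
#'
#' Proportion of mismatching sites among comparable sites. Under
#' `pairwise_delete` (default) a site is comparable when both sequences
#' carry an unambiguous base (`A/C/G/T`); gaps and `N` are excluded.
#' Under `complete_delete` only sites that are unambiguous in *both*
#' sequences of the pair after removing any site that carries a gap or `N`
#' in either sequence are used (for two sequences the two policies agree;
#' they differ at the matrix level, where complete deletion removes a site
#' from every pair if any sequence is ambiguous there).
#'
#' @param a,b Aligned sequences of equal length (character scalars).
#' @param gap_policy `"pairwise_delete"` or `"complete_delete"`.
#' @return Mismatch proportion in `[0, 1]`.
#' @export
p_distance <- function(a, b, gap_policy = c("pairwise_delete", "complete_delete")) {
  gap_policy <- match.arg(gap_policy)
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  if (length(av) != length(bv)) abort("sequences must have equal aligned length")
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  if (!any(ok)) abort("undefined distance: zero comparable sites after deletion")
  mean(av[ok] != bv[ok])
}

#' Jukes-Cantor (JC69) distance from a p-distance
#'
#' Corrects an observed mismatch proportion for multiple substitutions:
#' `-(3/4) * log(1 - (4/3) * p)`, in expected substitutions per site.
#'
#' @param p Mismatch proportion; must be below the saturation point 0.75.
#' @return Distance in substitutions per site.
#' @export
jc69_distance <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 0.75)) {
    abort("JC69 distance requires 0 <= p < 0.75 (saturation)")
  }
  -0.75 * log(1 - (4 / 3) * p)
}

#' Pairwise genetic distance matrix for aligned ASV sequences
#'
#' Computes all pairwise distances, guaranteeing symmetry and a zero
#' diagonal. Pairs with no comparable sites (or JC69-saturated pairs) are
#' recorded as `NA` and reported in the `"undefined_pairs"` attribute.
#'
#' @param seqs Named character vector of equal-length aligned sequences
#'   (at least 2).
#' @param model `"p"` (default) for the raw mismatch proportion, `"jc69"`
#'   for the Jukes-Cantor correction.
#' @param gap_policy Site-deletion policy, see [p_distance()].
#' @return A symmetric numeric matrix with ASV ids as dimnames.
#' @export
distance_matrix <- function(seqs, model = c("p", "jc69"),
                            gap_policy = c("pairwise_delete", "complete_delete")) {
  model <- match.arg(model)
  gap_policy <- match.arg(gap_policy)
  if (length(seqs) < 2) abort("need at least 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    abort("sequences must carry unique names")
  }
  widths <- nchar(seqs)
  if (any(widths != widths[1])) abort("aligned sequences must have equal length")
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  comparable <- chars == "A" | chars == "C" | chars == "G" | chars == "T"
  if (gap_policy == "complete_delete") {
    keep <- apply(comparable, 2, all)
    chars <- chars[, keep, drop = FALSE]
    comparable <- comparable[, keep, drop = FALSE]
  }
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  undefined <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      ok <- comparable[i, ] & comparable[j, ]
      if (!any(ok)) {
        d[i, j] <- d[j, i] <- NA_real_
        undefined <- c(undefined, paste(names(seqs)[i], names(seqs)[j], sep = ":"))
        next
      }
      p <- mean(chars[i, ok] != chars[j, ok])
      if (model == "jc69") {
        if (p >= 0.75) {
          d[i, j] <- d[j, i] <- NA_real_
          undefined <- c(undefined, paste(names(seqs)[i], names(seqs)[j], sep = ":"))
          next
        }
        p <- -0.75 * log(1 - (4 / 3) * p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  if (length(undefined) > 0) {
    warn(sprintf("%d pair(s) with undefined distance", length(undefined)))
  }
  attr(d, "undefined_pairs") <- undefined
  d
}

#' Distance matrix as a tidy pair table
#'
#' @param d Symmetric distance matrix from [distance_matrix()].
#' @return Tibble with columns `asv_a`, `asv_b` (lexicographic, `a < b`)
#'   and `gd`.
#' @export
tidy_distances <- function(d) {
  ids <- rownames(d)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  a <- ids[idx[, 1]]
  b <- ids[idx[, 2]]
  swap <- a > b
  tibble::tibble(
    asv_a = ifelse(swap, b, a),
    asv_b = ifelse(swap, a, b),
    gd = d[idx]
  ) |> dplyr::arrange(.data$asv_a, .data$asv_b)
}

#' Write a distance matrix as a square TSV
#'
#' @param d Distance matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  tbl <- dplyr::bind_cols(tibble::tibble(asv_id = rownames(d)),
                          tibble::as_tibble(d, .name_repair = "minimal"))
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}
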