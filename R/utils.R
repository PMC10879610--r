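# Internal helpers shared across modules.

# Deterministic 31-bit string hash; used to derive independent RNG streams
# per sample / per treatment so that row order never changes results.
stable_hash <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

# Sub-seed from (root seed, label); stays below 2^31 - 1.
seed_for <- function(seed, label) {
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + stable_hash(label)) %% 2147483647)
}

is_whole <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

# Wide abundance tibble (sample_id + one column per ASV) -> numeric matrix.
as_count_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl), "sample_id" %in% names(tbl))
  m <- as.matrix(tbl[setdiff(names(tbl), "sample_id")])
  rownames(m) <- tbl$sample_id
  storage.mode(m) <- "double"
  m
}

count_matrix_to_tibble <- function(m) {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)), out)
}

asv_ids <- function(tbl) setdiff(names(tbl), "sample_id")

check_abundance <- function(tbl, arg = "table") {
  if (!is.data.frame(tbl) || !"sample_id" %in% names(tbl)) {
    abort(sprintf("%s must be a data frame with a 'sample_id' column", arg))
  }
  dup <- tbl$sample_id[duplicated(tbl$sample_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicated sample id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  ids <- asv_ids(tbl)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(sprintf("duplicated ASV id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  m <- as_count_matrix(tbl)
  if (any(!is.finite(m))) abort("abundance table contains non-finite values")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative count at sample '%s', ASV '%s'",
                  rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  invisible(tbl)
}
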