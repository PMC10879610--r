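#' Read an ASV abundance table
#'
#' Reads a tab-separated count table with one header row of identifiers and
#' one identifier column, validates it, and returns a wide tibble with a
#' `sample_id` column followed by one integer column per ASV.
#'
#' @param path Path to a TSV file.
#' @param orientation Either `"samples_as_rows"` (default; the identifier
#'   column holds sample ids and the header holds ASV ids) or
#'   `"asvs_as_rows"` (the transpose).
#' @return A tibble, samples in rows, ASVs in columns.
#' @details Counts must be non-negative whole numbers; duplicated sample or
#'   ASV identifiers, negative values, and non-numeric cells are rejected
#'   with a message locating the offence.
#' @export
read_abundance <- function(path, orientation = c("samples_as_rows", "asvs_as_rows")) {
  orientation <- match.arg(orientation)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2 || nrow(raw) < 1) abort("abundance table must have an id column and at least one data column")
  row_ids <- as.character(raw[[1]])
  col_ids <- names(raw)[-1]
  body <- as.matrix(raw[-1])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                  body[bad[1, 1], bad[1, 2]], row_ids[bad[1, 1]], col_ids[bad[1, 2]]))
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative count at row '%s', column '%s'",
                  row_ids[bad[1]], col_ids[bad[2]]))
  }
  if (any(!is_whole(num))) {
    bad <- which(!is_whole(num), arr.ind = TRUE)[1, ]
    abort(sprintf("non-integer count %s at row '%s', column '%s'",
                  format(num[bad[1], bad[2]]), row_ids[bad[1]], col_ids[bad[2]]))
  }
  num <- round(num)
  if (orientation == "asvs_as_rows") {
    m <- t(num)
    rownames(m) <- col_ids
    colnames(m) <- row_ids
  } else {
    m <- num
    rownames(m) <- row_ids
    colnames(m) <- col_ids
  }
  tbl <- count_matrix_to_tibble(m)
  check_abundance(tbl)
  if (nrow(tbl) < 2 || length(asv_ids(tbl)) < 2) {
    abort("abundance table must contain at least 2 samples and 2 ASVs")
  }
  tbl
}

#' Write an abundance table to TSV
#'
#' @param table Wide abundance tibble (`sample_id` + ASV columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(table, path) {
  check_abundance(table)
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects tab-separated columns `sample_id`, `treatment_id`,
#' `experiment_id`, `diet`, `contact`, `n_voles`. Diet and contact levels
#' are normalised case-insensitively (and whitespace-trimmed) to
#' `{grass, chow}` and `{yes, no}`.
#'
#' @param path Path to a TSV file.
#' @return A tibble with one row per sample.
#' @export
read_metadata <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("sample_id", "treatment_id", "experiment_id", "diet", "contact", "n_voles")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("metadata is missing required column(s): %s", paste(missing, collapse = ", ")))
  }
  tbl <- tibble::as_tibble(tbl[required])
  tbl$diet <- normalize_level(tbl$diet, c("grass", "chow"), "diet")
  tbl$contact <- normalize_level(tbl$contact, c("yes", "no"), "contact")
  nv <- suppressWarnings(as.numeric(tbl$n_voles))
  if (any(is.na(nv)) || any(!is_whole(nv)) || any(nv < 1)) {
    bad <- tbl$n_voles[is.na(nv) | !is_whole(nv) | nv < 1][1]
    abort(sprintf("n_voles must be a positive integer; offending value: '%s'", bad))
  }
  tbl$n_voles <- as.integer(round(nv))
  dup <- tbl$sample_id[duplicated(tbl$sample_id)]
  if (length(dup) > 0) abort(sprintf("duplicated sample id(s) in metadata: %s", paste(unique(dup), collapse = ", ")))
  tbl
}

normalize_level <- function(x, levels, what) {
  norm <- tolower(trimws(x))
  bad <- setdiff(unique(norm), levels)
  if (length(bad) > 0) {
    abort(sprintf("unknown %s level(s): %s (expected one of %s)",
                  what, paste(bad, collapse = ", "), paste(levels, collapse = ", ")))
  }
  norm
}

#' Read aligned ASV sequences from FASTA
#'
#' Records may wrap across lines. Sequences are upper-cased; characters
#' outside `{A,C,G,T,-}` are recoded to `N` (treated as missing downstream).
#' All sequences must have equal aligned length.
#'
#' @param path Path to an aligned FASTA file.
#' @return A named character vector of equal-width aligned sequences.
#' @export
read_aligned_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup) > 0) abort(sprintf("duplicated sequence id(s): %s", paste(unique(dup), collapse = ", ")))
  seqs <- gsub("[^ACGT-]", "N", seqs)
  widths <- nchar(seqs)
  if (length(seqs) > 0 && any(widths != widths[1])) {
    first_bad <- names(seqs)[which(widths != widths[1])[1]]
    abort(sprintf("aligned sequences must have equal length; record '%s' has length %d (expected %d)",
                  first_bad, widths[widths != widths[1]][1], widths[1]))
  }
  seqs
}

#' Write aligned sequences to FASTA
#'
#' @param seqs Named character vector of aligned sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a taxonomy table
#'
#' TSV with column `asv_id` and any of `phylum`, `class`, `order`,
#' `family`, `genus`. Missing ranks are stored as empty strings and
#' rendered as `"Unassigned"` in reports.
#'
#' @param path Path to a TSV file.
#' @return A tibble with `asv_id` plus the five rank columns.
#' @export
read_taxonomy <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"asv_id" %in% names(tbl)) abort("taxonomy table must contain an 'asv_id' column")
  ranks <- c("phylum", "class", "order", "family", "genus")
  for (r in setdiff(ranks, names(tbl))) tbl[[r]] <- ""
  tbl <- tbl[c("asv_id", ranks)]
  tbl[ranks] <- lapply(tbl[ranks], function(x) ifelse(is.na(x), "", x))
  tbl
}

#' Write and read pair tables
#'
#' The pair table holds one row per ASV pair per group: the co-occurrence
#' index (Spearman rho), raw and FDR-adjusted p-values, and genetic
#' distance. Round-tripping through TSV preserves values to at least 10
#' significant digits.
#'
#' @param pairs A pair tibble as produced by [pair_table()].
#' @param path File path.
#' @return `write_pair_table()` returns `path` invisibly;
#'   `read_pair_table()` returns the tibble.
#' @export
write_pair_table <- function(pairs, path) {
  readr::write_tsv(pairs, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_pair_table
#' @export
read_pair_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    asv_a = "c", asv_b = "c", group_id = "c", experiment_id = "c",
    .default = readr::col_double()
  ), progress = FALSE)
}

#' Write a network edge list to TSV
#'
#' Columns: `source`, `target`, `rho`, `p`, `fdr`, `sign`. An empty network
#' yields a header-only file.
#'
#' @param network A `cooc_network` object (see [build_network()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "cooc_network"))
  edges <- network$edges
  out <- tibble::tibble(
    source = edges$asv_a, target = edges$asv_b,
    rho = edges$rho, p = edges$p_boot,
    fdr = if ("fdr" %in% names(edges)) edges$fdr else rep(NA_real_, nrow(edges)),
    sign = edges$sign
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    source = "c", target = "c", sign = "c", .default = readr::col_double()
  ), progress = FALSE)
}

#' Write a co-occurrence network to GraphML
#'
#' Node attributes: `phylum`, `degree`, `pos_degree`, `neg_degree`,
#' `betweenness`, `is_hub`; edge attributes: `weight` (rho) and `p`.
#'
#' @param network A `cooc_network` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  stopifnot(inherits(network, "cooc_network"))
  g <- as_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Validate a joint input bundle
#'
#' Cross-checks the three pipeline inputs: every sample in the abundance
#' table must have exactly one metadata row, and (when sequences are given)
#' every ASV must have an aligned sequence.
#'
#' @param abundance Wide abundance tibble.
#' @param metadata Sample metadata tibble.
#' @param seqs Optional named character vector of aligned sequences.
#' @param taxonomy Optional taxonomy tibble.
#' @return Invisibly, a list summarising counts of samples, ASVs, and
#'   treatment groups.
#' @export
validate_inputs <- function(abundance, metadata, seqs = NULL, taxonomy = NULL) {
  check_abundance(abundance)
  missing_meta <- setdiff(abundance$sample_id, metadata$sample_id)
  if (length(missing_meta) > 0) {
    abort(sprintf("sample(s) without metadata: %s", paste(head(missing_meta, 5), collapse = ", ")))
  }
  if (anyDuplicated(metadata$sample_id)) {
    abort("metadata contains duplicated sample ids")
  }
  if (!is.null(seqs)) {
    missing_seq <- setdiff(asv_ids(abundance), names(seqs))
    if (length(missing_seq) > 0) {
      abort(sprintf("ASV(s) without an aligned sequence: %s", paste(head(missing_seq, 5), collapse = ", ")))
    }
  }
  invisible(list(
    n_samples = nrow(abundance),
    n_asvs = length(asv_ids(abundance)),
    n_treatments = length(unique(metadata$treatment_id[metadata$sample_id %in% abundance$sample_id])),
    n_experiments = length(unique(metadata$experiment_id[metadata$sample_id %in% abundance$sample_id]))
  ))
}

#' Study design of the vole experiments
#'
#' The packaged treatment-level design table of the gut-microbiota study the
#' pipeline was built around: 37 treatment groups from 8 experiments, each
#' with its cohabitating group size, diet (grass vs. rabbit chow), and
#' physical-contact regime.
#'
#' @return A tibble with columns `study`, `experiment_id`, `condition`,
#'   `treatment`, `treatment_id`, `n_voles`, `diet`, `contact`.
#' @export
vole_treatments <- function() {
  path <- system.file("extdata", "vole_treatments.tsv", package = "microcooc")
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    n_voles = readr::col_integer(), .default = readr::col_character()
  ), progress = FALSE)
  tbl$diet <- normalize_level(tbl$diet, c("grass", "chow"), "diet")
  tbl$contact <- normalize_level(tbl$contact, c("yes", "no"), "contact")
  tbl
}
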