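# In-code fixtures shared across test files.

make_counts <- function(m, sample_ids = NULL, asv_ids = NULL) {
  m <- as.matrix(m)
  rownames(m) <- sample_ids %||% sprintf("s%02d", seq_len(nrow(m)))
  colnames(m) <- asv_ids %||% sprintf("ASV_%03d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_metadata <- function(sample_ids, treatment_ids,
                          experiment_ids = paste0("Exp_", treatment_ids),
                          diet = "chow", contact = "no", n_voles = 4L) {
  tibble::tibble(
    sample_id = sample_ids, treatment_id = treatment_ids,
    experiment_id = experiment_ids,
    diet = rep_len(diet, length(sample_ids)),
    contact = rep_len(contact, length(sample_ids)),
    n_voles = as.integer(rep_len(n_voles, length(sample_ids)))
  )
}

# small but complete synthetic study for pipeline-level tests
tiny_config <- function(seed = 11L, n_samples = 8L) {
  synth_config(
    n_asvs = 12, seq_length = 80, depth = 800,
    n_stress_factors = 2, responders_per_factor = 2,
    treatments = tibble::tibble(
      treatment_id = sprintf("T%d", 1:4),
      diet = c("grass", "grass", "chow", "chow"),
      contact = c("no", "yes", "no", "yes"),
      n_voles = c(2L, 8L, 4L, 2L),
      n_samples = rep(as.integer(n_samples), 4),
      diversity = c(0.9, 0.4, 0.7, 0.5)
    ),
    seed = seed
  )
}

write_tiny_study <- function(dir, seed = 11L) {
  generate_study(tiny_config(seed = seed), dir = dir)
}
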