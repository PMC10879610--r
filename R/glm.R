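#' Min-max normalisation
#'
#' Rescales a numeric vector affinely onto `[0, 1]`; used to put the
#' co-occurrence index and its continuous predictors on a common scale
#' before regression.
#'
#' @param x Numeric vector with `max(x) > min(x)`.
#' @return `(x - min) / (max - min)`.
#' @export
minmax <- function(x) {
  if (any(!is.finite(x))) abort("minmax requires finite values")
  r <- range(x)
  if (r[1] == r[2]) abort("constant vector: min-max normalization is degenerate")
  (x - r[1]) / (r[2] - r[1])
}

#' Collinearity screen among continuous candidates
#'
#' Computes pairwise Spearman correlations among candidate predictors and,
#' within every group of variables linked (transitively) by
#' `|rho| > threshold`, keeps only the highest-priority variable. The
#' default priority puts Shannon diversity first, so when the diversity
#' indices are mutually correlated only Shannon enters the model.
#'
#' @param candidates A data frame of continuous candidate predictors.
#' @param threshold Absolute-correlation threshold (default 0.5, strict).
#' @param keep_priority Character vector ordering variables from most to
#'   least preferred; unlisted variables rank after listed ones in column
#'   order.
#' @return A list with `retained` (character), `dropped` (character), and
#'   `cor_table` (tibble of pairwise correlations).
#' @export
collinearity_screen <- function(candidates, threshold = 0.5,
                                keep_priority = c("shannon", "n_voles", "simpson", "chao1")) {
  if (!is.data.frame(candidates) || ncol(candidates) < 2) {
    abort("need at least 2 candidate variables")
  }
  vars <- names(candidates)
  R <- suppressWarnings(cor(as.matrix(candidates), method = "spearman"))
  linked <- !is.na(R) & abs(R) > threshold
  diag(linked) <- FALSE
  # transitive closure -> connected components
  comp <- seq_along(vars)
  repeat {
    changed <- FALSE
    for (i in seq_along(vars)) {
      for (j in seq_along(vars)) {
        if (linked[i, j] && comp[j] != comp[i]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  priority <- match(vars, keep_priority)
  priority[is.na(priority)] <- length(keep_priority) + seq_along(vars)[is.na(priority)]
  retained <- unlist(lapply(unique(comp), function(cc) {
    members <- which(comp == cc)
    vars[members[which.min(priority[members])]]
  }))
  idx <- which(upper.tri(R), arr.ind = TRUE)
  cor_table <- tibble::tibble(
    var_a = vars[idx[, 1]], var_b = vars[idx[, 2]], rho = R[idx]
  )
  list(retained = retained[order(match(retained, vars))],
       dropped = setdiff(vars, retained),
       cor_table = cor_table)
}

#' Per-experiment linear fits of co-occurrence on genetic distance
#'
#' Ordinary least squares of the co-occurrence index (raw rho) on genetic
#' distance, one fit per experiment. Experiments with fewer than 3 pairs
#' or a constant genetic distance are skipped with a warning.
#'
#' @param pairs Pair tibble from [pair_table()] (needs `rho`, `gd`,
#'   `experiment_id`).
#' @param by Grouping column (default `"experiment_id"`).
#' @return Tibble `(experiment_id, n_pairs, intercept, slope, r, p_value)`.
#' @export
fit_lm <- function(pairs, by = "experiment_id") {
  if (!all(c("rho", "gd", by) %in% names(pairs))) {
    abort(sprintf("pairs must contain columns rho, gd, %s", by))
  }
  pairs <- pairs[is.finite(pairs$gd) & is.finite(pairs$rho), , drop = FALSE]
  groups <- split(pairs, pairs[[by]])
  skipped <- character(0)
  out <- purrr::map(names(groups), function(g) {
    d <- groups[[g]]
    if (nrow(d) < 3 || sd(d$gd) == 0) {
      skipped <<- c(skipped, g)
      return(NULL)
    }
    fit <- lm(rho ~ gd, data = d)
    sm <- summary(fit)
    tibble::tibble(
      experiment_id = g, n_pairs = nrow(d),
      intercept = coef(fit)[[1]], slope = coef(fit)[[2]],
      r = cor(d$gd, d$rho),
      p_value = sm$coefficients["gd", "Pr(>|t|)"]
    )
  })
  if (length(skipped) > 0) {
    warn(sprintf("skipped %d experiment(s) (too few pairs or constant gd): %s",
                 length(skipped), paste(head(skipped, 5), collapse = ", ")))
  }
  dplyr::bind_rows(out)
}

#' Build the GLM design table
#'
#' Assembles one row per ASV pair: the co-occurrence index as response
#' and `gd`, treatment-level Shannon diversity, group size `n_voles`, and
#' the two categorical covariates as predictors. Continuous columns
#' (response included) are min-max normalised over the pooled rows;
#' categorical columns are indicators with reference levels diet = chow
#' and contact = no. Candidate diversity/size covariates are screened for
#' collinearity first (Spearman `|rho| > threshold` keeps only the
#' highest-priority variable).
#'
#' @param pairs Pair tibble from [pair_table()] (treatment scope).
#' @param metadata Sample metadata tibble.
#' @param diversity Per-treatment diversity table from
#'   [treatment_diversity_table()]; computed covariates `shannon`,
#'   `simpson`, `chao1` are candidates.
#' @param pairs_filter `"all"` (default) or `"significant"` to keep only
#'   pairs with `fdr <= fdr_alpha`.
#' @param fdr_alpha FDR cut used when `pairs_filter = "significant"`.
#' @param screen Apply the collinearity screen (default `TRUE`).
#' @param threshold Collinearity threshold (default 0.5).
#' @param normalize Min-max normalise continuous columns (default `TRUE`).
#' @return A tibble with the response `rho` and predictor columns; the
#'   screen result and normalisation ranges are attached as attributes
#'   `"screen"` and `"ranges"`, the candidate term names as `"terms"`.
#' @export
build_glm_design <- function(pairs, metadata, diversity,
                             pairs_filter = c("all", "significant"),
                             fdr_alpha = 0.05, screen = TRUE, threshold = 0.5,
                             normalize = TRUE) {
  pairs_filter <- match.arg(pairs_filter)
  if (pairs_filter == "significant") {
    pairs <- pairs[pairs$fdr <= fdr_alpha, , drop = FALSE]
  }
  pairs <- pairs[is.finite(pairs$gd), , drop = FALSE]
  if (nrow(pairs) == 0) abort("no pair rows left to build a design from")

  treat <- metadata |>
    dplyr::distinct(.data$treatment_id, .data$diet, .data$contact, .data$n_voles)
  if (anyDuplicated(treat$treatment_id)) {
    abort("treatment covariates are not constant within treatment groups")
  }
  covars <- diversity |>
    dplyr::select("treatment_id", dplyr::any_of(c("shannon", "simpson", "chao1"))) |>
    dplyr::left_join(treat, by = "treatment_id")

  rows <- pairs |>
    dplyr::left_join(covars, by = c(group_id = "treatment_id"))
  if (any(is.na(rows$diet))) abort("pair groups without treatment covariates; build pairs with scope = 'treatment'")

  candidates <- rows |>
    dplyr::select(dplyr::any_of(c("shannon", "simpson", "chao1", "n_voles")))
  constant <- names(candidates)[vapply(candidates, function(x) sd(x) == 0, logical(1))]
  if (length(constant) > 0) {
    warn(sprintf("dropping constant candidate predictor(s): %s", paste(constant, collapse = ", ")))
    candidates <- candidates[setdiff(names(candidates), constant)]
  }
  screen_res <- NULL
  keep_covars <- names(candidates)
  if (screen && ncol(candidates) >= 2) {
    screen_res <- collinearity_screen(candidates, threshold = threshold)
    keep_covars <- screen_res$retained
  }

  design <- tibble::tibble(
    rho = rows$rho,
    gd = rows$gd
  )
  for (v in keep_covars) design[[v]] <- rows[[v]]
  design$diet_grass <- as.numeric(rows$diet == "grass")
  design$contact_yes <- as.numeric(rows$contact == "yes")

  ranges <- NULL
  if (normalize) {
    cont <- setdiff(names(design), c("diet_grass", "contact_yes"))
    ranges <- purrr::map(design[cont], range)
    for (v in cont) design[[v]] <- minmax(design[[v]])
  }
  terms <- setdiff(names(design), "rho")
  structure(design, terms = terms, screen = screen_res, ranges = ranges,
            class = c("cooc_design", class(design)))
}

#' Fit the Gaussian GLM of the co-occurrence index
#'
#' Gaussian-identity GLM (equivalent to OLS) of the normalised
#' co-occurrence index on the design's predictors, with intercept. AIC is
#' computed from the Gaussian profile log-likelihood (the dispersion
#' counts as a parameter).
#'
#' @param design Design tibble from [build_glm_design()].
#' @param terms Character vector of terms to include; defaults to all
#'   design terms.
#' @return A `cooc_glm` object wrapping the fitted [stats::glm] model.
#' @export
fit_glm <- function(design, terms = NULL) {
  all_terms <- attr(design, "terms") %||% setdiff(names(design), "rho")
  if (is.null(terms)) terms <- all_terms
  bad <- setdiff(terms, names(design))
  if (length(bad) > 0) abort(sprintf("unknown term(s): %s", paste(bad, collapse = ", ")))
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  form <- stats::as.formula(paste("rho ~", rhs))
  dat <- as.data.frame(design)
  if (nrow(dat) <= length(terms) + 1) abort("not enough rows for the requested terms")
  fit <- glm(form, family = gaussian(), data = dat)
  if (any(is.na(coef(fit)))) {
    abort(sprintf("rank-deficient design; aliased term(s): %s",
                  paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  structure(list(fit = fit, formula = paste("rho ~", rhs), terms = terms,
                 n = nrow(dat)),
            class = "cooc_glm")
}

#' @export
print.cooc_glm <- function(x, ...) {
  cat(sprintf("<cooc_glm> %s  (n = %d, AIC = %.1f)\n", x$formula, x$n, AIC(x$fit)))
  print(tidy(x), ...)
  invisible(x)
}

#' Broom-style accessors for `cooc_glm` fits
#'
#' @param x A `cooc_glm` object.
#' @param ... Unused.
#' @return `tidy()` gives one row per coefficient (`term`, `estimate`,
#'   `std_error`, `t_value`, `p_value`); `glance()` one row of model-level
#'   summaries (`aic`, `n`, `formula`, `df_residual`, `deviance`).
#' @method tidy cooc_glm
#' @export
tidy.cooc_glm <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std_error = unname(sm[, "Std. Error"]),
    t_value = unname(sm[, "t value"]),
    p_value = unname(sm[, "Pr(>|t|)"])
  )
}

#' @rdname tidy.cooc_glm
#' @method glance cooc_glm
#' @export
glance.cooc_glm <- function(x, ...) {
  tibble::tibble(
    aic = AIC(x$fit), n = x$n, formula = x$formula,
    df_residual = x$fit$df.residual, deviance = x$fit$deviance
  )
}

#' Exhaustive AIC model selection
#'
#' Fits every subset of the design's candidate terms (intercept always
#' included), ranks them by AIC, and returns the minimum-AIC fit. Ties are
#' broken in favour of fewer terms, then lexicographically by formula.
#'
#' @param design Design tibble from [build_glm_design()] (at most 12
#'   candidate terms).
#' @return The best `cooc_glm`, with the full ranking attached as the
#'   tibble `trace` (`formula`, `n_terms`, `aic`, `delta_aic`).
#' @export
select_model <- function(design) {
  terms <- attr(design, "terms") %||% setdiff(names(design), "rho")
  if (length(terms) > 12) abort("more than 12 candidate terms; exhaustive search refused")
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(terms)))
  fits <- purrr::map(seq_len(nrow(subsets)), function(i) {
    fit_glm(design, terms = terms[unlist(subsets[i, ])])
  })
  trace <- tibble::tibble(
    formula = purrr::map_chr(fits, "formula"),
    n_terms = purrr::map_int(fits, ~ length(.x$terms)),
    aic = purrr::map_dbl(fits, ~ AIC(.x$fit))
  )
  ord <- order(trace$aic, trace$n_terms, trace$formula)
  trace <- trace[ord, ]
  trace$delta_aic <- trace$aic - trace$aic[1]
  best <- fits[[ord[1]]]
  best$trace <- trace
  best
}

#' Subsample robustness of the GLM
#'
#' Pair rows enter the GLM as if independent although they share ASVs;
#' as a mitigation the model is refit on small random row subsets. Draws
#' `reps` independent subsamples of `frac` of the rows (without
#' replacement), refits the same terms, and summarises the spread and the
#' sign agreement of each coefficient with the full fit.
#'
#' @param design Design tibble from [build_glm_design()].
#' @param frac Subsample fraction (default 0.01).
#' @param reps Number of repetitions (default 10).
#' @param seed Integer seed.
#' @param terms Terms to fit; defaults to all design terms.
#' @return A list with `estimates` (tibble: `rep`, `term`, `estimate`) and
#'   `summary` (tibble: `term`, `full_estimate`, `mean`, `sd`,
#'   `sign_agreement`).
#' @export
subsample_robustness <- function(design, frac = 0.01, reps = 10, seed = 1L,
                                 terms = NULL) {
  all_terms <- attr(design, "terms") %||% setdiff(names(design), "rho")
  if (is.null(terms)) terms <- all_terms
  n <- nrow(design)
  m <- floor(frac * n)
  if (m <= length(terms) + 2) {
    abort(sprintf("subsample of %d rows is too small for %d terms; increase frac",
                  m, length(terms)))
  }
  full <- fit_glm(design, terms = terms)
  full_est <- tidy(full)
  ests <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(seq_len(reps), function(r) {
      rows <- sample.int(n, m)
      fit <- fit_glm(design[rows, , drop = FALSE], terms = terms)
      td <- tidy(fit)
      tibble::tibble(rep = r, term = td$term, estimate = td$estimate)
    })
  })
  summary_tbl <- ests |>
    dplyr::left_join(full_est[, c("term", "estimate")], by = "term",
                     suffix = c("", "_full")) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      full_estimate = .data$estimate_full[1],
      mean = mean(.data$estimate),
      sd = sd(.data$estimate),
      sign_agreement = mean(sign(.data$estimate) == sign(.data$estimate_full)),
      .groups = "drop"
    )
  list(estimates = ests, summary = summary_tbl)
}
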