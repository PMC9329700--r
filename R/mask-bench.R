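#' Mask a fraction of the observed entries
#'
#' Hides `floor(fraction * d)` of the `d` non-zero entries, sampled
#' uniformly without replacement, by setting them to zero — the standard
#' benchmark construction: the held-out values are ground truth for
#' recovery metrics. Structural zeros are never touched.
#'
#' @param x An [expression_matrix()] with at least one non-zero entry.
#' @param fraction Fraction of non-zero entries to mask, in (0, 1).
#' @param seed RNG seed; the same seed reproduces the same mask.
#' @return A list of class `masked_dataset`: `masked` (the `expr_matrix`
#'   with held-out entries zeroed), `mask_i`, `mask_j` (1-based
#'   coordinates), `truth_values`, `mask_fraction`, `seed`.
#' @export
mask_nonzero <- function(x, fraction, seed = 1L) {
  omega <- observed_set(x)
  if (omega$d < 1L) {
    rlang::abort("The matrix has no non-zero entries to mask.",
                 class = "gnimpute_validation_error")
  }
  n_mask <- floor(fraction * omega$d)
  if (!(fraction > 0 && fraction < 1) || n_mask < 1L) {
    rlang::abort("`fraction` must select at least one non-zero entry; use a larger fraction.",
                 class = "gnimpute_validation_error")
  }
  set.seed(seed)
  pick <- sample.int(omega$d, n_mask)
  mi <- omega$i[pick]
  mj <- omega$j[pick]
  vals <- unclass(x)
  truth <- vals[cbind(mi, mj)]
  vals[cbind(mi, mj)] <- 0
  masked <- expression_matrix(vals, gene_ids = rownames(x),
                              cell_ids = colnames(x),
                              labels = cell_labels(x),
                              layer_tag = layer_tag(x))
  structure(list(masked = masked, mask_i = mi, mask_j = mj,
                 truth_values = truth, mask_fraction = fraction,
                 seed = seed),
            class = "masked_dataset")
}

#' @export
print.masked_dataset <- function(x, ...) {
  cat(sprintf("<masked_dataset> %d entries hidden (%.1f%% of non-zeros), seed %d\n",
              length(x$truth_values), 100 * x$mask_fraction, x$seed))
  invisible(x)
}

metric_fun <- function(name) {
  switch(name,
         cor = function(p, denom) pearson_cor(p),
         fe = function(p, denom) frobenius_error(p, denom),
         mse = function(p, denom) mse(p),
         l1 = function(p, denom) l1_error(p),
         rlang::abort(sprintf("Unknown metric '%s'.", name),
                      class = "gnimpute_validation_error"))
}

#' Score an imputation against held-out masked values
#'
#' Per-cell mode (the default) computes each metric on every cell's masked
#' coordinates separately and averages over cells with at least one masked
#' entry; cells whose correlation is undefined (constant values) are
#' skipped, not scored 0. Pooled mode computes each metric once over all
#' masked coordinates, with the Frobenius-error denominator taken over the
#' whole reference matrix.
#'
#' @param md A [mask_nonzero()] result.
#' @param imputed The imputed [expression_matrix()] (same dimensions as the
#'   source).
#' @param truth The unmasked source [expression_matrix()] (used for the
#'   pooled Frobenius denominator; per-cell mode uses the held-out values).
#' @param metrics Subset of `c("cor", "fe", "mse", "l1")`.
#' @param per_cell Per-cell averaging (default) or pooled.
#' @return A tibble: `metric`, `value`, `n_cells_used`.
#' @export
score_imputation <- function(md, imputed, truth = NULL,
                             metrics = c("cor", "fe", "mse", "l1"),
                             per_cell = TRUE) {
  est <- unclass(imputed)[cbind(md$mask_i, md$mask_j)]
  tv <- md$truth_values
  if (!per_cell) {
    denom <- if (is.null(truth)) sum(tv^2) else sum(unclass(truth)^2)
    p <- masked_pair(est, tv)
    return(purrr::map_dfr(metrics, function(mname) {
      tibble::tibble(metric = mname,
                     value = metric_fun(mname)(p, denom),
                     n_cells_used = NA_integer_)
    }))
  }
  cells <- split(seq_along(tv), md$mask_j)
  purrr::map_dfr(metrics, function(mname) {
    f <- metric_fun(mname)
    per <- purrr::map_dbl(cells, function(idx) {
      p <- masked_pair(est[idx], tv[idx])
      tryCatch(f(p, sum(p$truth^2)),
               gnimpute_undefined_metric_error = function(e) NA_real_)
    })
    used <- sum(!is.na(per))
    tibble::tibble(metric = mname,
                   value = mean(per, na.rm = TRUE),
                   n_cells_used = as.integer(used))
  })
}

#' Masking benchmark over replicates
#'
#' For each masking fraction and replicate (seed `base_seed + replicate`),
#' hides that fraction of the non-zero entries, runs the imputer on the
#' masked matrix, and scores the recovery of the hidden values per cell.
#' Re-imputation is run independently for every replicate.
#'
#' @param x The (preprocessed, log-transformed) [expression_matrix()].
#' @param fractions Masking fractions, e.g. `c(0.02, 0.05, 0.10)`.
#' @param n_replicates Replicates per fraction (default 60).
#' @param cfg [gn_config()] for the default Gauss-Newton imputer.
#' @param metrics Metrics to report.
#' @param imputer Any function mapping an `expr_matrix` to an imputed
#'   `expr_matrix`; defaults to [impute()] with `cfg`. Stubs (identity,
#'   zero-filling) are useful for calibration.
#' @param base_seed Base RNG seed; replicate r uses `base_seed + r`.
#' @param per_cell Per-cell averaging (default) or pooled scoring.
#' @return A tibble of class `mask_benchmark` with columns `fraction`,
#'   `replicate`, `seed`, `metric`, `value`, `n_cells_used`.
#' @export
run_replicates <- function(x, fractions, n_replicates = 60L,
                           cfg = gn_config(),
                           metrics = c("cor", "fe", "mse", "l1"),
                           imputer = NULL, base_seed = 1L, per_cell = TRUE) {
  stopifnot(n_replicates >= 1L, length(fractions) >= 1L)
  imputer <- imputer %||% function(xm) impute(xm, cfg)$x_star
  grid <- expand.grid(fraction = fractions, replicate = seq_len(n_replicates))
  out <- purrr::pmap_dfr(grid, function(fraction, replicate) {
    seed <- base_seed + replicate
    md <- mask_nonzero(x, fraction, seed = seed)
    xs <- imputer(md$masked)
    dplyr::mutate(
      score_imputation(md, xs, truth = x, metrics = metrics,
                       per_cell = per_cell),
      fraction = fraction, replicate = as.integer(replicate),
      seed = as.integer(seed), .before = 1L)
  })
  class(out) <- c("mask_benchmark", class(out))
  out
}

#' Summarize a masking benchmark
#'
#' @param object A [run_replicates()] result.
#' @param ... Unused.
#' @return A tibble with mean and sd of each metric per fraction.
#' @export
summary.mask_benchmark <- function(object, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(object), .data$fraction, .data$metric),
    mean = mean(.data$value), sd = stats::sd(.data$value),
    n = dplyr::n(), .groups = "drop")
}

#' Plot a masking benchmark
#'
#' @param object A [run_replicates()] result.
#' @param ... Unused.
#' @return A ggplot: one boxplot of replicate values per masking fraction,
#'   faceted by metric.
#' @export
autoplot.mask_benchmark <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = factor(100 * .data$fraction),
                               y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~ .data$metric, scales = "free_y") +
    ggplot2::labs(x = "Masking percentage of non-zero entries",
                  y = "Per-cell mean metric") +
    ggplot2::theme_minimal()
}
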