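#' Remove duplicated gene rows
#'
#' Among rows that share a gene identifier, the row with the largest total
#' count is kept (ties broken by first occurrence), so deduplication retains
#' the most information and is deterministic. Row order of the kept genes
#' follows their first occurrence in the input.
#'
#' @param x An [expression_matrix()].
#' @return An `expr_matrix` with unique gene identifiers.
#' @export
drop_duplicate_genes <- function(x) {
  ids <- rownames(x)
  if (!anyDuplicated(ids)) {
    return(x)
  }
  totals <- rowSums(x)
  # stable keep-max: order by descending total, take first hit per id, then
  # restore original row order of the winners
  ord <- order(-totals, seq_along(ids))
  winners <- ord[!duplicated(ids[ord])]
  subset_expr(x, i = sort(winners))
}

#' Filter lowly expressed genes and shallow cells
#'
#' Drops genes expressed (non-zero) in fewer than `min_cells_per_gene` cells,
#' then drops cells with fewer than `min_genes_per_cell` expressed genes,
#' counted on the gene-filtered matrix. This is a single pass: the gene
#' filter is computed on the input and the cell filter on its result, with no
#' iteration to a fixed point (`iterate = TRUE` repeats the pass until the
#' dimensions stabilize).
#'
#' @param x An [expression_matrix()].
#' @param min_cells_per_gene Minimum number of cells in which a gene must be
#'   non-zero (default 5).
#' @param min_genes_per_cell Minimum number of non-zero genes a cell must
#'   have (default 200).
#' @param iterate Repeat the two-step pass to a fixed point (default `FALSE`).
#' @return The filtered `expr_matrix`; labels are subset with the cells.
#' @export
filter_matrix <- function(x, min_cells_per_gene = 5L, min_genes_per_cell = 200L,
                          iterate = FALSE) {
  stopifnot(min_cells_per_gene >= 0, min_genes_per_cell >= 0)
  repeat {
    keep_genes <- rowSums(unclass(x) != 0) >= min_cells_per_gene
    if (!any(keep_genes)) {
      rlang::abort("Filtering removed every gene; lower the thresholds.",
                   class = "gnimpute_empty_result_error")
    }
    y <- subset_expr(x, i = which(keep_genes))
    keep_cells <- colSums(unclass(y) != 0) >= min_genes_per_cell
    if (!any(keep_cells)) {
      rlang::abort("Filtering removed every cell; lower the thresholds.",
                   class = "gnimpute_empty_result_error")
    }
    y <- subset_expr(y, j = which(keep_cells))
    if (!iterate || identical(dim(y), dim(x))) {
      return(y)
    }
    x <- y
  }
}

#' Log-transform a count matrix
#'
#' Replaces every entry v by log(v + 1). Zeros map to zeros, so the observed
#' (non-zero) set is unchanged — the transform never creates or destroys
#' observations.
#'
#' @param x An [expression_matrix()] with `layer_tag = "counts"`.
#' @param base Logarithm base; natural log by default.
#' @return The transformed `expr_matrix`, `layer_tag = "log1p"`.
#' @export
log_transform <- function(x, base = exp(1)) {
  if (layer_tag(x) != "counts") {
    rlang::abort("Input is already log-transformed.",
                 class = "gnimpute_state_error")
  }
  vals <- log1p(unclass(x))
  if (base != exp(1)) {
    vals <- vals / log(base)
  }
  expression_matrix(vals, gene_ids = rownames(x), cell_ids = colnames(x),
                    labels = cell_labels(x), layer_tag = "log1p")
}

#' Standard preprocessing pipeline
#'
#' Deduplicate genes, apply the abundance filters, then log-transform:
#' the order used throughout the package.
#'
#' @inheritParams filter_matrix
#' @inheritParams log_transform
#' @return A preprocessed `expr_matrix` (`layer_tag = "log1p"`).
#' @export
preprocess_matrix <- function(x, min_cells_per_gene = 5L,
                              min_genes_per_cell = 200L, base = exp(1)) {
  x |>
    drop_duplicate_genes() |>
    filter_matrix(min_cells_per_gene, min_genes_per_cell) |>
    log_transform(base = base)
}
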