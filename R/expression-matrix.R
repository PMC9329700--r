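#' Expression matrix container
#'
#' A lightweight S3 container for a gene-by-cell expression matrix: a dense
#' non-negative numeric matrix (`values`) with gene identifiers as rownames,
#' cell identifiers as colnames, optional per-cell type labels, and a layer
#' tag recording whether the values are raw counts or log1p-transformed.
#'
#' Rows are genes, columns are cells, throughout the package.
#'
#' @param values Numeric matrix, genes in rows, cells in columns. No negative
#'   entries.
#' @param gene_ids Character vector of gene identifiers (length `nrow(values)`).
#'   Defaults to existing rownames, or `g1..gm`.
#' @param cell_ids Character vector of cell identifiers (length `ncol(values)`).
#'   Defaults to existing colnames, or `c1..cn`.
#' @param labels Optional factor/character of cell-type labels, one per cell.
#' @param layer_tag `"counts"` or `"log1p"`.
#'
#' @return An object of class `expr_matrix`: the values matrix with dimnames
#'   set, plus attributes `labels` and `layer_tag`.
#' @export
#' @examples
#' x <- expression_matrix(matrix(c(5, 0, 0, 0, 0, 2), nrow = 3, byrow = TRUE))
#' dim(x)
#' observed_set(x)$d
expression_matrix <- function(values, gene_ids = NULL, cell_ids = NULL,
                              labels = NULL, layer_tag = c("counts", "log1p")) {
  layer_tag <- match.arg(layer_tag)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  m <- nrow(values)
  n <- ncol(values)
  if (is.null(gene_ids)) {
    gene_ids <- rownames(values) %||% paste0("g", seq_len(m))
  }
  if (is.null(cell_ids)) {
    cell_ids <- colnames(values) %||% paste0("c", seq_len(n))
  }
  if (length(gene_ids) != m) {
    rlang::abort("`gene_ids` must have one entry per row of `values`.",
                 class = "gnimpute_validation_error")
  }
  if (length(cell_ids) != n) {
    rlang::abort("`cell_ids` must have one entry per column of `values`.",
                 class = "gnimpute_validation_error")
  }
  if (anyNA(values) || any(values < 0)) {
    rlang::abort("Expression values must be non-negative and non-missing.",
                 class = "gnimpute_validation_error")
  }
  if (!is.null(labels)) {
    if (length(labels) != n) {
      rlang::abort("`labels` must have one entry per cell.",
                   class = "gnimpute_validation_error")
    }
    labels <- as.character(labels)
  }
  dimnames(values) <- list(as.character(gene_ids), as.character(cell_ids))
  structure(values,
            labels = labels,
            layer_tag = layer_tag,
            class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  zf <- mean(x == 0)
  cat(sprintf("<expr_matrix> %d genes x %d cells [%s], %.1f%% zeros%s\n",
              nrow(x), ncol(x), attr(x, "layer_tag"), 100 * zf,
              if (is.null(attr(x, "labels"))) "" else
                sprintf(", %d cell types", length(unique(attr(x, "labels"))))))
  invisible(x)
}

gene_ids <- function(x) rownames(x)
cell_ids <- function(x) colnames(x)

#' Cell-type labels of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of labels, or `NULL` if none attached.
#' @export
cell_labels <- function(x) attr(x, "labels")

#' Layer tag of an expression matrix
#' @param x An `expr_matrix`.
#' @return `"counts"` or `"log1p"`.
#' @export
layer_tag <- function(x) attr(x, "layer_tag")

# Subset an expr_matrix keeping metadata consistent (labels follow cells).
subset_expr <- function(x, i = NULL, j = NULL) {
  i <- i %||% seq_len(nrow(x))
  j <- j %||% seq_len(ncol(x))
  vals <- unclass(x)[i, j, drop = FALSE]
  labs <- attr(x, "labels")
  expression_matrix(vals,
                    gene_ids = rownames(x)[i], cell_ids = colnames(x)[j],
                    labels = if (!is.null(labs)) labs[j],
                    layer_tag = attr(x, "layer_tag"))
}

#' Coordinates of the observed (non-zero) entries
#'
#' The completion model treats the non-zero entries of the expression matrix
#' as trustworthy observations and everything else as missing. This returns
#' that observed index set: the coordinates of every non-zero entry and their
#' count `d`.
#'
#' @param x An `expr_matrix` (or plain matrix).
#' @return A list of class `observed_set` with integer vectors `i` (gene row
#'   index), `j` (cell column index), both 1-based, and `d = length(i)`.
#' @export
observed_set <- function(x) {
  idx <- which(unclass(x) != 0, arr.ind = TRUE)
  structure(list(i = as.integer(idx[, 1L]), j = as.integer(idx[, 2L]),
                 d = nrow(idx), dim = dim(x)),
            class = "observed_set")
}

#' @export
print.observed_set <- function(x, ...) {
  cat(sprintf("<observed_set> d = %d of %d x %d\n", x$d, x$dim[1], x$dim[2]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
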