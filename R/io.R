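#' Read a gene-by-cell expression matrix
#'
#' Two on-disk layouts are supported:
#'
#' * `format = "mtx"`: Matrix Market coordinate file (1-based indices on
#'   disk), with required sidecars `<stem>.genes.tsv` and `<stem>.cells.tsv`
#'   (one id per line, no header) and an optional `<stem>.labels.tsv`
#'   (tab-separated, header `cell_id	label`).
#' * `format = "csv"`: dense CSV with gene ids in the first column and cell
#'   ids in the header row.
#'
#' Explicitly stored zeros in a Matrix Market file are normalized away on
#' load, so the observed set is well defined: sparse zeros and stored zeros
#' are indistinguishable in the returned matrix.
#'
#' @param path Path to the `.mtx` or `.csv` file.
#' @param format `"mtx"` or `"csv"`; inferred from the file extension when
#'   missing.
#' @param transpose If `TRUE`, the file stores cells in rows and is
#'   transposed on load.
#' @return An [expression_matrix()] with `layer_tag = "counts"`.
#' @export
read_matrix <- function(path, format = c("auto", "mtx", "csv"),
                        transpose = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "csv"
  }
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path), class = "gnimpute_io_error")
  }
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    genes_path <- paste0(stem, ".genes.tsv")
    cells_path <- paste0(stem, ".cells.tsv")
    for (p in c(genes_path, cells_path)) {
      if (!file.exists(p)) {
        rlang::abort(sprintf("Missing sidecar file: %s", p),
                     class = "gnimpute_format_error")
      }
    }
    mm <- Matrix::drop0(Matrix::readMM(path))
    gene_ids <- readLines(genes_path)
    cell_ids <- readLines(cells_path)
    labels <- NULL
    labels_path <- paste0(stem, ".labels.tsv")
    if (file.exists(labels_path)) {
      lab_df <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
      labels <- lab_df$label[match(cell_ids, lab_df$cell_id)]
    }
    values <- as.matrix(mm)
    if (transpose) {
      values <- t(values)
    }
    x <- expression_matrix(values, gene_ids = gene_ids, cell_ids = cell_ids,
                           labels = labels, layer_tag = "counts")
  } else {
    raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
    gene_ids <- raw[[1L]]
    body <- raw[, -1L, drop = FALSE]
    values <- suppressWarnings(
      matrix(as.numeric(as.matrix(body)), nrow = nrow(body))
    )
    if (anyNA(values)) {
      bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
      rlang::abort(
        sprintf("Non-numeric value at row %d, column %d of %s",
                bad[1L], bad[2L], path),
        class = "gnimpute_parse_error")
    }
    if (transpose) {
      x <- expression_matrix(t(values), gene_ids = colnames(body),
                             cell_ids = gene_ids, layer_tag = "counts")
    } else {
      x <- expression_matrix(values, gene_ids = gene_ids,
                             cell_ids = colnames(body), layer_tag = "counts")
    }
  }
  x
}

#' Write an expression matrix
#'
#' The inverse of [read_matrix()]: `mtx` output is 1-based Matrix Market
#' coordinate format with `<stem>.genes.tsv` / `<stem>.cells.tsv` sidecars
#' (and `<stem>.labels.tsv` when labels are attached); `csv` output is a
#' dense table with gene ids in column 1 and cell ids in the header.
#'
#' @param x An [expression_matrix()].
#' @param path Output path (`.mtx` or `.csv`).
#' @param format `"mtx"` or `"csv"`; inferred from the extension when missing.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, format = c("auto", "mtx", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "csv"
  }
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    sp <- Matrix::drop0(methods::as(unclass(x), "CsparseMatrix"))
    Matrix::writeMM(sp, path)
    writeLines(rownames(x), paste0(stem, ".genes.tsv"))
    writeLines(colnames(x), paste0(stem, ".cells.tsv"))
    labs <- cell_labels(x)
    if (!is.null(labs)) {
      utils::write.table(
        data.frame(cell_id = colnames(x), label = labs),
        paste0(stem, ".labels.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else {
    df <- data.frame(gene_id = rownames(x), unclass(x), check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
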