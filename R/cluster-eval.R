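#' K-means clustering of cells
#'
#' Cells are observations and genes are features (the full gene space of the
#' log/imputed matrix, unless `pca` reduces it first). Seeding is
#' k-means++; each restart is refined with Lloyd iterations and the best of
#' `n_init` restarts by total within-cluster sum of squares is returned.
#' Deterministic given `seed`.
#'
#' @param x An [expression_matrix()] (genes x cells).
#' @param k Number of clusters, `2 <= k <= n_cells`.
#' @param seed RNG seed.
#' @param n_init Number of restarts (default 10).
#' @param pca Optional number of principal components to reduce the cells
#'   to before clustering; `NULL` (default) clusters on the full gene space.
#' @return Integer cluster labels, one per cell, with attribute `inertia`.
#' @export
kmeans_cells <- function(x, k, seed = 1L, n_init = 10L, pca = NULL) {
  n <- ncol(x)
  if (k > n) {
    rlang::abort("`k` exceeds the number of cells.",
                 class = "gnimpute_dimension_error")
  }
  stopifnot(k >= 2L)
  feats <- t(unclass(x))
  if (!is.null(pca)) {
    feats <- stats::prcomp(feats, rank. = min(pca, dim(feats)))$x
  }
  set.seed(seed)
  best <- NULL
  for (init in seq_len(n_init)) {
    centers <- kmeanspp_centers(feats, k)
    fit <- lloyd_kmeans(feats, centers)
    if (is.null(best) || fit$inertia < best$inertia) {
      best <- fit
    }
  }
  structure(as.integer(best$cluster), inertia = best$inertia)
}

# Lloyd iterations with BLAS-based assignment: the distance argmin uses
# ||x - c||^2 = ||x||^2 - 2 x.c + ||c||^2, so each sweep is one matrix
# product. Empty clusters are reseeded at the point farthest from its
# center.
lloyd_kmeans <- function(feats, centers, iter_max = 100L) {
  k <- nrow(centers)
  n <- nrow(feats)
  assign_prev <- integer(n)
  for (it in seq_len(iter_max)) {
    scores <- feats %*% t(centers) - rep(rowSums(centers^2) / 2, each = n)
    assign <- max.col(scores, ties.method = "first")
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
    sums <- rowsum(feats, assign)            # rows sorted by cluster id
    sizes <- tabulate(assign, nbins = k)
    present <- sort(unique(assign))
    centers[present, ] <- sums / sizes[present]
    empty <- which(sizes == 0L)
    for (e in empty) {
      d2 <- rowSums(feats^2) - 2 * scores[cbind(seq_len(n), assign)]
      far <- which.max(d2)
      centers[e, ] <- feats[far, ]
    }
  }
  d2 <- rowSums((feats - centers[assign, , drop = FALSE])^2)
  list(cluster = assign, inertia = sum(d2))
}

# k-means++ seeding: first center uniform, each next center drawn with
# probability proportional to the squared distance to the nearest chosen
# center.
kmeanspp_centers <- function(feats, k) {
  n <- nrow(feats)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(feats, 2L, feats[idx[1L], ], "-")^2)
  for (c in seq_len(k - 1L)) {
    if (sum(d2) <= 0) {
      remaining <- setdiff(seq_len(n), idx[seq_len(c)])
      idx[c + 1L] <- remaining[sample.int(length(remaining), 1L)]
    } else {
      idx[c + 1L] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(feats, 2L, feats[idx[c + 1L], ], "-")^2))
  }
  feats[idx, , drop = FALSE]
}

#' Raw-versus-imputed clustering comparison
#'
#' Runs [kmeans_cells()] on the raw and the imputed matrix for every seed
#' and scores each partition against the true cell-type labels with
#' [nmi()].
#'
#' @param raw,imputed [expression_matrix()] objects over the same cells.
#' @param true_labels Reference cell-type labels (defaults to the labels
#'   attached to `raw`).
#' @param k Number of clusters; defaults to the number of distinct labels.
#' @param seeds Integer vector of clustering seeds.
#' @param n_init Restarts per seed.
#' @param pca Passed to [kmeans_cells()].
#' @return A tibble of class `clustering_report`: `matrix` ("raw" or
#'   "imputed"), `seed`, `nmi`.
#' @export
clustering_report <- function(raw, imputed, true_labels = NULL, k = NULL,
                              seeds = 1:5, n_init = 10L, pca = NULL) {
  true_labels <- true_labels %||% cell_labels(raw)
  if (is.null(true_labels)) {
    rlang::abort("True cell-type labels are required.",
                 class = "gnimpute_validation_error")
  }
  k <- k %||% length(unique(true_labels))
  out <- purrr::map_dfr(seeds, function(s) {
    tibble::tibble(
      matrix = c("raw", "imputed"),
      seed = as.integer(s),
      nmi = c(nmi(kmeans_cells(raw, k, seed = s, n_init = n_init, pca = pca),
                  true_labels),
              nmi(kmeans_cells(imputed, k, seed = s, n_init = n_init, pca = pca),
                  true_labels)))
  })
  class(out) <- c("clustering_report", class(out))
  out
}

#' Summarize a clustering report
#'
#' @param object A [clustering_report()] result.
#' @param ... Unused.
#' @return Mean and sd of NMI per matrix.
#' @export
summary.clustering_report <- function(object, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(object), .data$matrix),
    mean_nmi = mean(.data$nmi), sd_nmi = stats::sd(.data$nmi),
    n_seeds = dplyr::n(), .groups = "drop")
}
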