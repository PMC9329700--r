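#' Paired estimated/held-out value vectors at masked coordinates
#'
#' Masked-recovery metrics compare the imputed values at the masked
#' coordinates with the held-out truth. This helper validates the pairing.
#'
#' @param estimated,truth Numeric vectors of equal length `k >= 1`.
#' @return A list of class `masked_pair` with `estimated`, `truth`, `k`.
#' @export
masked_pair <- function(estimated, truth) {
  if (length(estimated) != length(truth) || length(truth) < 1L) {
    rlang::abort("`estimated` and `truth` must be non-empty vectors of equal length.",
                 class = "gnimpute_validation_error")
  }
  structure(list(estimated = as.numeric(estimated),
                 truth = as.numeric(truth),
                 k = length(truth)),
            class = "masked_pair")
}

as_masked_pair <- function(p) {
  if (inherits(p, "masked_pair")) p else masked_pair(p$estimated, p$truth)
}

#' Frobenius error of masked-entry recovery
#'
#' The squared recovery error, `sum((estimated - truth)^2) / denom`, with no
#' square root — a relative squared error. For per-cell reporting `denom`
#' defaults to the sum of squared held-out truth values of the same pair, so
#' values are comparable across cells; pass the global reference sum of
#' squares for the pooled variant.
#'
#' @param p A [masked_pair()] (or list with `estimated`/`truth`).
#' @param denom Positive reference sum of squares; defaults to
#'   `sum(truth^2)`.
#' @return Non-negative scalar; 0 iff the vectors coincide.
#' @export
frobenius_error <- function(p, denom = NULL) {
  p <- as_masked_pair(p)
  denom <- denom %||% sum(p$truth^2)
  if (!is.numeric(denom) || denom <= 0) {
    rlang::abort("Frobenius error is undefined for a zero reference norm.",
                 class = "gnimpute_undefined_metric_error")
  }
  sum((p$estimated - p$truth)^2) / denom
}

#' Pearson correlation between imputed and held-out values
#'
#' @param p A [masked_pair()].
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_cor <- function(p) {
  p <- as_masked_pair(p)
  se <- stats::sd(p$estimated)
  st <- stats::sd(p$truth)
  if (p$k < 2L || is.na(se) || is.na(st) || se == 0 || st == 0) {
    rlang::abort("Correlation is undefined when either vector is constant.",
                 class = "gnimpute_undefined_metric_error")
  }
  stats::cor(p$estimated, p$truth)
}

#' Mean squared error over masked coordinates
#' @param p A [masked_pair()].
#' @return `mean((estimated - truth)^2)`.
#' @export
mse <- function(p) {
  p <- as_masked_pair(p)
  mean((p$estimated - p$truth)^2)
}

#' Mean absolute error over masked coordinates
#' @param p A [masked_pair()].
#' @return `mean(abs(estimated - truth))`.
#' @export
l1_error <- function(p) {
  p <- as_masked_pair(p)
  mean(abs(p$estimated - p$truth))
}

#' Normalized mutual information between two partitions
#'
#' `2 I(U, V) / (H(U) + H(V))` from the label contingency table, natural-log
#' entropies (the base cancels). Symmetric and invariant to relabeling.
#' When both partitions are single-class they are identical as partitions
#' and the value is 1 by convention.
#'
#' @param pred_labels,true_labels Equal-length label vectors.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(pred_labels, true_labels) {
  if (length(pred_labels) != length(true_labels) || length(true_labels) < 1L) {
    rlang::abort("Label vectors must be non-empty and of equal length.",
                 class = "gnimpute_validation_error")
  }
  tab <- table(pred_labels, true_labels)
  n <- sum(tab)
  pu <- rowSums(tab) / n
  pv <- colSums(tab) / n
  hu <- -sum(pu[pu > 0] * log(pu[pu > 0]))
  hv <- -sum(pv[pv > 0] * log(pv[pv > 0]))
  if (hu + hv == 0) {
    return(1)
  }
  pj <- tab / n
  nz <- pj > 0
  mi <- sum(pj[nz] * log(pj[nz] / (pu[row(pj)[nz]] * pv[col(pj)[nz]])))
  max(0, min(1, 2 * mi / (hu + hv)))
}

#' Coefficient of variation of a gene within a cell type
#'
#' Two conventions: `as_printed` returns `|mu / sigma|` (mean over spread,
#' the package default for fidelity with the evaluation it reproduces);
#' `standard` returns the conventional `|sigma / mu|`. `sigma` is the
#' population standard deviation by default.
#'
#' @param values Expression values of one gene across the cells of one type
#'   (callers computing the before-imputation statistic pass only the
#'   non-zero cells; after imputation, all cells of the type).
#' @param mode `"as_printed"` or `"standard"`.
#' @param sample_sd Use the sample (n-1) standard deviation instead of the
#'   population one.
#' @return Non-negative scalar, or error when the chosen denominator is 0.
#' @export
coefficient_of_variation <- function(values, mode = c("as_printed", "standard"),
                                     sample_sd = FALSE) {
  mode <- match.arg(mode)
  if (length(values) < 2L) {
    rlang::abort("At least two cells are needed for a coefficient of variation.",
                 class = "gnimpute_validation_error")
  }
  mu <- mean(values)
  sg <- stats::sd(values)
  if (!sample_sd) {
    sg <- sg * sqrt((length(values) - 1) / length(values))
  }
  if (mode == "as_printed") {
    if (sg == 0) {
      rlang::abort("CV (mean/sd form) is undefined for constant values.",
                   class = "gnimpute_undefined_metric_error")
    }
    abs(mu / sg)
  } else {
    if (mu == 0) {
      rlang::abort("CV (sd/mean form) is undefined for zero-mean values.",
                   class = "gnimpute_undefined_metric_error")
    }
    abs(sg / mu)
  }
}

#' Per-gene coefficient-of-variation table for one or all cell types
#'
#' For every gene and cell type, the before statistic is computed on the
#' gene's non-zero values in cells of the type in `before` and the after
#' statistic on all cells of the type in `after`. Genes whose statistic is
#' undefined (constant values, or fewer than two usable cells) get `NA`.
#'
#' @param before,after [expression_matrix()] objects sharing genes, cells
#'   and labels (`before` is typically the raw log matrix, `after` the
#'   imputed one).
#' @param mode Passed to [coefficient_of_variation()].
#' @return A tibble: `gene_id`, `cell_type`, `cv_before`, `cv_after`,
#'   `mean_nonzero` (mean of the gene's non-zero before-values in the type,
#'   the usual color scale for this comparison), `n_cells`,
#'   `n_nonzero_cells`.
#' @export
cv_table <- function(before, after, mode = c("as_printed", "standard")) {
  mode <- match.arg(mode)
  labs <- cell_labels(before)
  if (is.null(labs)) {
    rlang::abort("`before` must carry cell-type labels.",
                 class = "gnimpute_validation_error")
  }
  stopifnot(identical(dim(before), dim(after)))
  safe_cv <- function(v) {
    if (length(v) < 2L) return(NA_real_)
    tryCatch(coefficient_of_variation(v, mode = mode),
             gnimpute_undefined_metric_error = function(e) NA_real_)
  }
  purrr::map_dfr(unique(labs), function(type) {
    jj <- which(labs == type)
    bv <- unclass(before)[, jj, drop = FALSE]
    av <- unclass(after)[, jj, drop = FALSE]
    tibble::tibble(
      gene_id = rownames(before),
      cell_type = type,
      cv_before = unname(apply(bv, 1L, function(v) safe_cv(v[v != 0]))),
      cv_after = unname(apply(av, 1L, safe_cv)),
      mean_nonzero = unname(apply(bv, 1L, function(v) {
        if (any(v != 0)) mean(v[v != 0]) else NA_real_
      })),
      n_cells = length(jj),
      n_nonzero_cells = rowSums(bv != 0))
  })
}

#' Maximal information coefficient (MIC)
#'
#' A MINE-style statistic for general (including non-linear) pairwise
#' dependence: over all grids with `a * b <= n^alpha` cells, the mutual
#' information of the induced 2D histogram normalized by `log(min(a, b))`,
#' maximized. One axis is equipartitioned; the other is optimized by the
#' approximate dynamic program over superclumps, and both orientations are
#' tried. Noiseless functional relationships score 1; independent noise
#' scores near 0.
#'
#' @param xvals,yvals Numeric vectors, equal length `n >= 10`.
#' @param alpha Grid-size exponent (default 0.6, the original MINE
#'   recommendation).
#' @param max_clumps_factor Superclump budget per x-bin count (default 15).
#' @return MIC in `[0, 1]`; 0 when either input is constant.
#' @export
mic <- function(xvals, yvals, alpha = 0.6, max_clumps_factor = 15) {
  n <- length(xvals)
  if (length(yvals) != n || n < 10L) {
    rlang::abort("`xvals` and `yvals` must have equal length >= 10.",
                 class = "gnimpute_validation_error")
  }
  if (length(unique(xvals)) < 2L || length(unique(yvals)) < 2L) {
    return(0)
  }
  B <- max(n^alpha, 4)
  best <- 0
  for (orient in 1:2) {
    xx <- if (orient == 1) xvals else yvals
    yy <- if (orient == 1) yvals else xvals
    for (b in 2:max(2L, floor(B / 2))) {
      maxa <- floor(B / b)
      if (maxa < 2) break
      q <- equifreq_bins(yy, b)
      if (length(unique(q)) < 2L) next
      Ivals <- optimize_axis_mi(xx, q, maxa, max_clumps_factor)
      if (!length(Ivals)) next
      ls <- seq_along(Ivals) + 1L          # number of x bins per entry
      scores <- cummax(Ivals) / log(pmin(ls, length(unique(q))))
      best <- max(best, max(scores, na.rm = TRUE))
    }
  }
  max(0, min(1, best))
}

# Equal-frequency binning that never splits ties: bin by rank quantile of
# the midranked values.
equifreq_bins <- function(v, b) {
  r <- rank(v, ties.method = "average")
  as.integer(cut(r, breaks = stats::quantile(r, probs = seq(0, 1, length.out = b + 1)),
                 include.lowest = TRUE, labels = FALSE))
}

# Approximate MINE x-axis optimization. Given y-bin labels q, returns the
# maximal H(P) - H(P,Q) + H(Q) (= mutual information) achievable with l =
# 2..maxa x-axis interval bins, where candidate cut points are superclump
# boundaries. Dynamic program over cumulative y-class counts.
optimize_axis_mi <- function(x, q, maxa, clump_factor) {
  ord <- order(x)
  xs <- x[ord]
  qs <- q[ord]
  n <- length(xs)
  # clumps: runs of identical x values must never be split
  new_clump <- c(TRUE, xs[-1] != xs[-n])
  clump_id <- cumsum(new_clump)
  k <- clump_id[n]
  ends <- which(c(new_clump[-1], TRUE))       # last index of each clump
  # superclumps: cap candidate cuts at clump_factor * maxa by merging
  khat <- max(2L, as.integer(clump_factor * maxa))
  if (k > khat) {
    take <- unique(ends[round(seq(1, k, length.out = khat))])
    ends <- take
    k <- length(ends)
  }
  nb <- max(qs)
  # cum[q, t]: count of class q within the first t superclumps
  cum <- matrix(0, nb, k)
  prev <- 0L
  counts <- numeric(nb)
  for (t in seq_len(k)) {
    seg <- qs[(prev + 1L):ends[t]]
    tab <- tabulate(seg, nbins = nb)
    counts <- counts + tab
    cum[, t] <- counts
    prev <- ends[t]
  }
  ct <- ends                                   # cumulative point counts
  hq_all <- ent(cum[, k] / n)
  # F[t, l]: max of H(P) - H(P,Q) over partitions of the first t superclumps
  # into exactly l interval bins
  maxl <- min(maxa, k)
  if (maxl < 2) return(numeric(0))
  Fm <- matrix(-Inf, k, maxl)
  Fm[, 1L] <- vapply(seq_len(k), function(t) -ent(cum[, t] / ct[t]), 0)
  # tail-segment entropies H(Q on clumps (s, t]), all s < t, vectorized:
  # hseg_list[[t]][s] = seg_n * H of the segment = sum over classes of
  # -n_q log(n_q / seg_n)
  for (l in 2:maxl) {
    for (t in l:k) {
      s <- (l - 1L):(t - 1L)
      seg_counts <- cum[, t] - cum[, s, drop = FALSE]   # nb x |s|
      seg_n <- ct[t] - ct[s]
      pl <- seg_counts * log(seg_counts)
      pl[seg_counts == 0] <- 0
      nh <- seg_n * log(seg_n) - colSums(pl)            # seg_n * H(segment)
      Fm[t, l] <- max((ct[s] * Fm[s, l - 1L] - nh) / ct[t])
    }
  }
  hq_all + Fm[k, 2:maxl]
}

ent <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}
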