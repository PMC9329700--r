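#' Parameters of the gamma-Poisson group simulator
#'
#' The generator emulates the Splat model of scRNA-seq counts: gamma gene
#' base means, log-normal differential-expression factors per group,
#' log-normal expected library sizes, a mean-dependent biological
#' coefficient of variation (BCV) inflated per gene by a scaled chi-square
#' draw, gamma-Poisson counts, and an optional logistic dropout layer.
#' Defaults are the published Splat defaults (the simulator's standard
#' operating point for group simulations); dropout is off by default, so
#' zeros arise from sampling alone.
#'
#' @param n_genes,n_cells Matrix dimensions.
#' @param n_groups Number of cell groups (cell types).
#' @param group_probs Group probabilities (simplex); equal by default.
#' @param mean_shape,mean_rate Gamma shape/rate of gene base means
#'   (defaults 0.6, 0.3).
#' @param out_prob Probability a gene is an expression outlier (default
#'   0.05); outlier genes have their base mean replaced by the median base
#'   mean times a log-normal factor.
#' @param out_loc,out_scale Log-normal location/scale of outlier factors
#'   (defaults 4, 0.5).
#' @param de_prob Probability a gene is differentially expressed in a group
#'   (default 0.1).
#' @param de_loc,de_scale Log-normal location/scale of DE factors (defaults
#'   0.1, 0.4).
#' @param de_down_prob Probability a DE factor is inverted to a down-factor
#'   (default 0.5).
#' @param lib_loc,lib_scale Log-normal parameters of the expected library
#'   size (defaults 11, 0.2).
#' @param bcv_common,bcv_df Common BCV and its inflation degrees of freedom
#'   (defaults 0.1, 60).
#' @param dropout_mid,dropout_shape Logistic dropout midpoint and shape;
#'   dropout is disabled when `dropout_shape` is `NULL` (the default).
#' @param seed RNG seed; identical parameter sets give bit-identical counts.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 1000L, n_cells = 100L, n_groups = 1L,
                       group_probs = NULL,
                       mean_shape = 0.6, mean_rate = 0.3,
                       out_prob = 0.05, out_loc = 4, out_scale = 0.5,
                       de_prob = 0.1, de_loc = 0.1, de_scale = 0.4,
                       de_down_prob = 0.5,
                       lib_loc = 11, lib_scale = 0.2,
                       bcv_common = 0.1, bcv_df = 60,
                       dropout_mid = 0, dropout_shape = NULL,
                       seed = 1L) {
  group_probs <- group_probs %||% rep(1 / n_groups, n_groups)
  if (length(group_probs) != n_groups ||
      abs(sum(group_probs) - 1) > 1e-9 ||
      any(group_probs < 0 | group_probs > 1)) {
    rlang::abort("`group_probs` must be a length-`n_groups` probability simplex.",
                 class = "gnimpute_validation_error")
  }
  probs <- c(de_prob, de_down_prob, out_prob)
  if (any(probs < 0 | probs > 1) || mean_rate <= 0 || mean_shape <= 0 ||
      de_scale <= 0 || lib_scale <= 0 || bcv_common <= 0 || bcv_df <= 0) {
    rlang::abort("Rates and scales must be positive; probabilities in [0, 1].",
                 class = "gnimpute_validation_error")
  }
  structure(list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
                 n_groups = as.integer(n_groups), group_probs = group_probs,
                 mean_shape = mean_shape, mean_rate = mean_rate,
                 out_prob = out_prob, out_loc = out_loc, out_scale = out_scale,
                 de_prob = de_prob, de_loc = de_loc, de_scale = de_scale,
                 de_down_prob = de_down_prob,
                 lib_loc = lib_loc, lib_scale = lib_scale,
                 bcv_common = bcv_common, bcv_df = bcv_df,
                 dropout_mid = dropout_mid, dropout_shape = dropout_shape,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate group-structured scRNA-seq counts
#'
#' Generative sequence: (1) gene base means from a gamma distribution,
#' with a fraction `out_prob` of expression outliers whose base mean is the
#' median base mean times a log-normal factor; (2) group labels from the group simplex; (3) per-gene, per-group DE
#' factors (log-normal, inverted with probability `de_down_prob`, 1 for
#' non-DE genes); (4) expected library sizes (log-normal); (5) cell-level
#' means proportional to base mean times the cell's group factor, rescaled
#' per cell to hit its library size; (6) BCV
#' `(bcv_common + 1/sqrt(mu)) * sqrt(bcv_df / chi2_g)` with a per-gene
#' chi-square draw, gamma-perturbed means, Poisson counts; (7) optional
#' logistic dropout, zeroing counts while recording the pre-dropout truth.
#'
#' @param params A [sim_params()].
#' @return A list of class `sim_result`: `counts` (an [expression_matrix()]
#'   with group labels attached), `true_means` (cell-level expected means,
#'   before noise), `pre_dropout_counts`, `dropout_mask` (logical matrix,
#'   `TRUE` where a count was zeroed by dropout; all-`FALSE` when dropout is
#'   off), `de_factors` (gene x group), `params`.
#' @export
simulate_counts <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)
  m <- p$n_genes; n <- p$n_cells
  base_means <- stats::rgamma(m, shape = p$mean_shape, rate = p$mean_rate)
  if (p$out_prob > 0) {
    is_outlier <- stats::runif(m) < p$out_prob
    out_fac <- stats::rlnorm(m, meanlog = p$out_loc, sdlog = p$out_scale)
    base_means[is_outlier] <- stats::median(base_means) * out_fac[is_outlier]
  } else {
    is_outlier <- rep(FALSE, m)
  }
  groups <- sample.int(p$n_groups, n, replace = TRUE, prob = p$group_probs)
  de_factors <- matrix(1, m, p$n_groups)
  for (g in seq_len(p$n_groups)) {
    if (p$n_groups > 1L && p$de_prob > 0) {
      is_de <- stats::runif(m) < p$de_prob
      fac <- stats::rlnorm(m, meanlog = p$de_loc, sdlog = p$de_scale)
      down <- stats::runif(m) < p$de_down_prob
      fac[down] <- 1 / fac[down]
      de_factors[is_de, g] <- fac[is_de]
    }
  }
  lib_sizes <- stats::rlnorm(n, meanlog = p$lib_loc, sdlog = p$lib_scale)
  mu <- base_means * de_factors[, groups, drop = FALSE]   # m x n, recycled by column
  mu <- sweep(mu, 2, lib_sizes / colSums(mu), "*")
  bcv_infl <- sqrt(p$bcv_df / stats::rchisq(m, df = p$bcv_df))
  bcv <- (p$bcv_common + 1 / sqrt(mu)) * bcv_infl
  shape <- 1 / bcv^2
  mu_noisy <- matrix(stats::rgamma(m * n, shape = shape, rate = shape / mu), m, n)
  counts <- matrix(stats::rpois(m * n, lambda = mu_noisy), m, n)
  pre_dropout <- counts
  dropout_mask <- matrix(FALSE, m, n)
  if (!is.null(p$dropout_shape)) {
    drop_prob <- stats::plogis(p$dropout_shape * (log(mu) - p$dropout_mid))
    dropout_mask <- matrix(stats::runif(m * n) < drop_prob, m, n)
    counts[dropout_mask] <- 0L
  }
  gene_ids <- sprintf("gene%d", seq_len(m))
  cell_ids <- sprintf("cell%d", seq_len(n))
  x <- expression_matrix(counts, gene_ids = gene_ids, cell_ids = cell_ids,
                         labels = sprintf("group%d", groups),
                         layer_tag = "counts")
  structure(list(counts = x, true_means = mu,
                 pre_dropout_counts = pre_dropout,
                 dropout_mask = dropout_mask,
                 de_factors = de_factors, groups = groups,
                 outlier_genes = is_outlier, params = p),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d genes x %d cells, %d group(s), %.1f%% zeros\n",
              nrow(x$counts), ncol(x$counts), x$params$n_groups,
              100 * mean(x$counts == 0)))
  invisible(x)
}

#' Calibrate the simulator to a target zero fraction
#'
#' Bisection on one generative knob — the library-size location (larger
#' libraries mean fewer zeros) or the dropout midpoint — until the simulated
#' overall zero fraction lands within `tol` of `target`. A fixed probe seed
#' is used for every evaluation so the bisection is deterministic.
#'
#' @param params A [sim_params()].
#' @param target Target zero fraction in (0, 1).
#' @param knob `"lib_loc"` or `"dropout_mid"`.
#' @param tol Acceptable absolute deviation (default 0.02, two percentage
#'   points).
#' @param bounds Search interval for the knob.
#' @param max_iter Bisection iteration cap.
#' @return `params` with the knob replaced by the calibrated value, and an
#'   attribute `achieved_zero_fraction` from the final probe.
#' @export
calibrate_zero_fraction <- function(params, target,
                                    knob = c("lib_loc", "dropout_mid"),
                                    tol = 0.02,
                                    bounds = NULL, max_iter = 40L) {
  stopifnot(inherits(params, "sim_params"))
  knob <- match.arg(knob)
  if (!(target > 0 && target < 1)) {
    rlang::abort("`target` must lie in (0, 1).",
                 class = "gnimpute_validation_error")
  }
  if (knob == "dropout_mid" && is.null(params$dropout_shape)) {
    rlang::abort("Enable dropout (set `dropout_shape`) before calibrating `dropout_mid`.",
                 class = "gnimpute_validation_error")
  }
  bounds <- bounds %||% switch(knob, lib_loc = c(2, 20), dropout_mid = c(-10, 15))
  zf_at <- function(value) {
    probe <- params
    probe[[knob]] <- value
    mean(simulate_counts(probe)$counts == 0)
  }
  # zero fraction falls as lib_loc grows and rises with dropout_mid
  sgn <- if (knob == "lib_loc") -1 else 1
  f <- function(v) sgn * (zf_at(v) - target)     # increasing in v
  # fixed-point shortcut: current params may already hit the target
  current <- params[[knob]]
  zf_cur <- zf_at(current)
  if (abs(zf_cur - target) <= tol / 2) {
    attr(params, "achieved_zero_fraction") <- zf_cur
    return(params)
  }
  lo <- bounds[1]; hi <- bounds[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0 || fhi < 0) {
    rlang::abort(
      sprintf("Target zero fraction %.3f unreachable in [%g, %g]: bracket values %.3f and %.3f.",
              target, lo, hi, sgn * flo + target, sgn * fhi + target),
      class = "gnimpute_calibration_error")
  }
  mid <- current
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= tol / 2 || (hi - lo) < 1e-4) break
    if (fm < 0) lo <- mid else hi <- mid
  }
  out <- params
  out[[knob]] <- mid
  achieved <- zf_at(mid)
  if (abs(achieved - target) > tol) {
    rlang::abort(
      sprintf("Calibration stalled: achieved %.3f for target %.3f.", achieved, target),
      class = "gnimpute_calibration_error")
  }
  attr(out, "achieved_zero_fraction") <- achieved
  out
}
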