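#' Configuration for Gauss-Newton low-rank completion
#'
#' @param rank_c Completion rank: the known number of cell types, or 5 when
#'   the cell types are unknown (the usual working assumption for a typical
#'   scRNA-seq experiment).
#' @param beta Scalar in (0, 2] parameterizing the family of update rules;
#'   1 (the default) gives the plain Gauss-Newton update and performed best
#'   empirically.
#' @param max_outer_iters Maximum number of outer Gauss-Newton iterations.
#' @param outer_tol Stop when the relative change of the observed-entry
#'   residual norm between consecutive iterations falls below this.
#' @param inner_max_iters Iteration cap for the LSQR inner solver (default
#'   250). The update is a truncated Gauss-Newton step: on densely observed
#'   matrices the linearized system is inconsistent and LSQR's asymptotic
#'   least-squares test converges slowly, while the outer iteration only
#'   needs an approximate step, so a modest fixed budget is both faster and
#'   sufficient; raise it (up to `10 * rank_c * (m + n)`) for
#'   high-precision completion of exactly low-rank matrices.
#' @param inner_tol LSQR atol/btol stopping tolerance (default 1e-4). The
#'   outer loop only needs an inexact step, so a moderate inner tolerance
#'   loses nothing; tighten it together with `outer_tol` for
#'   machine-precision completion of exactly low-rank matrices.
#' @param inner_start `"warm"` starts LSQR at `(1 + beta)/2 * (U_t, V_t)`, so
#'   LSQR's implicit minimum-norm solution is the minimum-norm *increment*
#'   (the classical Gauss-Newton step). `"zero"` starts at the origin,
#'   selecting the minimum-norm factor pair itself.
#' @param literal_eps Use the measurement-with-shift variant in which the
#'   beta-scaled current-iterate term also appears inside the measurement
#'   vector (kept for comparison; the default form is self-consistent).
#' @param damp Optional LSQR damping (Tikhonov) parameter; 0 disables it.
#' @param seed Seed for any randomized fallback; the default pipeline is
#'   fully deterministic and does not consume it.
#' @return A list of class `gn_config`.
#' @export
gn_config <- function(rank_c = 5L, beta = 1, max_outer_iters = 50L,
                      outer_tol = 1e-4, inner_max_iters = 250L,
                      inner_tol = 1e-4, inner_start = c("warm", "zero"),
                      literal_eps = FALSE, damp = 0, seed = 1L) {
  inner_start <- match.arg(inner_start)
  if (!(beta > 0 && beta <= 2)) {
    rlang::abort("`beta` must lie in (0, 2].", class = "gnimpute_validation_error")
  }
  if (rank_c < 1) {
    rlang::abort("`rank_c` must be a positive integer.",
                 class = "gnimpute_validation_error")
  }
  structure(list(rank_c = as.integer(rank_c), beta = beta,
                 max_outer_iters = as.integer(max_outer_iters),
                 outer_tol = outer_tol, inner_max_iters = inner_max_iters,
                 inner_tol = inner_tol, inner_start = inner_start,
                 literal_eps = literal_eps, damp = damp, seed = seed),
            class = "gn_config")
}

#' Truncated-SVD initialization of the factor pair
#'
#' Computes the rank-r truncated SVD of the zero-filled expression matrix
#' (no centering or rescaling) via an eigendecomposition of the smaller Gram
#' matrix, and splits the singular values symmetrically:
#' `U = U_r diag(sqrt(s))`, `V = V_r diag(sqrt(s))`, so `U V'` is a best
#' rank-r approximation in Frobenius norm. Fully deterministic; singular
#' vector signs are fixed by making the largest-magnitude loading positive.
#'
#' @param x Matrix (or [expression_matrix()]).
#' @param r Rank, `1 <= r <= min(dim(x))`.
#' @return List of class `factor_pair` with matrices `U` (m x r), `V`
#'   (n x r) and `r`.
#' @export
truncated_svd_init <- function(x, r) {
  x <- unclass(x)
  m <- nrow(x); n <- ncol(x)
  if (r > min(m, n)) {
    rlang::abort("Rank exceeds the matrix dimensions.",
                 class = "gnimpute_dimension_error")
  }
  if (n <= m) {
    eg <- eigen(crossprod(x), symmetric = TRUE)
    ev <- pmax(eg$values[seq_len(r)], 0)
    sv <- sqrt(ev)
    Vr <- eg$vectors[, seq_len(r), drop = FALSE]
    Ur <- x %*% Vr
    pos <- sv > sv[1] * 1e-12 + 1e-300
    Ur[, pos] <- sweep(Ur[, pos, drop = FALSE], 2, sv[pos], "/")
    Ur[, !pos] <- 0
  } else {
    eg <- eigen(tcrossprod(x), symmetric = TRUE)
    ev <- pmax(eg$values[seq_len(r)], 0)
    sv <- sqrt(ev)
    Ur <- eg$vectors[, seq_len(r), drop = FALSE]
    Vr <- crossprod(x, Ur)
    pos <- sv > sv[1] * 1e-12 + 1e-300
    Vr[, pos] <- sweep(Vr[, pos, drop = FALSE], 2, sv[pos], "/")
    Vr[, !pos] <- 0
  }
  # deterministic sign convention per component
  for (k in seq_len(r)) {
    piv <- which.max(abs(Vr[, k]))
    if (Vr[piv, k] < 0) {
      Vr[, k] <- -Vr[, k]
      Ur[, k] <- -Ur[, k]
    }
  }
  root <- sqrt(sv)
  structure(list(U = sweep(Ur, 2, root, "*"),
                 V = sweep(Vr, 2, root, "*"),
                 r = as.integer(r)),
            class = "factor_pair")
}

#' Linearized measurement operator at the current factor pair
#'
#' The Gauss-Newton linearization of the factorized completion objective
#' needs, per inner iteration, the linear map taking a stacked candidate
#' pair `(U, V)` to the length-d vector of entries of
#' `U_t V' + U V_t'` at the observed coordinates, together with its adjoint.
#' Both are returned matrix-free as closures over the current pair.
#'
#' The stacked parameter vector is `c(vec(U), vec(V))`, column-major, of
#' length `rank * (m + n)`.
#'
#' @param pair A `factor_pair` (the current iterate `(U_t, V_t)`).
#' @param omega An [observed_set()].
#' @return List with `forward(z)` (length-d), `adjoint(w)` (length
#'   `rank * (m + n)`), and the dimensions `m`, `n`, `r`, `d`.
#' @export
gn_linear_operator <- function(pair, omega) {
  Ut <- pair$U; Vt <- pair$V
  m <- nrow(Ut); n <- nrow(Vt); r <- pair$r
  i <- omega$i; j <- omega$j
  nu <- m * r
  unpack <- function(z) {
    list(U = matrix(z[seq_len(nu)], m, r),
         V = matrix(z[nu + seq_len(n * r)], n, r))
  }
  forward <- function(z) {
    uv <- unpack(z)
    sampled_bilinear(Ut, uv$V, i, j) + sampled_bilinear(uv$U, Vt, i, j)
  }
  adjoint <- function(w) {
    dU <- accumulate_outer(w, Vt, i, j, m)
    dV <- accumulate_outer(w, Ut, j, i, n)
    c(dU, dV)
  }
  list(forward = forward, adjoint = adjoint, unpack = unpack,
       m = m, n = n, r = r, d = omega$d)
}

#' One Gauss-Newton update of the factor pair
#'
#' Linearizes the observed-entry least-squares objective at the current pair
#' (dropping the second-order cross term), solves the resulting linear
#' least-squares problem with LSQR, and combines the solution with the
#' current iterate according to the beta update family. With `beta = 1` the
#' returned pair is exactly the inner solution.
#'
#' @param pair Current `factor_pair`.
#' @param x Expression matrix being completed.
#' @param omega Its [observed_set()].
#' @param cfg A [gn_config()].
#' @return The updated `factor_pair`, with attributes `inner_iters` and
#'   `inner_resid` from the LSQR solve.
#' @export
gn_step <- function(pair, x, omega, cfg = gn_config(rank_c = pair$r)) {
  op <- gn_linear_operator(pair, omega)
  sx <- unclass(x)[cbind(omega$i, omega$j)]
  st <- sampled_bilinear(pair$U, pair$V, omega$i, omega$j)
  beta <- cfg$beta
  # measurement vector: observed values plus the beta-scaled current-iterate
  # term moved to the right-hand side (self-consistent form); the literal
  # variant carries the shift inside the measurement as well
  b <- if (cfg$literal_eps) sx + 2 * beta * st else sx + beta * st
  p <- op$r * (op$m + op$n)
  itnlim <- min(cfg$inner_max_iters %||% 250L,
                max(10L * op$r * (op$m + op$n), 100L))
  if (cfg$inner_start == "warm") {
    z0 <- (1 + beta) / 2 * c(pair$U, pair$V)
    rhs <- b - (1 + beta) * st
    sol <- lsqr_solve(op$forward, op$adjoint, rhs, p,
                      atol = cfg$inner_tol, btol = cfg$inner_tol,
                      itnlim = itnlim, damp = cfg$damp)
    z <- z0 + sol$x
  } else {
    sol <- lsqr_solve(op$forward, op$adjoint, b, p,
                      atol = cfg$inner_tol, btol = cfg$inner_tol,
                      itnlim = itnlim, damp = cfg$damp)
    z <- sol$x
  }
  if (!all(is.finite(z))) {
    rlang::abort(
      sprintf("Inner least-squares solve produced non-finite values at LSQR iteration %d.",
              sol$itn),
      class = "gnimpute_numerical_error")
  }
  prime <- op$unpack(z)
  out <- structure(list(U = (1 - beta) / 2 * pair$U + prime$U,
                        V = (1 - beta) / 2 * pair$V + prime$V,
                        r = pair$r),
                   class = "factor_pair")
  attr(out, "inner_iters") <- sol$itn
  attr(out, "inner_resid") <- sol$resid_norm
  out
}

#' Impute dropout zeros by Gauss-Newton low-rank completion
#'
#' Treats the non-zero entries of a log-transformed expression matrix as
#' trustworthy observations and completes the matrix under a rank constraint
#' equal to the (known or assumed) number of cell types. The factor pair is
#' initialized by truncated SVD of the zero-filled matrix and refined by
#' iterated Gauss-Newton linearization, each step solved with LSQR. The
#' completed matrix is clamped at zero (expression cannot be negative) and
#' the observed entries are restored exactly — only missing values are
#' imputed.
#'
#' @param x An [expression_matrix()], normally `layer_tag = "log1p"`; raw
#'   counts are accepted with a warning.
#' @param cfg A [gn_config()].
#' @return An object of class `gn_imputation`: list with `x_star` (the
#'   imputed `expr_matrix`), `factors` (final `factor_pair`),
#'   `residual_trace` (observed-entry residual norm per iteration, index 0 =
#'   after initialization), `n_iters`, `converged`, `config`.
#' @export
#' @examples
#' set.seed(1)
#' truth <- abs(matrix(rnorm(60), 10, 6)) + 0.1
#' truth <- truth %*% matrix(1, 6, 1) %*% matrix(1, 1, 6) / 6  # rank 1
#' x <- truth; x[sample(60, 12)] <- 0
#' fit <- impute(expression_matrix(x, layer_tag = "log1p"),
#'               gn_config(rank_c = 1))
#' max(abs(fit$x_star - truth))
impute <- function(x, cfg = gn_config()) {
  stopifnot(inherits(cfg, "gn_config"))
  if (layer_tag(x) == "counts") {
    rlang::warn("Imputing raw counts; log-transformed input is recommended.")
  }
  omega <- observed_set(x)
  if (omega$d == 0L) {
    rlang::abort("The matrix has no observed (non-zero) entries.",
                 class = "gnimpute_empty_observation_error")
  }
  m <- nrow(x); n <- ncol(x)
  if (cfg$rank_c > min(m, n)) {
    rlang::abort("`rank_c` exceeds the matrix dimensions.",
                 class = "gnimpute_dimension_error")
  }
  sx <- unclass(x)[cbind(omega$i, omega$j)]
  sx_norm <- sqrt(sum(sx^2))
  obs_resid <- function(pair) {
    sqrt(sum((sampled_bilinear(pair$U, pair$V, omega$i, omega$j) - sx)^2))
  }
  pair <- truncated_svd_init(x, cfg$rank_c)
  res <- obs_resid(pair)
  trace <- res
  converged <- FALSE
  iters <- 0L
  for (t in seq_len(cfg$max_outer_iters)) {
    pair <- gn_step(pair, x, omega, cfg)
    res_new <- obs_resid(pair)
    trace <- c(trace, res_new)
    iters <- t
    if (res_new <= 1e-10 * sx_norm) {        # residual floor: exact fit
      converged <- TRUE
      break
    }
    if (abs(res - res_new) / max(res, 1e-12) < cfg$outer_tol) {
      converged <- TRUE
      res <- res_new
      break
    }
    res <- res_new
  }
  xs <- pair$U %*% t(pair$V)
  xs[xs < 0] <- 0                            # expression is non-negative
  xs[cbind(omega$i, omega$j)] <- sx          # observed entries are kept
  x_star <- expression_matrix(xs, gene_ids = rownames(x),
                              cell_ids = colnames(x),
                              labels = cell_labels(x),
                              layer_tag = layer_tag(x))
  structure(list(x_star = x_star, factors = pair,
                 residual_trace = trace, n_iters = iters,
                 converged = converged, config = cfg, d = omega$d),
            class = "gn_imputation")
}

#' @export
print.gn_imputation <- function(x, ...) {
  cat(sprintf(
    "<gn_imputation> rank %d, beta %g: %d iterations (%s), residual %.4g -> %.4g\n",
    x$config$rank_c, x$config$beta, x$n_iters,
    if (x$converged) "converged" else "not converged",
    x$residual_trace[1], x$residual_trace[length(x$residual_trace)]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-iteration residual trace of a completion fit
#'
#' @param x A `gn_imputation` object.
#' @param ... Unused.
#' @return A tibble with columns `iter` (0 = after SVD initialization) and
#'   `observed_residual` (Euclidean norm over the observed entries).
#' @export
tidy.gn_imputation <- function(x, ...) {
  tibble::tibble(iter = seq_along(x$residual_trace) - 1L,
                 observed_residual = x$residual_trace)
}

#' One-row summary of a completion fit
#'
#' @param x A `gn_imputation` object.
#' @param ... Unused.
#' @return A one-row tibble: rank, beta, iterations, convergence flag,
#'   initial and final observed residual, imputed-entry count.
#' @export
glance.gn_imputation <- function(x, ...) {
  tibble::tibble(rank_c = x$config$rank_c, beta = x$config$beta,
                 n_iters = x$n_iters, converged = x$converged,
                 initial_residual = x$residual_trace[1],
                 final_residual = x$residual_trace[length(x$residual_trace)],
                 n_observed = x$d,
                 n_imputed = sum(unclass(x$x_star) != 0) - x$d)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the observed-entry residual trace
#'
#' @param object A `gn_imputation` object.
#' @param ... Unused.
#' @return A ggplot: residual norm (log scale) against outer iteration.
#' @export
autoplot.gn_imputation <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$iter, y = .data$observed_residual)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Gauss-Newton iteration",
                  y = "Observed-entry residual norm") +
    ggplot2::theme_minimal()
}
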