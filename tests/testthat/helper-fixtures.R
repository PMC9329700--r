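# Shared fixture builders. Everything is generated in code at test time.

# plain numeric matrix view of an expr_matrix (drops class and metadata)
plain <- function(x) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(y), dimnames = dimnames(y))
  y
}

# random sparse non-negative count matrix
random_count_matrix <- function(m, n, density = 0.5, seed = 1L,
                                labels = NULL) {
  set.seed(seed)
  vals <- matrix(0, m, n)
  nz <- sample.int(m * n, round(density * m * n))
  vals[nz] <- rpois(length(nz), 5) + 1
  expression_matrix(vals, labels = labels, layer_tag = "counts")
}

# strictly positive planted low-rank matrix with a fraction of entries zeroed
planted_lowrank <- function(m, n, r, zero_frac, seed = 1L) {
  set.seed(seed)
  A <- matrix(abs(rnorm(m * r)) + 0.1, m, r)
  B <- matrix(abs(rnorm(n * r)) + 0.1, n, r)
  truth <- A %*% t(B)
  hidden <- sample.int(m * n, round(zero_frac * m * n))
  observed <- truth
  observed[hidden] <- 0
  list(truth = truth, hidden = hidden,
       x = expression_matrix(observed, layer_tag = "log1p"))
}

# dense nonlinear least-squares oracle: minimize the observed-entry residual
# over (U, V) directly with L-BFGS, multi-started from the given pair and
# jittered copies of it (plain first-order descent can stall in shallow
# saddles that the stated start sits near)
nls_completion_oracle <- function(x, omega, pair0, n_jitter = 5L) {
  m <- nrow(x); n <- ncol(x); r <- pair0$r
  sx <- unclass(x)[cbind(omega$i, omega$j)]
  obj <- function(z) {
    U <- matrix(z[seq_len(m * r)], m, r)
    V <- matrix(z[m * r + seq_len(n * r)], n, r)
    pred <- rowSums(U[omega$i, , drop = FALSE] * V[omega$j, , drop = FALSE])
    sum((pred - sx)^2)
  }
  grad <- function(z) {
    U <- matrix(z[seq_len(m * r)], m, r)
    V <- matrix(z[m * r + seq_len(n * r)], n, r)
    res <- rowSums(U[omega$i, , drop = FALSE] * V[omega$j, , drop = FALSE]) - sx
    dU <- matrix(0, m, r); dV <- matrix(0, n, r)
    for (k in seq_along(res)) {
      dU[omega$i[k], ] <- dU[omega$i[k], ] + 2 * res[k] * V[omega$j[k], ]
      dV[omega$j[k], ] <- dV[omega$j[k], ] + 2 * res[k] * U[omega$i[k], ]
    }
    c(dU, dV)
  }
  z0 <- c(pair0$U, pair0$V)
  starts <- c(list(z0),
              lapply(seq_len(n_jitter), function(k) {
                z0 + stats::rnorm(length(z0), sd = 0.05 * k * (1 + mean(abs(z0))))
              }))
  best <- Inf
  for (z in starts) {
    fit <- stats::optim(z, obj, grad, method = "L-BFGS-B",
                        control = list(maxit = 5000, factr = 10))
    best <- min(best, fit$value)
  }
  sqrt(best)
}

# exhaustive small-n MIC oracle for the MINE-style estimator: one axis is
# equifrequency-binned (same convention as the estimator: quantile cut of
# average ranks), the other axis is optimized by brute-force enumeration of
# every interval partition — no dynamic programming, no superclumps. Both
# orientations are tried over all grid shapes with a*b <= n^alpha.
mic_exhaustive_oracle <- function(x, y, alpha = 0.6) {
  n <- length(x)
  B <- max(n^alpha, 4)
  equifreq <- function(v, b) {
    r <- rank(v, ties.method = "average")
    as.integer(cut(r, stats::quantile(r, seq(0, 1, length.out = b + 1)),
                   include.lowest = TRUE, labels = FALSE))
  }
  grid_mi <- function(px, py) {
    tab <- table(px, py)
    pj <- tab / n
    pr <- rowSums(pj); pc <- colSums(pj)
    nzc <- pj > 0
    sum(pj[nzc] * log(pj[nzc] / (pr[row(pj)[nzc]] * pc[col(pj)[nzc]])))
  }
  best <- 0
  for (orient in 1:2) {
    xx <- if (orient == 1) x else y
    yy <- if (orient == 1) y else x
    pos <- rank(xx, ties.method = "first")     # distinct values assumed
    for (b in 2:floor(B / 2)) {
      q <- equifreq(yy, b)
      nb <- length(unique(q))
      for (a in 2:floor(B / b)) {
        for (cx in utils::combn(n - 1, a - 1, simplify = FALSE)) {
          px <- findInterval(pos, c(0, cx, n) + 0.5)
          best <- max(best, grid_mi(px, q) / log(min(a, nb)))
        }
      }
    }
  }
  best
}
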