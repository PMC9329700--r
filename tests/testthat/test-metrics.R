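test_that("Frobenius error matches hand arithmetic and is scale invariant", {
  p <- masked_pair(c(0, 0), c(1, 2))
  expect_equal(frobenius_error(p), 1.0)           # (1+4)/5
  expect_equal(frobenius_error(masked_pair(1:4, 1:4)), 0)
  for (t in c(0.5, 2)) {
    ps <- masked_pair(t * c(0, 0), t * c(1, 2))
    expect_equal(frobenius_error(ps), frobenius_error(p))
  }
  expect_error(frobenius_error(masked_pair(c(1, 1), c(0, 0))),
               class = "gnimpute_undefined_metric_error")
})

test_that("correlation, MSE and L1 follow their defining formulas", {
  expect_equal(pearson_cor(masked_pair(c(1, 2, 3), c(1, 2, 3))), 1)
  expect_equal(pearson_cor(masked_pair(c(1, 2, 3), -c(1, 2, 3))), -1)
  # direct covariance / (sd sd) arithmetic, population normalization cancels
  est <- c(1, 2, 3); tru <- c(1, 2, 4)
  byhand <- mean((est - mean(est)) * (tru - mean(tru))) /
    (sqrt(mean((est - mean(est))^2)) * sqrt(mean((tru - mean(tru))^2)))
  expect_equal(pearson_cor(masked_pair(est, tru)), byhand)
  expect_error(pearson_cor(masked_pair(c(1, 1), c(1, 2))),
               class = "gnimpute_undefined_metric_error")

  expect_equal(mse(masked_pair(0, 3)), 9)
  expect_equal(l1_error(masked_pair(0, 3)), 3)
  expect_equal(mse(masked_pair(1:5, 1:5)), 0)
  # Jensen: mean of squares dominates squared mean
  set.seed(4)
  for (trial in 1:10) {
    p <- masked_pair(rnorm(20), rnorm(20))
    expect_gte(mse(p), l1_error(p)^2)
  }
})

test_that("NMI matches brute-force contingency computation", {
  expect_equal(nmi(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)   # relabeled identity
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)   # independent
  # hand-built contingency for pred {0,0,1,1}, true {0,0,0,1}
  tab <- matrix(c(2, 1, 0, 1), 2, 2)                   # rows pred, cols true
  n <- 4
  pj <- tab / n; pr <- rowSums(pj); pc <- colSums(pj)
  nzc <- pj > 0
  mi <- sum(pj[nzc] * log(pj[nzc] / outer(pr, pc)[nzc]))
  h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 0, 0, 1)), 2 * mi / (h(pr) + h(pc)))
  # symmetry and permutation invariance
  set.seed(2)
  a <- sample(3, 30, TRUE); b <- sample(4, 30, TRUE)
  expect_equal(nmi(a, b), nmi(b, a))
  perm <- c(3, 1, 2)
  expect_equal(nmi(perm[a], b), nmi(a, b))
  # both sides single-class: identical partitions by definition
  expect_equal(nmi(rep(1, 5), rep(7, 5)), 1)
})

test_that("coefficient of variation implements both conventions", {
  v <- c(2, 2, 2, 4)
  sg <- sqrt(mean((v - 2.5)^2))                        # population sd
  expect_equal(coefficient_of_variation(v), abs(2.5 / sg))
  expect_equal(coefficient_of_variation(v), 2.8868, tolerance = 1e-4)
  expect_equal(coefficient_of_variation(v, mode = "standard"), abs(sg / 2.5))
  expect_error(coefficient_of_variation(c(3, 3, 3)),
               class = "gnimpute_undefined_metric_error")
  expect_equal(coefficient_of_variation(c(3, 3, 3), mode = "standard"), 0)
  for (t in c(0.5, 2)) {
    expect_equal(coefficient_of_variation(t * v), coefficient_of_variation(v))
  }
})

test_that("cv_table computes before on non-zero cells and after on all cells", {
  vals <- rbind(c(0, 2, 4, 0), c(1, 1, 1, 1))
  before <- expression_matrix(vals, labels = rep("t1", 4), layer_tag = "log1p")
  after_vals <- rbind(c(1, 2, 4, 3), c(1, 1, 1, 1))
  after <- expression_matrix(after_vals, labels = rep("t1", 4),
                             layer_tag = "log1p")
  tab <- cv_table(before, after)
  g1 <- tab[tab$gene_id == "g1", ]
  expect_equal(g1$cv_before, coefficient_of_variation(c(2, 4)))
  expect_equal(g1$cv_after, coefficient_of_variation(c(1, 2, 4, 3)))
  expect_equal(g1$mean_nonzero, 3)
  expect_true(is.na(tab[tab$gene_id == "g2", ]$cv_after))  # constant gene
})

test_that("MIC is 1 for noiseless functional relationships", {
  set.seed(1)
  x <- sort(runif(200))
  expect_equal(mic(x, x), 1)
  x2 <- seq(-1, 1, length.out = 200)
  expect_equal(mic(x2, x2^2), 1)
})

test_that("MIC of independent noise stays small", {
  set.seed(10)
  vals <- replicate(10, {
    mic(runif(500), runif(500))
  })
  expect_lt(mean(vals), 0.2)
})

test_that("MIC matches an exhaustive grid-search oracle at small n", {
  set.seed(3)
  for (trial in 1:3) {
    x <- rnorm(14)
    y <- 0.5 * x + rnorm(14) * c(1, 0.2, 0.05)[trial]
    got <- mic(x, y, max_clumps_factor = 100)   # no superclump merging at n=14
    ref <- mic_exhaustive_oracle(x, y)
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("MIC degenerate inputs return 0", {
  expect_equal(mic(rep(1, 20), rnorm(20)), 0)
  expect_equal(mic(rnorm(20), rep(2, 20)), 0)
})
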