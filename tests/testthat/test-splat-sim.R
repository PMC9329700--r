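test_that("identical parameters give bit-identical counts", {
  p <- sim_params(n_genes = 300, n_cells = 50, n_groups = 2, seed = 4)
  a <- simulate_counts(p)
  b <- simulate_counts(p)
  expect_identical(plain(a$counts), plain(b$counts))
  expect_identical(a$groups, b$groups)
})

test_that("counts are non-negative integers with labels near the group simplex", {
  p <- sim_params(n_genes = 200, n_cells = 600, n_groups = 3,
                  group_probs = c(0.5, 0.3, 0.2), seed = 7)
  s <- simulate_counts(p)
  v <- plain(s$counts)
  expect_true(all(v >= 0))
  expect_true(all(v == round(v)))
  freq <- tabulate(s$groups, 3) / 600
  # binomial 3-sigma band around each group probability
  for (g in 1:3) {
    se <- sqrt(p$group_probs[g] * (1 - p$group_probs[g]) / 600)
    expect_lt(abs(freq[g] - p$group_probs[g]), 4 * se)
  }
})

test_that("without group structure all cells are exchangeable", {
  s <- simulate_counts(sim_params(n_genes = 400, n_cells = 300, n_groups = 1,
                                  de_prob = 0, seed = 2))
  # per-gene two-sample t-tests between arbitrary halves on library-
  # normalized log expression: rejections at the nominal rate only
  v <- plain(s$counts)
  v <- log1p(sweep(v, 2, 1e4 / colSums(v), "*"))
  top <- order(rowMeans(v), decreasing = TRUE)[1:50]
  half <- rep(c(TRUE, FALSE), 150)
  pvals <- apply(v[top, ], 1, function(r) {
    stats::t.test(r[half], r[!half])$p.value
  })
  expect_lt(sum(pvals < 0.05), 10)   # 50 tests at the 5% level
})

test_that("mean library size matches the log-normal moment", {
  p <- sim_params(n_genes = 500, n_cells = 500, n_groups = 1,
                  lib_loc = 8, lib_scale = 0.3, seed = 5)
  s <- simulate_counts(p)
  libs <- colSums(plain(s$counts))
  expected <- exp(8 + 0.3^2 / 2)
  se <- stats::sd(libs) / sqrt(500)
  expect_lt(abs(mean(libs) - expected), 3 * se)
})

test_that("zero fraction decreases as library sizes grow", {
  for (seed in 1:3) {
    zf <- vapply(c(5, 6.5, 8), function(loc) {
      mean(simulate_counts(sim_params(n_genes = 400, n_cells = 120,
                                      lib_loc = loc,
                                      seed = seed))$counts == 0)
    }, 0)
    expect_true(all(diff(zf) < 0))
  }
})

test_that("strong planted differential expression is detectable by a t statistic", {
  p <- sim_params(n_genes = 1500, n_cells = 300, n_groups = 2,
                  de_loc = 1, de_prob = 0.1, lib_loc = 9, seed = 6)
  s <- simulate_counts(p)
  v <- log1p(plain(s$counts))
  g1 <- s$groups == 1
  tstat <- abs(apply(v, 1, function(r) {
    if (stats::sd(r) == 0) return(0)
    tryCatch(stats::t.test(r[g1], r[!g1])$statistic, error = function(e) 0)
  }))
  is_de <- s$de_factors[, 1] != 1 | s$de_factors[, 2] != 1
  # AUROC of the t statistic for recovering planted DE genes
  r <- rank(tstat)
  auroc <- (sum(r[is_de]) - sum(is_de) * (sum(is_de) + 1) / 2) /
    (sum(is_de) * sum(!is_de))
  expect_gt(auroc, 0.9)
})

test_that("logistic dropout zeroes counts and records the pre-dropout truth", {
  p <- sim_params(n_genes = 300, n_cells = 80, n_groups = 1,
                  dropout_shape = -1, dropout_mid = 2, seed = 3)
  s <- simulate_counts(p)
  expect_true(any(s$dropout_mask))
  expect_true(all(s$counts[s$dropout_mask] == 0))
  keep <- !s$dropout_mask
  expect_identical(plain(s$counts)[keep], s$pre_dropout_counts[keep] * 1)
})

test_that("zero-fraction calibration hits its target and is a no-op at a fixed point", {
  p <- sim_params(n_genes = 800, n_cells = 150, n_groups = 2, seed = 9)
  target <- 0.45
  pc <- calibrate_zero_fraction(p, target)
  achieved <- mean(simulate_counts(pc)$counts == 0)
  expect_lt(abs(achieved - target), 0.02)

  # asking for the zero fraction the current parameters already produce
  # returns them unchanged
  zf0 <- mean(simulate_counts(p)$counts == 0)
  p2 <- calibrate_zero_fraction(p, zf0)
  expect_equal(p2$lib_loc, p$lib_loc)

  expect_error(calibrate_zero_fraction(p, 0.999, bounds = c(8, 12)),
               class = "gnimpute_calibration_error")
  expect_error(calibrate_zero_fraction(p, 0.3, knob = "dropout_mid"),
               class = "gnimpute_validation_error")
})

test_that("invalid simplexes are rejected", {
  expect_error(sim_params(n_groups = 2, group_probs = c(0.9, 0.3)),
               class = "gnimpute_validation_error")
  expect_error(sim_params(de_prob = 1.4), class = "gnimpute_validation_error")
})
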