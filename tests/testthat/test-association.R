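test_that("pearson correlation matches the covariance-formula oracle", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1.0)
  expect_equal(pearson_correlation(x, -x)$r, -1.0)

  y <- c(2, 1, 4, 3, 5)
  got <- pearson_correlation(x, y)
  want <- oracle_pearson(x, y)
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)

  expect_error(pearson_correlation(x, rep(1, 5)), "zero variance")
  expect_error(pearson_correlation(x, 1:4), "equal length")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")

  # affine invariance (sign flips with negative scale)
  set.seed(33)
  for (k in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    r0 <- pearson_correlation(x, y)$r
    expect_equal(pearson_correlation(3 * x + 7, y)$r, r0, tolerance = 1e-12)
    expect_equal(pearson_correlation(x, -2 * y + 1)$r, -r0, tolerance = 1e-12)
  }
})

test_that("the structure-RLU scan recovers planted relations and flags the rest", {
  set.seed(37)
  n <- 40
  cov <- runif(n, 5, 30)
  tab <- data.frame(
    mirna = "m1", metric = "coverage_score", radius = 2,
    value = cov, mean_rlu = 0.5 + 0.01 * cov + rnorm(n, 0, 0.02))
  res <- structure_rlu_scan(tab)
  expect_equal(nrow(res), 1L)
  expect_gt(res$pearson_r, 0.5)
  expect_lt(res$p_value, 1e-3)
  expect_identical(res$flag, "ok")

  # permutation symmetry in row order
  perm <- tab[sample(n), ]
  expect_equal(structure_rlu_scan(perm)$pearson_r, res$pearson_r)

  # insufficient n and constant metric are flagged, not dropped
  tab2 <- rbind(tab,
                data.frame(mirna = "m2", metric = "coverage_score",
                           radius = 2, value = 1,
                           mean_rlu = c(0.5, 0.6, 0.7, 0.8)),
                data.frame(mirna = "m3", metric = "paired_fraction_w0",
                           radius = NA, value = c(10, 20),
                           mean_rlu = c(0.5, 0.6)))
  res2 <- structure_rlu_scan(tab2)
  expect_identical(res2$flag[res2$mirna == "m2"], "zero_variance")
  expect_identical(res2$flag[res2$mirna == "m3"], "insufficient_n")
})

test_that("site-count correlation flags degenerate input and finds planted trends", {
  flat <- data.frame(site_count = rep(2L, 10), mean_rlu = runif(10))
  expect_identical(site_count_rlu_correlation(flat)$flag, "zero_variance")

  set.seed(41)
  k <- sample(1:5, 50, replace = TRUE)
  inv <- data.frame(site_count = k, mean_rlu = 1 - 0.08 * k + rnorm(50, 0, 0.03))
  res <- site_count_rlu_correlation(inv)
  expect_lt(res$r, -0.5)
  expect_identical(res$flag, "ok")

  # independent simulation: the null is retained at about the nominal rate
  hits <- 0L
  for (b in 1:300) {
    d <- data.frame(site_count = sample(1:4, 30, replace = TRUE),
                    mean_rlu = rnorm(30, 1, 0.1))
    if (site_count_rlu_correlation(d)$p < 0.05) hits <- hits + 1L
  }
  expect_lt(hits / 300, 0.12)
})
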