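toy_plate <- function(test_ff, ctrl_ff, renilla = 10) {
  # one construct, 4 replicates x 2 duplicates; firefly given per replicate
  rows <- list()
  for (cond in c("mirX", "empty")) {
    ff <- if (cond == "mirX") test_ff else ctrl_ff
    for (i in 1:4) {
      rows[[length(rows) + 1L]] <- data.frame(
        construct_id = "c1_f1", mirna_id = cond, replicate = i,
        duplicate = 1:2, firefly = ff[[i]], renilla = renilla,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("RLU normalization is a per-replicate ratio of ratios", {
  p <- toy_plate(test_ff = list(8, 8, 8, 8), ctrl_ff = list(10, 10, 10, 10))
  expect_equal(unname(normalize_rlu(p, "c1_f1", "mirX")), rep(0.8, 4))

  same <- toy_plate(list(7, 9, 11, 13), list(7, 9, 11, 13))
  expect_equal(unname(normalize_rlu(same, "c1_f1", "mirX")), rep(1, 4))

  # duplicates averaged inside the replicate: (100,110)/10 vs (125,125)/10
  p2 <- toy_plate(list(c(100, 110), c(100, 110), c(100, 110), c(100, 110)),
                  list(125, 125, 125, 125))
  expect_equal(unname(normalize_rlu(p2, "c1_f1", "mirX")), rep(0.84, 4))

  bad <- p; bad$renilla[1] <- 0
  expect_error(normalize_rlu(bad, "c1_f1", "mirX"), "non-positive")
  expect_error(normalize_rlu(p, "c1_f1", "absent"), "no measurements")
})

test_that("welch_t_test agrees with the closed-form computation", {
  a <- c(0.78, 0.80, 0.80, 0.82)
  b <- c(0.98, 1.00, 1.00, 1.02)
  got <- welch_t_test(a, b)
  want <- oracle_welch(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)

  expect_equal(welch_t_test(b, a)$t, -got$t)
  expect_equal(welch_t_test(b, a)$p, got$p)

  eq <- welch_t_test(a, a)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)

  expect_error(welch_t_test(rep(1, 4), rep(2, 4)), "zero variance")
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")

  set.seed(19)
  for (k in 1:200) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1), sd = runif(1, .5, 2))
    got <- welch_t_test(a, b); want <- oracle_welch(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("validation requires both the RLU reduction and significance", {
  v <- validate_mti(c(0.85, 0.95, 0.85, 1.30, 0.65),
                    c(0.01, 0.001, 0.20, 0.01, 0.001))
  expect_equal(v$validated, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(v$category,
               c("moderate", "none", "moderate", "upregulated", "strong"))
})

test_that("gene-level aggregation takes independent minima and any-validation", {
  rec <- data.frame(gene = "G", mirna = "m",
                    mean_rlu = c(0.85, 0.95), p_value = c(0.01, 0.30),
                    validated = c(TRUE, FALSE), stringsAsFactors = FALSE)
  g <- aggregate_gene_level(rec)
  expect_equal(g$best_rlu, 0.85)
  expect_equal(g$best_p, 0.01)
  expect_true(g$validated)

  # minima can come from different fragments
  rec2 <- data.frame(gene = "G", mirna = "m",
                     mean_rlu = c(0.80, 0.88), p_value = c(0.04, 0.001),
                     validated = c(TRUE, TRUE), stringsAsFactors = FALSE)
  g2 <- aggregate_gene_level(rec2)
  expect_equal(c(g2$best_rlu, g2$best_p), c(0.80, 0.001))

  # adding a fragment can never un-validate a gene
  set.seed(23)
  for (k in 1:30) {
    n <- sample(2:6, 1)
    rec <- data.frame(gene = "G", mirna = "m",
                      mean_rlu = runif(n, 0.4, 1.2),
                      p_value = runif(n), stringsAsFactors = FALSE)
    rec$validated <- rec$mean_rlu < 0.9 & rec$p_value < 0.05
    before <- aggregate_gene_level(rec[-n, , drop = FALSE])
    after <- aggregate_gene_level(rec)
    expect_true(!before$validated || after$validated)
    expect_lte(after$best_rlu, before$best_rlu)
    expect_lte(after$best_p, before$best_p)
  }
  expect_error(aggregate_gene_level(rec[0, ]), "nrow")
})

test_that("validation rates match the printed per-miRNA arithmetic", {
  expect_equal(validation_rate(76, 95), 80.0)
  expect_equal(validation_rate(96, 190), 50.5)
  expect_equal(validation_rate(0, 10), 0.0)
  recs <- data.frame(mirna = rep(c("a", "b"), c(4, 6)),
                     validated = c(rep(TRUE, 3), rep(FALSE, 4),
                                   rep(TRUE, 3)))
  tab <- validation_rate(recs)
  expect_equal(tab$rate[tab$mirna == "a"], 75.0)
  expect_equal(tab$rate[tab$mirna == "b"], 50.0)
  expect_equal(validation_rate(recs, by = NULL), 60.0)
})

test_that("screen statistics recover known effects from simulated plates", {
  set.seed(29)
  truth <- data.frame(
    construct_id = c("gA_f1", "gA_f2", "gB_f1"),
    mirna_id = c("m1", "m1", "m2"),
    true_mean = c(0.6, 1.0, 0.85), stringsAsFactors = FALSE)
  plate <- generate_plate(truth, noise_sd = 0.02)
  res <- screen_statistics(plate)
  expect_equal(nrow(res), 3L)
  expect_identical(res$gene, c("gA", "gA", "gB"))
  m <- res$mean_rlu[match(truth$construct_id, res$construct_id)]
  expect_true(all(abs(m - truth$true_mean) < 0.1))
  expect_true(res$validated[res$construct_id == "gA_f1"])
  expect_false(res$validated[res$construct_id == "gA_f2"])
  expect_true(all(res$p_adj >= res$p_value))
})
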