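test_that("canonical site patterns follow the seed-match definitions", {
  pat <- site_patterns(tiny_mir129())
  expect_identical(pat[["6mer"]], "CAAAAA")
  expect_identical(pat[["7mer-m8"]], "GCAAAAA")
  expect_identical(pat[["7mer-A1"]], "CAAAAAA")
  expect_identical(pat[["8mer"]], "GCAAAAAA")

  homo <- mirna("polyA", strrep("A", 15))
  expect_identical(site_patterns(homo)[["6mer"]], "UUUUUU")

  set.seed(21)
  for (k in 1:20) {
    pat <- site_patterns(random_mirna())
    expect_identical(substr(pat[["8mer"]], 8, 8), "A")
    expect_identical(substr(pat[["7mer-A1"]], 7, 7), "A")
    expect_identical(substr(pat[["8mer"]], 1, 7), pat[["7mer-m8"]])
    expect_identical(substr(pat[["7mer-m8"]], 2, 7), pat[["6mer"]])
  }
})

test_that("find_seed_sites labels each core with its maximal type", {
  m <- tiny_mir129()
  s8 <- find_seed_sites(utr_fragment("g", "f", "AUGCAAAAAAGG"), m)
  expect_equal(nrow(s8), 1L)
  expect_identical(s8$site_type, "8mer")
  expect_equal(c(s8$start, s8$end), c(3L, 10L))
  expect_identical(s8$target_seq, "GCAAAAAA")

  expect_equal(nrow(find_seed_sites(utr_fragment("g", "f", "GGGGGGGG"), m)), 0L)

  s6 <- find_seed_sites(utr_fragment("g", "f", "CCAAAAAC"), m)
  expect_identical(s6$site_type, "6mer")
  expect_equal(c(s6$start, s6$end), c(2L, 7L))
})

test_that("find_seed_sites matches the exhaustive per-offset oracle", {
  set.seed(31)
  for (k in 1:60) {
    mir <- random_mirna(sample(18:23, 1))
    # AU-biased background raises the hit rate for typical seeds
    seq <- paste(sample(c("A", "U", "G", "C"), sample(50:300, 1),
                        replace = TRUE, prob = c(.35, .35, .15, .15)),
                 collapse = "")
    got <- find_seed_sites(utr_fragment("g", "f", seq), mir)
    want <- oracle_scan(seq, mir)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_identical(got$site_type, want$site_type)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("no reported site type is upgradable (maximality)", {
  set.seed(41)
  for (k in 1:40) {
    mir <- random_mirna()
    pat <- site_patterns(mir)
    seq <- random_rna(200)
    sites <- find_seed_sites(utr_fragment("g", "f", seq), mir)
    for (i in seq_len(nrow(sites))) {
      ty <- sites$site_type[i]
      core_start <- if (ty %in% c("8mer", "7mer-m8")) sites$start[i] + 1L
                    else sites$start[i]
      if (ty != "8mer") {
        expect_false(core_start > 1L && core_start + 6L <= nchar(seq) &&
          substr(seq, core_start - 1L, core_start + 6L) == pat[["8mer"]])
      }
      if (ty == "6mer") {
        expect_false(core_start > 1L &&
          substr(seq, core_start - 1L, core_start + 5L) == pat[["7mer-m8"]])
        expect_false(core_start + 6L <= nchar(seq) &&
          substr(seq, core_start, core_start + 6L) == pat[["7mer-A1"]])
      }
    }
  }
})

test_that("count_sites counts disjoint planted cores", {
  m <- tiny_mir129()
  expect_equal(count_sites(utr_fragment("g", "f", "AUGCAAAAAAGG"), m), 1L)
  expect_equal(count_sites(utr_fragment("g", "f", "GGGGGGGG"), m), 0L)
  two <- paste0("GGG", "GCAAAAAA", "GGGGG", "GCAAAAAA", "GGG")
  expect_equal(count_sites(utr_fragment("g", "f", two), m), 2L)
})

test_that("pairwise overlap counts intersections for pairs and triples", {
  ov <- pairwise_site_overlap(list(m1 = c("a", "b"), m2 = c("b", "c")))
  expect_equal(ov$shared[ov$mirnas == "m1+m2"], 1L)

  dis <- pairwise_site_overlap(list(m1 = "a", m2 = "b", m3 = "c"))
  expect_true(all(dis$shared == 0L))

  tri <- pairwise_site_overlap(list(m1 = "a", m2 = "a", m3 = "a"))
  expect_equal(tri$shared[tri$order == 3], 1L)
  expect_true(all(tri$shared[tri$order == 2] == 1L))
})
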