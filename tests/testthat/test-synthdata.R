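test_that("planted sites are recovered exactly by the scanner", {
  set.seed(43)
  panel <- default_mirnas()
  planted <- data.frame(mirna = "miR-129-5p", site_type = "8mer",
                        position = 150L, stringsAsFactors = FALSE)
  frag <- generate_utr(300, planted, panel)
  found <- find_seed_sites(frag, panel[["miR-129-5p"]])
  expect_equal(nrow(found), 1L)
  expect_identical(found$site_type, "8mer")
  expect_equal(c(found$start, found$end), c(150L, 157L))

  none <- generate_utr(300, NULL, panel)
  for (m in panel) expect_equal(count_sites(none, m), 0L)

  # two miRNAs planted on the same fragment show up as a shared fragment
  two <- generate_utr(400, data.frame(
    mirna = c("synmiR-1", "synmiR-2"), site_type = "7mer-m8",
    position = c(100L, 250L)), panel, fragment_id = "shared_f1")
  lists <- lapply(panel[c("synmiR-1", "synmiR-2")], function(m) {
    s <- find_seed_sites(two, m)
    unique(s$fragment_id)
  })
  ov <- pairwise_site_overlap(lists)
  expect_equal(ov$shared, 1L)

  expect_error(generate_utr(100, data.frame(
    mirna = "synmiR-1", site_type = "8mer", position = 98L), panel), "fit")
  expect_error(generate_utr(100, data.frame(
    mirna = c("synmiR-1", "synmiR-1"), site_type = "8mer",
    position = c(20L, 24L)), panel), "overlap")
})

test_that("simulated plates honour the noise model and determinism", {
  truth <- data.frame(construct_id = "c_f1", mirna_id = "m1", true_mean = 1.0)
  exact <- generate_plate(truth, noise_sd = 0)
  expect_equal(unname(normalize_rlu(exact, "c_f1", "m1")), rep(1, 4))

  set.seed(47); p1 <- generate_plate(truth, noise_sd = 0.05)
  set.seed(47); p2 <- generate_plate(truth, noise_sd = 0.05)
  expect_identical(p1, p2)

  # grand-mean recovery over many constructs
  set.seed(49)
  many <- data.frame(construct_id = sprintf("c%04d_f1", 1:300),
                     mirna_id = "m1", true_mean = 0.6)
  plate <- generate_plate(many, noise_sd = 0.05)
  means <- vapply(many$construct_id, function(cid)
    mean(normalize_rlu(plate, cid, "m1")), numeric(1))
  expect_lt(abs(mean(means) - 0.6), 0.02)
})

test_that("study bundles are deterministic and internally consistent", {
  cfg <- study_config(n_genes = 5, utr_length_range = c(200, 900),
                      fold_structures = FALSE, rng_seed = 101)
  b1 <- generate_study(cfg)
  b2 <- generate_study(cfg)
  expect_identical(b1$plate, b2$plate)
  expect_identical(b1$truth_sites, b2$truth_sites)
  expect_identical(b1$utrs, b2$utrs)

  # every planted site is recovered on its fragment, and nothing else
  frag_ids <- vapply(b1$fragments, function(f) f$fragment_id, character(1))
  found <- do.call(rbind, lapply(b1$fragments, function(f) {
    do.call(rbind, lapply(b1$mirnas, function(m) find_seed_sites(f, m)))
  }))
  # sites inside overlap zones would appear twice; the generator avoids them
  key <- function(d) sort(paste(d$fragment_id, d$mirna, d$site_type,
                                d$start, d$end))
  expect_identical(key(found), key(b1$truth_sites))

  # effects reference real fragments and use the configured classes
  expect_true(all(b1$truth_effects$construct_id %in% frag_ids))
  expect_true(all(b1$truth_effects$class %in%
                    c("repressed", "upregulated", "null")))
  expect_true(all(b1$truth_effects$true_mean[b1$truth_effects$class == "null"]
                  == 1.0))
})

test_that("study bundles write to disk in the pipeline's file dialects", {
  cfg <- study_config(n_genes = 3, utr_length_range = c(150, 400),
                      sites_per_gene = c(1L, 2L), rng_seed = 53)
  b <- generate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(b, dir)
  expect_true(all(file.exists(file.path(dir,
    c("fragments.fasta", "mirnas.fasta", "plate.tsv",
      "truth_sites.tsv", "config.txt")))))
  expect_match(readLines(file.path(dir, "plate.tsv"), n = 1), "rng_seed: 53")
  plate <- read_plate_tsv(file.path(dir, "plate.tsv"))
  expect_identical(sort(names(plate)),
                   sort(c("construct_id", "mirna_id", "replicate",
                          "duplicate", "firefly", "renilla")))
  frags <- read_utr_fasta(file.path(dir, "fragments.fasta"))
  expect_equal(length(frags), length(b$fragments))
  if (length(b$structures) > 0) {
    sts <- read_vienna(file.path(dir, "structures.dbn"))
    expect_identical(sts[[1]]$dotbracket,
                     b$structures[[names(sts)[1]]]$dotbracket)
  }
})
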