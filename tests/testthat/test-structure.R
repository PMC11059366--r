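test_that("dot-bracket parsing extracts pairs by bracket matching", {
  s <- parse_dotbracket(c("GGGGAAAACCCC", "((((....))))"))
  expect_equal(unname(s$pairs),
               cbind(1:4, 12:9))
  expect_equal(nrow(parse_dotbracket(c("AAAAA", "....."))$pairs), 0L)

  expect_error(secondary_structure("ACG", "(.)"), "fewer than 3")
  expect_error(secondary_structure("ACGU", "(..."), "unbalanced")
  expect_error(secondary_structure("ACGU", "...)"), "unbalanced")
  expect_error(secondary_structure("ACGUA", "(.[))"), "pseudoknot")
  expect_error(secondary_structure("ACGU", "....."), "length")

  # header and trailing energy annotation are tolerated
  rec <- parse_dotbracket(">frag1\nGGGGAAAACCCC\n((((....)))) (-3.20)")
  expect_identical(attr(rec, "name"), "frag1")
  expect_equal(nrow(rec$pairs), 4L)
})

test_that("baseline folding recovers the obvious hairpin and respects filters", {
  expect_identical(fold_baseline("GGGGAAAACCCC")$dotbracket, "((((....))))")
  expect_identical(fold_baseline(strrep("A", 10))$dotbracket, strrep(".", 10))
  expect_error(fold_baseline("ACGUA"), "at least 10")

  set.seed(5)
  for (k in 1:25) {
    st <- fold_baseline(random_rna(sample(20:90, 1)))
    # output re-validates through the constructor (balanced, hairpin >= 3)
    expect_s3_class(secondary_structure(st$sequence, st$dotbracket),
                    "secondary_structure")
    for (h in oracle_helices(st)) {
      expect_gte(nrow(h), 2L)  # no isolated pairs
      ends <- rbind(h[1L, ], h[nrow(h), ])
      for (r in 1:2) {
        a <- substr(st$sequence, ends[r, 1L], ends[r, 1L])
        b <- substr(st$sequence, ends[r, 2L], ends[r, 2L])
        expect_false(paste0(a, b) %in% c("GU", "UG"))  # no G-U helix ends
      }
    }
  }
})

test_that("paired fraction windows count bound bases with clipping", {
  s <- parse_dotbracket(c("GGGGAAAACCCC", "((((....))))"))
  expect_equal(paired_fraction(s, c(5, 8), 0), 0.0)
  expect_equal(paired_fraction(s, c(5, 8), 5), 66.7)
  expect_equal(paired_fraction(s, c(1, 4), 0), 100.0)
  expect_error(paired_fraction(s, c(10, 14), 0), "bounds")

  # widening the window only changes the extension, never the in-site count
  set.seed(6)
  for (k in 1:10) {
    st <- fold_baseline(random_rna(80))
    span <- sort(sample(10:70, 2))
    for (w in c(0, 5, 50)) {
      pf <- paired_fraction(st, span, w)
      expect_gte(pf, 0)
      expect_lte(pf, 100)
    }
  }
})

test_that("vienna files round-trip through reader and writer", {
  set.seed(8)
  sts <- list(a = fold_baseline(random_rna(40)),
              b = fold_baseline(random_rna(60)))
  path <- withr::local_tempfile(fileext = ".dbn")
  write_vienna(sts, path)
  back <- read_vienna(path)
  expect_named(back, c("a", "b"))
  expect_identical(back$a$dotbracket, sts$a$dotbracket)
  expect_identical(back$b$sequence, sts$b$sequence)
})
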