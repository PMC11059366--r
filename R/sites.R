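#' Canonical target-site patterns for a miRNA
#'
#' Derives the four canonical binding-site patterns, written 5' to 3' on the
#' target strand, from the miRNA seed:
#'
#' * `6mer` — reverse complement of miRNA positions 2-7;
#' * `7mer-m8` — reverse complement of positions 2-8;
#' * `7mer-A1` — the 6mer followed by an `A` opposite miRNA position 1;
#' * `8mer` — the 7mer-m8 followed by that `A`.
#'
#' The position-1 adenine is a literal target `A` regardless of the miRNA's
#' first nucleotide, per the standard canonical-site convention.
#'
#' @param mirna A [mirna()] object (mature sequence at least 8 nt).
#' @return Named character vector with entries `6mer`, `7mer-A1`, `7mer-m8`,
#'   `8mer`.
#' @examples
#' site_patterns(mirna("miR-129-5p", "CUUUUUGCGGUCUGGGCUUGC"))
#' @export
site_patterns <- function(mirna) {
  stopifnot(inherits(mirna, "mirna"))
  if (nchar(mirna$sequence) < 8L) {
    stop("miRNA must be at least 8 nt to derive canonical patterns",
         call. = FALSE)
  }
  core <- reverse_complement(mirna$seed)            # complements 2-7
  ext  <- reverse_complement(mirna$seed_extended)   # complements 2-8
  c("6mer"    = core,
    "7mer-A1" = paste0(core, "A"),
    "7mer-m8" = ext,
    "8mer"    = paste0(ext, "A"))
}

#' Locate canonical miRNA binding sites on a UTR fragment
#'
#' Scans the fragment for exact occurrences of the 6mer seed-match core and
#' labels each occurrence with the maximal canonical type it supports: an
#' upstream match to miRNA position 8 and/or a downstream target `A`
#' upgrade a core hit to 7mer-m8, 7mer-A1 or 8mer. Exact Watson-Crick
#' matching only (no G:U wobble). Overlapping cores are each reported.
#'
#' @param fragment A [utr_fragment()] (or a plain sequence string).
#' @param mirna A [mirna()] object.
#' @return `data.frame` with one row per site, sorted 5' to 3' by `start`:
#'   columns `gene`, `fragment_id`, `mirna`, `site_type`, `start`, `end`
#'   (1-based inclusive fragment coordinates), `target_seq`.
#' @examples
#' m <- mirna("miR-129-5p", "CUUUUUGCGGUCUGGGCUUGC")
#' find_seed_sites(utr_fragment("g", "f1", "AUGCAAAAAAGG"), m)
#' @export
find_seed_sites <- function(fragment, mirna) {
  if (is.character(fragment)) {
    fragment <- utr_fragment("?", "?", fragment)
  }
  stopifnot(inherits(fragment, "utr_fragment"), inherits(mirna, "mirna"))
  seq <- fragment$sequence
  len <- nchar(seq)
  pat <- site_patterns(mirna)
  core <- pat[["6mer"]]
  # base complementary to miRNA position 8 (first char of the 7mer-m8 pattern)
  m8_base <- substr(pat[["7mer-m8"]], 1L, 1L)

  # every core occurrence, overlaps included (gregexpr would skip them)
  starts <- integer(0)
  if (len >= 6L) {
    for (p in seq_len(len - 5L)) {
      if (substr(seq, p, p + 5L) == core) starts <- c(starts, p)
    }
  }
  if (length(starts) == 0L) {
    return(empty_sites_df())
  }

  rows <- lapply(starts, function(p) {
    has_m8 <- p > 1L && substr(seq, p - 1L, p - 1L) == m8_base
    has_a1 <- p + 6L <= len && substr(seq, p + 6L, p + 6L) == "A"
    if (has_m8 && has_a1) {
      type <- "8mer";    s <- p - 1L; e <- p + 6L
    } else if (has_m8) {
      type <- "7mer-m8"; s <- p - 1L; e <- p + 5L
    } else if (has_a1) {
      type <- "7mer-A1"; s <- p;      e <- p + 6L
    } else {
      type <- "6mer";    s <- p;      e <- p + 5L
    }
    data.frame(
      gene        = fragment$gene,
      fragment_id = fragment$fragment_id,
      mirna       = mirna$name,
      site_type   = type,
      start       = s,
      end         = e,
      target_seq  = substr(seq, s, e),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

empty_sites_df <- function() {
  data.frame(
    gene = character(0), fragment_id = character(0), mirna = character(0),
    site_type = character(0), start = integer(0), end = integer(0),
    target_seq = character(0), stringsAsFactors = FALSE
  )
}

#' Number of canonical binding sites on a fragment
#'
#' @inheritParams find_seed_sites
#' @return Non-negative integer count of seed-match sites.
#' @export
count_sites <- function(fragment, mirna) {
  nrow(find_seed_sites(fragment, mirna))
}

#' Fragment overlap between the target sets of several miRNAs
#'
#' Counts, for every pair and every triple of miRNAs, the fragments that
#' carry binding sites for all members, i.e. the intersection cardinalities
#' of their target-fragment sets.
#'
#' @param site_lists Named list mapping miRNA name to a character vector of
#'   fragment identifiers with at least one site for that miRNA.
#' @return `data.frame` with columns `mirnas` (members joined by `+`),
#'   `order` (2 or 3) and `shared` (count of shared fragments).
#' @examples
#' pairwise_site_overlap(list(m1 = c("a", "b"), m2 = c("b", "c")))
#' @export
pairwise_site_overlap <- function(site_lists) {
  stopifnot(is.list(site_lists), !is.null(names(site_lists)),
            all(nzchar(names(site_lists))))
  site_lists <- lapply(site_lists, unique)
  nms <- names(site_lists)
  combos <- list()
  if (length(nms) >= 2L) {
    combos <- c(combos, utils::combn(nms, 2L, simplify = FALSE))
  }
  if (length(nms) >= 3L) {
    combos <- c(combos, utils::combn(nms, 3L, simplify = FALSE))
  }
  if (length(combos) == 0L) {
    return(data.frame(mirnas = character(0), order = integer(0),
                      shared = integer(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(combos, function(cc) {
    shared <- Reduce(intersect, site_lists[cc])
    data.frame(mirnas = paste(cc, collapse = "+"),
               order = length(cc),
               shared = length(shared),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Convert a site table to BED intervals
#'
#' The package keeps 1-based inclusive coordinates everywhere; the 0-based
#' half-open conversion happens only at this writer boundary.
#'
#' @param sites Site table from [find_seed_sites()].
#' @return `data.frame` in BED6 column order (`chrom` is the fragment id,
#'   `name` is `mirna:site_type`).
#' @export
sites_to_bed <- function(sites) {
  data.frame(
    chrom  = sites$fragment_id,
    start  = sites$start - 1L,
    end    = sites$end,
    name   = paste(sites$mirna, sites$site_type, sep = ":"),
    score  = 0L,
    strand = "+",
    stringsAsFactors = FALSE
  )
}

#' Write a site table as TSV or BED
#'
#' @param sites Site table from [find_seed_sites()].
#' @param path Output file path.
#' @param format `"tsv"` (full columns, 1-based inclusive) or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  tab <- if (format == "bed") sites_to_bed(sites) else sites
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = (format == "tsv"))
  invisible(path)
}
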