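#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Uppercases the input and maps thymine to uracil, so that DNA-distributed
#' 3'UTR libraries and mature miRNA sequences share one alphabet
#' (`A`, `C`, `G`, `U`).
#'
#' @param raw Single non-empty character string over
#'   `A,C,G,T,U` (either case).
#' @return Character string of the same length over `{A,C,G,U}`.
#' @examples
#' normalize_sequence("acgt")
#' @export
normalize_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (is.na(raw) || nchar(raw) == 0L) {
    stop("sequence must be non-empty", call. = FALSE)
  }
  up <- toupper(raw)
  chars <- strsplit(up, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "U"))
  if (length(bad) > 0L) {
    stop(sprintf("invalid nucleotide '%s' at position %d",
                 chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  gsub("T", "U", up, fixed = TRUE)
}

#' Reverse complement of an RNA sequence
#'
#' Watson-Crick complement (A-U, G-C), read 3' to 5'. Applying it twice
#' returns the input.
#'
#' @param seq RNA string over `{A,C,G,U}` (DNA accepted and normalized).
#' @return Reverse-complemented RNA string.
#' @examples
#' reverse_complement("UUUUUG")  # "CAAAAA"
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_sequence(seq)
  chars <- rev(strsplit(seq, "", fixed = TRUE)[[1L]])
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(comp[chars], collapse = "")
}

#' GC content of a sequence, in percent
#'
#' @param seq Non-empty RNA/DNA string.
#' @param digits Decimal places to round to (default 1, the convention for
#'   reporting seed GC content).
#' @return Percentage in `[0, 100]`.
#' @examples
#' gc_content("UUUUUG")  # 16.7
#' @export
gc_content <- function(seq, digits = 1L) {
  seq <- normalize_sequence(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  round(100 * sum(chars %in% c("G", "C")) / length(chars), digits)
}

#' Construct a mature miRNA with derived seed sequences
#'
#' The seed region is nucleotides 2-7 of the mature sequence (5' to 3');
#' the extended seed additionally includes nucleotide 8. Both drive the
#' canonical target-site patterns used by [site_patterns()] and
#' [find_seed_sites()].
#'
#' @param name miRNA identifier, e.g. `"miR-129-5p"`.
#' @param sequence Mature sequence, 15-30 nt, RNA or DNA alphabet.
#' @return Object of class `mirna` with fields `name`, `sequence`, `seed`
#'   (6 nt) and `seed_extended` (7 nt).
#' @examples
#' m <- mirna("miR-129-5p", "CUUUUUGCGGUCUGGGCUUGC")
#' m$seed
#' @export
mirna <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  sequence <- normalize_sequence(sequence)
  n <- nchar(sequence)
  if (n < 15L || n > 30L) {
    stop(sprintf("mature miRNA must be 15-30 nt, got %d", n), call. = FALSE)
  }
  structure(
    list(
      name          = name,
      sequence      = sequence,
      seed          = substr(sequence, 2L, 7L),
      seed_extended = substr(sequence, 2L, 8L)
    ),
    class = "mirna"
  )
}

#' @export
print.mirna <- function(x, ...) {
  cat(sprintf("<mirna> %s\n  sequence: 5'-%s-3' (%d nt)\n  seed: %s  extended: %s\n",
              x$name, x$sequence, nchar(x$sequence), x$seed, x$seed_extended))
  invisible(x)
}

#' Construct a 3'UTR fragment
#'
#' A reporter-sized tile of a full 3'UTR, tracked by its 1-based start in the
#' parent UTR so fragment-local site coordinates can be lifted back.
#'
#' @param gene Gene identifier.
#' @param fragment_id Fragment identifier (unique within the library).
#' @param sequence Fragment sequence, RNA or DNA alphabet.
#' @param parent_offset 1-based start of this fragment in the full UTR.
#' @return Object of class `utr_fragment`.
#' @export
utr_fragment <- function(gene, fragment_id, sequence, parent_offset = 1L) {
  stopifnot(is.character(gene), length(gene) == 1L,
            is.character(fragment_id), length(fragment_id) == 1L)
  parent_offset <- as.integer(parent_offset)
  if (is.na(parent_offset) || parent_offset < 1L) {
    stop("parent_offset must be >= 1", call. = FALSE)
  }
  structure(
    list(
      gene          = gene,
      fragment_id   = fragment_id,
      sequence      = normalize_sequence(sequence),
      parent_offset = parent_offset
    ),
    class = "utr_fragment"
  )
}

#' @export
print.utr_fragment <- function(x, ...) {
  cat(sprintf("<utr_fragment> %s / %s: %d nt, parent offset %d\n",
              x$gene, x$fragment_id, nchar(x$sequence), x$parent_offset))
  invisible(x)
}
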