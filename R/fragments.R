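#' Plan the tiling of a full 3'UTR into reporter-sized fragments
#'
#' Splits a UTR of length `utr_length` into the minimal number of fragments
#' of at most `target_len` nt, with consecutive fragments overlapping by
#' exactly `overlap` nt. Fragment lengths are as equal as possible (they
#' differ by at most 1 nt; the extra nucleotide goes to the earlier
#' fragments). A UTR that fits in one tile yields a single fragment.
#'
#' @param utr_length Full UTR length in nt (>= 1).
#' @param target_len Maximum fragment length, default 675 nt.
#' @param overlap Overlap between consecutive fragments, default 30 nt.
#' @return Object of class `fragment_plan`: list with `n_fragments`,
#'   `target_len`, `overlap`, `utr_length` and `intervals`, a `data.frame`
#'   of 1-based inclusive `start`/`end` columns.
#' @examples
#' plan_fragments(1320)  # two 675-nt fragments overlapping by 30
#' @export
plan_fragments <- function(utr_length, target_len = 675L, overlap = 30L) {
  utr_length <- as.integer(utr_length)
  target_len <- as.integer(target_len)
  overlap <- as.integer(overlap)
  stopifnot(length(utr_length) == 1L, !is.na(utr_length), utr_length >= 1L,
            overlap >= 0L)
  if (target_len <= overlap) {
    stop("target_len must exceed overlap", call. = FALSE)
  }
  if (utr_length <= target_len) {
    n <- 1L
    lens <- utr_length
  } else {
    step <- target_len - overlap
    n <- as.integer(ceiling((utr_length - overlap) / step))
    # total tiled length counts each internal overlap twice
    total <- utr_length + (n - 1L) * overlap
    base <- total %/% n
    extra <- total %% n
    lens <- rep(base, n)
    if (extra > 0L) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  }
  starts <- integer(n)
  starts[1L] <- 1L
  if (n > 1L) {
    for (i in 2:n) starts[i] <- starts[i - 1L] + lens[i - 1L] - overlap
  }
  structure(
    list(
      n_fragments = n,
      target_len = target_len,
      overlap = overlap,
      utr_length = utr_length,
      intervals = data.frame(start = starts, end = starts + lens - 1L)
    ),
    class = "fragment_plan"
  )
}

#' @export
print.fragment_plan <- function(x, ...) {
  cat(sprintf("<fragment_plan> UTR %d nt -> %d fragment(s) (<= %d nt, overlap %d)\n",
              x$utr_length, x$n_fragments, x$target_len, x$overlap))
  print(x$intervals)
  invisible(x)
}

#' Cut a full UTR sequence according to a fragment plan
#'
#' @param utr Full UTR sequence (string), RNA or DNA alphabet.
#' @param plan A [plan_fragments()] result for the same length.
#' @param gene Gene identifier used for the emitted fragments.
#' @return List of [utr_fragment()] objects; `fragment_id` is
#'   `"<gene>_f<k>"` and `parent_offset` the interval start.
#' @export
apply_plan <- function(utr, plan, gene = "gene") {
  stopifnot(inherits(plan, "fragment_plan"))
  utr <- normalize_sequence(utr)
  if (nchar(utr) != plan$utr_length) {
    stop(sprintf("plan is for a %d-nt UTR but sequence has %d nt",
                 plan$utr_length, nchar(utr)), call. = FALSE)
  }
  lapply(seq_len(plan$n_fragments), function(k) {
    s <- plan$intervals$start[k]
    e <- plan$intervals$end[k]
    utr_fragment(gene, sprintf("%s_f%d", gene, k),
                 substr(utr, s, e), parent_offset = s)
  })
}

#' Summarize a reporter library of fragment plans
#'
#' @param plans Named list of [plan_fragments()] results, one per gene.
#' @param exclude Character vector of fragment ids (`"<gene>_f<k>"`) removed
#'   from the library, e.g. failed syntheses.
#' @return List with `n_genes` and `n_fragments` after exclusions.
#' @export
library_summary <- function(plans, exclude = character(0)) {
  stopifnot(is.list(plans))
  if (length(plans) == 0L) {
    return(list(n_genes = 0L, n_fragments = 0L))
  }
  stopifnot(!is.null(names(plans)), all(nzchar(names(plans))))
  ids <- unlist(lapply(names(plans), function(g) {
    sprintf("%s_f%d", g, seq_len(plans[[g]]$n_fragments))
  }))
  kept <- setdiff(ids, exclude)
  list(n_genes = length(plans), n_fragments = length(kept))
}

#' Read UTR or miRNA sequences from a FASTA file
#'
#' Thin wrappers over [Biostrings::readBStringSet()] that normalize to the
#' RNA alphabet. `read_mirna_fasta()` additionally derives seeds.
#'
#' @param path FASTA file path.
#' @return `read_utr_fasta()`: named character vector of RNA sequences.
#'   `read_mirna_fasta()`: list of [mirna()] objects.
#' @export
read_utr_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- vapply(as.character(set), normalize_sequence, character(1))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' @rdname read_utr_fasta
#' @export
read_mirna_fasta <- function(path) {
  seqs <- read_utr_fasta(path)
  lapply(seq_along(seqs), function(i) mirna(names(seqs)[i], seqs[[i]]))
}

#' Write library fragments to FASTA
#'
#' Headers follow `gene|fragment_id|start-end` so fragment provenance
#' survives a round trip through external tools.
#'
#' @param fragments List of [utr_fragment()] objects.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fragments_fasta <- function(fragments, path) {
  seqs <- vapply(fragments, function(f) f$sequence, character(1))
  headers <- vapply(fragments, function(f) {
    sprintf("%s|%s|%d-%d", f$gene, f$fragment_id, f$parent_offset,
            f$parent_offset + nchar(f$sequence) - 1L)
  }, character(1))
  set <- Biostrings::BStringSet(setNames(seqs, headers))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
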