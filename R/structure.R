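#' Construct and validate a secondary structure
#'
#' Couples an RNA sequence with a dot-bracket string and the base-pair set
#' derived from it by bracket matching. Only nested (pseudoknot-free)
#' structures are representable; hairpin loops must enclose at least 3
#' unpaired bases.
#'
#' @param sequence RNA (or DNA) sequence.
#' @param dotbracket String of the same length over `(`, `)`, `.`.
#' @return Object of class `secondary_structure`: list with `sequence`,
#'   `dotbracket` and `pairs`, an `m x 2` matrix of 1-based pair indices
#'   (`i < j`, sorted by `i`).
#' @export
secondary_structure <- function(sequence, dotbracket) {
  sequence <- normalize_sequence(sequence)
  stopifnot(is.character(dotbracket), length(dotbracket) == 1L)
  if (nchar(dotbracket) != nchar(sequence)) {
    stop("sequence and dot-bracket string differ in length", call. = FALSE)
  }
  chars <- strsplit(dotbracket, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad) > 0L) {
    stop(sprintf(
      "unsupported character '%s' at position %d (pseudoknots and other bracket types are not representable)",
      chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2L)
  plist <- list()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      open <- c(open, i)
    } else if (chars[i] == ")") {
      if (length(open) == 0L) {
        stop(sprintf("unbalanced ')' at position %d", i), call. = FALSE)
      }
      j <- open[length(open)]
      open <- open[-length(open)]
      plist[[length(plist) + 1L]] <- c(j, i)
    }
  }
  if (length(open) > 0L) {
    stop(sprintf("unbalanced '(' at position %d", open[1L]), call. = FALSE)
  }
  if (length(plist) > 0L) {
    pairs <- do.call(rbind, plist)
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
    # hairpin check: the innermost pair of every helix must enclose >= 3
    # unpaired bases; for nested structures it is enough that every pair
    # spans at least min-hairpin + 1
    short <- pairs[, 2L] - pairs[, 1L] - 1L < 3L
    if (any(short)) {
      k <- which(short)[1L]
      stop(sprintf("hairpin loop closed by pair (%d,%d) has fewer than 3 unpaired bases",
                   pairs[k, 1L], pairs[k, 2L]), call. = FALSE)
    }
  }
  colnames(pairs) <- c("i", "j")
  structure(
    list(sequence = sequence, dotbracket = dotbracket, pairs = pairs),
    class = "secondary_structure"
  )
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> %d nt, %d base pairs\n%s\n%s\n",
              nchar(x$sequence), nrow(x$pairs), x$sequence, x$dotbracket))
  invisible(x)
}

#' Parse a Vienna dot-bracket record
#'
#' Accepts the 2-line (sequence, structure) or 3-line (`>name` header first)
#' record format; a trailing free-energy annotation like `(-12.30)` on the
#' structure line is stripped.
#'
#' @param text Character vector of record lines, or a single string with
#'   embedded newlines.
#' @return A [secondary_structure()]; the header name, if present, is
#'   attached as attribute `"name"`.
#' @examples
#' parse_dotbracket(c("GGGGAAAACCCC", "((((....))))"))
#' @export
parse_dotbracket <- function(text) {
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  text <- text[nzchar(trimws(text))]
  name <- NULL
  if (length(text) > 0L && startsWith(text[1L], ">")) {
    name <- trimws(sub("^>", "", text[1L]))
    text <- text[-1L]
  }
  if (length(text) < 2L) {
    stop("a dot-bracket record needs a sequence line and a structure line",
         call. = FALSE)
  }
  seq_line <- trimws(text[1L])
  struct_line <- trimws(text[2L])
  struct_line <- sub("\\s+\\(\\s*-?[0-9.]+\\s*\\)$", "", struct_line)
  out <- secondary_structure(seq_line, struct_line)
  if (!is.null(name)) attr(out, "name") <- name
  out
}

#' Read and write Vienna dot-bracket files
#'
#' Files hold one or more `>name` / sequence / structure records.
#'
#' @param path File path.
#' @return `read_vienna()`: named list of [secondary_structure()] objects.
#' @export
read_vienna <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- which(startsWith(lines, ">"))
  if (length(heads) == 0L) {
    rec <- parse_dotbracket(lines)
    return(setNames(list(rec), "record1"))
  }
  ends <- c(heads[-1L] - 1L, length(lines))
  recs <- lapply(seq_along(heads), function(k) {
    parse_dotbracket(lines[heads[k]:ends[k]])
  })
  setNames(recs, vapply(recs, function(r) attr(r, "name"), character(1)))
}

#' @rdname read_vienna
#' @param structures Named list of [secondary_structure()] objects.
#' @export
write_vienna <- function(structures, path) {
  stopifnot(is.list(structures), !is.null(names(structures)))
  lines <- unlist(lapply(names(structures), function(nm) {
    s <- structures[[nm]]
    c(paste0(">", nm), s$sequence, s$dotbracket)
  }))
  writeLines(lines, path)
  invisible(path)
}

partner_vector <- function(structure) {
  n <- nchar(structure$sequence)
  partner <- integer(n)
  if (nrow(structure$pairs) > 0L) {
    partner[structure$pairs[, 1L]] <- structure$pairs[, 2L]
    partner[structure$pairs[, 2L]] <- structure$pairs[, 1L]
  }
  partner
}

pairs_to_dotbracket <- function(n, pairs) {
  chars <- rep(".", n)
  if (nrow(pairs) > 0L) {
    chars[pairs[, 1L]] <- "("
    chars[pairs[, 2L]] <- ")"
  }
  paste(chars, collapse = "")
}

# Decompose a pair set into maximal helices (runs of stacked pairs).
# Returns a list of integer matrices, each sorted outside-in.
helices_from_pairs <- function(pairs, n) {
  if (nrow(pairs) == 0L) return(list())
  partner <- integer(n)
  partner[pairs[, 1L]] <- pairs[, 2L]
  partner[pairs[, 2L]] <- pairs[, 1L]
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  seen <- logical(n)
  out <- list()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]
    if (seen[i]) next
    j <- pairs[r, 2L]
    helix <- list(c(i, j))
    seen[i] <- TRUE
    while (i + 1L <= n && j - 1L >= 1L && i + 1L < j - 1L &&
           partner[i + 1L] == j - 1L) {
      i <- i + 1L
      j <- j - 1L
      helix[[length(helix) + 1L]] <- c(i, j)
      seen[i] <- TRUE
    }
    out[[length(out) + 1L]] <- do.call(rbind, helix)
  }
  out
}

is_gu <- function(seq, i, j) {
  a <- substr(seq, i, i)
  b <- substr(seq, j, j)
  (a == "G" && b == "U") || (a == "U" && b == "G")
}

#' Fold an RNA sequence with a self-contained baseline model
#'
#' Computes a maximum-weight nested pairing by dynamic programming (pair
#' weights G-C = 3, A-U = 2, G-U = 1; hairpin loops of at least 3 unpaired
#' bases) and then applies two structural filters: helices are trimmed of
#' G-U pairs at their ends, and isolated base pairs (helices of a single
#' pair) are removed. The result is deterministic for a fixed input.
#'
#' This is a light-weight stand-alone folding model intended for fixtures
#' and pipelines that must run without an external thermodynamic folder;
#' externally computed dot-bracket structures can always be ingested
#' verbatim via [parse_dotbracket()] / [read_vienna()].
#'
#' @param seq RNA (or DNA) sequence, 10 to 2000 nt.
#' @return A [secondary_structure()].
#' @examples
#' fold_baseline("GGGGAAAACCCC")$dotbracket  # "((((....))))"
#' @export
fold_baseline <- function(seq) {
  seq <- normalize_sequence(seq)
  n <- nchar(seq)
  if (n < 10L) stop("fold_baseline needs at least 10 nt", call. = FALSE)
  if (n > 2000L) {
    stop("fold_baseline supports up to 2000 nt; fold fragments, not full UTRs",
         call. = FALSE)
  }
  partner <- nussinov_pairs(seq, 3L)
  keep <- which(partner > seq_len(n))
  pairs <- cbind(i = keep, j = partner[keep])

  # post-filters: trim helix-terminal G-U pairs, then drop isolated pairs
  helices <- helices_from_pairs(pairs, n)
  kept <- list()
  for (h in helices) {
    while (nrow(h) > 0L && is_gu(seq, h[1L, 1L], h[1L, 2L])) {
      h <- h[-1L, , drop = FALSE]
    }
    while (nrow(h) > 0L && is_gu(seq, h[nrow(h), 1L], h[nrow(h), 2L])) {
      h <- h[-nrow(h), , drop = FALSE]
    }
    if (nrow(h) >= 2L) kept[[length(kept) + 1L]] <- h
  }
  pairs <- if (length(kept) > 0L) do.call(rbind, kept) else
    matrix(integer(0), ncol = 2L)
  secondary_structure(seq, pairs_to_dotbracket(n, pairs))
}

#' Fraction of paired bases at a binding site
#'
#' Percentage of bases marked `(` or `)` in the dot-bracket string over the
#' site interval extended by `window` nt on both sides (clipped to the
#' sequence). Window 0 inspects the site itself; windows 5 and 50 probe the
#' local neighbourhood.
#'
#' @param structure A [secondary_structure()].
#' @param site Either a one-row site table from [find_seed_sites()] or a
#'   numeric `c(start, end)` (1-based inclusive).
#' @param window Non-negative extension in nt (0, 5 and 50 are the
#'   conventional choices).
#' @return Percentage in `[0, 100]`, one decimal.
#' @export
paired_fraction <- function(structure, site, window = 0L) {
  stopifnot(inherits(structure, "secondary_structure"), window >= 0)
  se <- site_span(site)
  L <- nchar(structure$sequence)
  if (se[1L] < 1L || se[2L] > L || se[1L] > se[2L]) {
    stop("site is out of structure bounds", call. = FALSE)
  }
  lo <- max(1L, se[1L] - as.integer(window))
  hi <- min(L, se[2L] + as.integer(window))
  seg <- strsplit(substr(structure$dotbracket, lo, hi), "", fixed = TRUE)[[1L]]
  round(100 * sum(seg %in% c("(", ")")) / length(seg), 1L)
}

site_span <- function(site) {
  if (is.data.frame(site)) {
    stopifnot(nrow(site) == 1L, all(c("start", "end") %in% names(site)))
    c(as.integer(site$start), as.integer(site$end))
  } else {
    stopifnot(is.numeric(site), length(site) == 2L)
    as.integer(site)
  }
}
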