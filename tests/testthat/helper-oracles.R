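# Independent brute-force oracles used across the suite. These deliberately
# re-derive results from first principles (exhaustive scans, closed-form
# formulas, all-pairs distances) so they share no code path with the
# implementation they check.

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

random_mirna <- function(len = 21L, name = "m") {
  mirna(name, random_rna(len))
}

# exhaustive per-offset site scan: at every 6mer-core position compare the
# full site patterns directly against the fragment substring
oracle_scan <- function(seq, mir) {
  pat <- site_patterns(mir)
  L <- nchar(seq)
  out <- list()
  for (p in seq_len(max(L - 5L, 0L))) {
    if (substr(seq, p, p + 5L) != pat[["6mer"]]) next
    if (p > 1L && p + 6L <= L &&
        substr(seq, p - 1L, p + 6L) == pat[["8mer"]]) {
      out[[length(out) + 1L]] <- list(type = "8mer", s = p - 1L, e = p + 6L)
    } else if (p > 1L && substr(seq, p - 1L, p + 5L) == pat[["7mer-m8"]]) {
      out[[length(out) + 1L]] <- list(type = "7mer-m8", s = p - 1L, e = p + 5L)
    } else if (p + 6L <= L && substr(seq, p, p + 6L) == pat[["7mer-A1"]]) {
      out[[length(out) + 1L]] <- list(type = "7mer-A1", s = p, e = p + 6L)
    } else {
      out[[length(out) + 1L]] <- list(type = "6mer", s = p, e = p + 5L)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(site_type = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  df <- data.frame(site_type = vapply(out, `[[`, "", "type"),
                   start = vapply(out, `[[`, 0L, "s"),
                   end = vapply(out, `[[`, 0L, "e"),
                   stringsAsFactors = FALSE)
  df[order(df$start, df$end), , drop = FALSE]
}

# textbook Welch statistic, Welch-Satterthwaite df, two-sided p
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# all-pairs Euclidean distance coverage count
oracle_coverage <- function(coords, span, r) {
  D <- as.matrix(dist(coords))
  mean(vapply(span[1L]:span[2L], function(s) sum(D[s, ] <= r + 1e-9),
              numeric(1)))
}

# Pearson r from the covariance formula plus the t transform
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# helix decomposition used to audit fold_baseline post-filters
oracle_helices <- function(structure) {
  pairs <- structure$pairs
  if (nrow(pairs) == 0L) return(list())
  n <- nchar(structure$sequence)
  partner <- integer(n)
  partner[pairs[, 1L]] <- pairs[, 2L]
  partner[pairs[, 2L]] <- pairs[, 1L]
  seen <- logical(n)
  hx <- list()
  for (i in sort(pairs[, 1L])) {
    if (seen[i]) next
    j <- partner[i]
    rows <- list(c(i, j))
    seen[i] <- TRUE
    while (i + 1L < j - 1L && partner[i + 1L] == j - 1L) {
      i <- i + 1L; j <- j - 1L
      rows[[length(rows) + 1L]] <- c(i, j)
      seen[i] <- TRUE
    }
    hx[[length(hx) + 1L]] <- do.call(rbind, rows)
  }
  hx
}

tiny_mir129 <- function() mirna("miR-129-5p", "CUUUUUGCGGUCUGGGCUUGC")
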