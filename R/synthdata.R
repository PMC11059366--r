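#' Default miRNA panel for synthetic studies
#'
#' Four mature miRNAs: miR-129-5p with its published mimic sequence, and
#' three synthetic mature sequences (fixed, arbitrary, spanning a range of
#' seed GC contents) standing in for the rest of a screen panel.
#'
#' @return Named list of [mirna()] objects.
#' @export
default_mirnas <- function() {
  seqs <- c(
    "miR-129-5p" = "CUUUUUGCGGUCUGGGCUUGC",
    "synmiR-1"   = "UCGGAUCCGUAUGAACUGACCA",
    "synmiR-2"   = "AGGCUAUCACGUUAGCAAGUCU",
    "synmiR-3"   = "UUACCGAGCCAUAGGCAUCGAU"
  )
  mapply(mirna, names(seqs), seqs, SIMPLIFY = FALSE)
}

#' Configuration of a synthetic reporter-screen study
#'
#' Bundles every tunable of [generate_study()]: library geometry, miRNA
#' panel, planted-site density, the effect model (true mean normalized RLU
#' per MTI class) and the replicate noise model. Defaults emulate the scale
#' of a disease-specific screen at desk size: repressed MTIs draw their
#' true mean uniformly from 0.40-0.88, null MTIs sit at 1.00, occasional
#' up-regulated MTIs at 1.30, with replicate noise sd 0.05 across 4
#' biological replicates in technical duplicates.
#'
#' @param n_genes Number of genes in the library.
#' @param utr_length_range Full-UTR length range in nt.
#' @param mirnas Named list of [mirna()] objects (default
#'   [default_mirnas()]).
#' @param sites_per_gene Integer range of planted sites per gene.
#' @param prop_repressed,prop_upregulated Class probabilities for a tested
#'   MTI (remainder is null).
#' @param repressed_range True-mean range of repressed MTIs.
#' @param upregulated_mean True mean of up-regulated MTIs.
#' @param noise_sd Replicate noise sd on the normalized-RLU scale.
#' @param replicates,duplicates Biological replicates and technical
#'   duplicates per condition.
#' @param target_len,overlap Fragmentation geometry (nt).
#' @param fold_structures Fold tested fragments with [fold_baseline()]?
#' @param control_tag `mirna_id` used for the empty-vector control.
#' @param rng_seed Integer seed; the whole bundle is a deterministic
#'   function of the config.
#' @return Object of class `study_config` (a validated list).
#' @export
study_config <- function(n_genes = 20L,
                         utr_length_range = c(200L, 4000L),
                         mirnas = default_mirnas(),
                         sites_per_gene = c(1L, 3L),
                         prop_repressed = 0.60,
                         prop_upregulated = 0.02,
                         repressed_range = c(0.40, 0.88),
                         upregulated_mean = 1.30,
                         noise_sd = 0.05,
                         replicates = 4L,
                         duplicates = 2L,
                         target_len = 675L,
                         overlap = 30L,
                         fold_structures = TRUE,
                         control_tag = "empty",
                         rng_seed = 1L) {
  stopifnot(n_genes >= 1L, length(utr_length_range) == 2L,
            utr_length_range[1L] >= 50L,
            utr_length_range[1L] <= utr_length_range[2L],
            is.list(mirnas), length(mirnas) >= 1L,
            all(vapply(mirnas, inherits, logical(1), "mirna")),
            prop_repressed >= 0, prop_upregulated >= 0,
            prop_repressed + prop_upregulated <= 1,
            all(repressed_range > 0), noise_sd >= 0,
            replicates >= 2L, duplicates >= 1L, target_len > overlap)
  if (is.null(names(mirnas)) || any(!nzchar(names(mirnas)))) {
    names(mirnas) <- vapply(mirnas, function(m) m$name, character(1))
  }
  cfg <- list(n_genes = as.integer(n_genes),
              utr_length_range = as.integer(utr_length_range),
              mirnas = mirnas,
              sites_per_gene = as.integer(sites_per_gene),
              prop_repressed = prop_repressed,
              prop_upregulated = prop_upregulated,
              repressed_range = repressed_range,
              upregulated_mean = upregulated_mean,
              noise_sd = noise_sd,
              replicates = as.integer(replicates),
              duplicates = as.integer(duplicates),
              target_len = as.integer(target_len),
              overlap = as.integer(overlap),
              fold_structures = isTRUE(fold_structures),
              control_tag = control_tag,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "study_config"
  cfg
}

# uniform integer in [lo, hi]; avoids sample()'s scalar surprise
sample_int_range <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# normal draws truncated at 0 (redraw); exact when sd = 0
rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  while (any(x <= 0)) {
    k <- which(x <= 0)
    x[k] <- rnorm(length(k), mean, sd)
  }
  x
}

#' Generate a random UTR sequence with planted binding sites
#'
#' Writes the exact canonical site pattern of each requested (miRNA,
#' site type) at its requested position into a uniform random background,
#' then verifies by rescanning that the sequence contains exactly the
#' planted sites for every miRNA of the panel -- backgrounds that create
#' spurious sites, or flanks that would upgrade a planted site's type, are
#' rejected and re-rolled (up to `max_attempts` times).
#'
#' @param length Sequence length in nt.
#' @param planted `data.frame` with columns `mirna` (panel name),
#'   `site_type` and `position` (1-based start of the full site span).
#'   Zero rows plant nothing.
#' @param mirnas Named list of [mirna()] objects (the screen panel the
#'   guarantee holds for).
#' @param gene,fragment_id Identifiers for the emitted fragment.
#' @param max_attempts Rejection-sampling cap.
#' @return A [utr_fragment()] with the realized site table attached as
#'   attribute `"planted_sites"`.
#' @export
generate_utr <- function(length, planted = NULL, mirnas = default_mirnas(),
                         gene = "gene", fragment_id = "gene_f1",
                         max_attempts = 1000L) {
  length <- as.integer(length)
  stopifnot(length >= 10L)
  if (is.null(planted)) {
    planted <- data.frame(mirna = character(0), site_type = character(0),
                          position = integer(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("mirna", "site_type", "position") %in% names(planted)),
            all(planted$mirna %in% names(mirnas)))
  # expected realized sites
  expected <- planted
  expected$pattern <- vapply(seq_len(nrow(planted)), function(k) {
    site_patterns(mirnas[[planted$mirna[k]]])[[planted$site_type[k]]]
  }, character(1))
  expected$start <- as.integer(planted$position)
  expected$end <- expected$start + nchar(expected$pattern) - 1L
  if (nrow(expected) > 0L) {
    if (any(expected$start < 1L) || any(expected$end > length)) {
      stop("planted site does not fit in the sequence", call. = FALSE)
    }
    ord <- order(expected$start)
    expected <- expected[ord, , drop = FALSE]
    if (nrow(expected) > 1L &&
        any(expected$start[-1L] <= expected$end[-nrow(expected)])) {
      stop("planted sites overlap", call. = FALSE)
    }
  }

  bases <- c("A", "C", "G", "U")
  for (attempt in seq_len(max_attempts)) {
    chars <- sample(bases, length, replace = TRUE)
    for (k in seq_len(nrow(expected))) {
      chars[expected$start[k]:expected$end[k]] <-
        strsplit(expected$pattern[k], "", fixed = TRUE)[[1L]]
    }
    frag <- utr_fragment(gene, fragment_id, paste(chars, collapse = ""))
    ok <- TRUE
    for (nm in names(mirnas)) {
      found <- find_seed_sites(frag, mirnas[[nm]])
      exp_m <- expected[expected$mirna == nm, , drop = FALSE]
      same <- nrow(found) == nrow(exp_m) &&
        (nrow(found) == 0L ||
           (all(found$site_type == exp_m$site_type) &&
              all(found$start == exp_m$start) &&
              all(found$end == exp_m$end)))
      if (!same) { ok <- FALSE; break }
    }
    if (ok) {
      sites <- if (nrow(expected) > 0L) {
        data.frame(gene = gene, fragment_id = fragment_id,
                   mirna = expected$mirna, site_type = expected$site_type,
                   start = expected$start, end = expected$end,
                   target_seq = expected$pattern, stringsAsFactors = FALSE)
      } else {
        empty_sites_df()
      }
      attr(frag, "planted_sites") <- sites
      return(frag)
    }
  }
  stop(sprintf("could not place the requested sites in %d attempts",
               max_attempts), call. = FALSE)
}

#' Simulate dual-luciferase plate measurements
#'
#' Draws firefly/renilla readings such that the per-replicate normalized
#' RLU of each MTI is Normal(true mean, `noise_sd`), truncated at 0.
#' Control-condition ratios have true mean 1.0. The two technical
#' duplicates of a replicate share its ratio (they share a lysate) and
#' differ only in absolute scale.
#'
#' @param mti_truth `data.frame` with columns `construct_id`, `mirna_id`
#'   and `true_mean` (one row per tested MTI).
#' @param noise_sd Replicate noise sd on the normalized scale.
#' @param replicates,duplicates Replicate structure.
#' @param control_tag `mirna_id` emitted for the control condition.
#' @return Plate `data.frame` in the [read_plate_tsv()] schema.
#' @export
generate_plate <- function(mti_truth, noise_sd = 0.05, replicates = 4L,
                           duplicates = 2L, control_tag = "empty") {
  stopifnot(is.data.frame(mti_truth),
            all(c("construct_id", "mirna_id", "true_mean")
                %in% names(mti_truth)),
            all(mti_truth$true_mean > 0), replicates >= 2L, duplicates >= 1L)
  out <- list()
  emit <- function(cid, mid, ratios) {
    for (i in seq_len(replicates)) {
      renilla <- runif(duplicates, 5, 20)
      out[[length(out) + 1L]] <<- data.frame(
        construct_id = cid, mirna_id = mid,
        replicate = i, duplicate = seq_len(duplicates),
        firefly = ratios[i] * renilla, renilla = renilla,
        stringsAsFactors = FALSE)
    }
  }
  for (cid in unique(mti_truth$construct_id)) {
    ctrl <- rnorm_pos(replicates, 1.0, noise_sd)
    emit(cid, control_tag, ctrl)
    rows <- mti_truth[mti_truth$construct_id == cid, , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      norm <- rnorm_pos(replicates, rows$true_mean[k], noise_sd)
      emit(cid, rows$mirna_id[k], norm * ctrl)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a complete synthetic reporter-screen study
#'
#' Produces a self-consistent bundle: a fragment library with planted
#' canonical sites, per-fragment secondary structures (via
#' [fold_baseline()], optional), simulated plates, and truth tables
#' recording every planted site and true effect for downstream recovery
#' scoring. Fully deterministic given `config$rng_seed`.
#'
#' Planted sites are placed strictly inside a single fragment, clear of the
#' inter-fragment overlap zones, so the fragment-level truth is exact.
#'
#' @param config A [study_config()].
#' @return Object of class `study_bundle`: list with `config`, `mirnas`,
#'   `utrs`, `plans`, `fragments`, `truth_sites`, `truth_effects`,
#'   `plate` and `structures`.
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$rng_seed)
  mirnas <- config$mirnas
  site_types <- c("6mer", "7mer-A1", "7mer-m8", "8mer")
  genes <- sprintf("g%03d", seq_len(config$n_genes))

  utrs <- list(); plans <- list(); fragments <- list()
  truth_sites <- list()
  for (g in genes) {
    L <- sample_int_range(config$utr_length_range[1L], config$utr_length_range[2L])
    plan <- plan_fragments(L, config$target_len, config$overlap)
    n_sites <- sample_int_range(config$sites_per_gene[1L], config$sites_per_gene[2L])
    planted <- data.frame(mirna = character(0), site_type = character(0),
                          position = integer(0), stringsAsFactors = FALSE)
    taken <- matrix(numeric(0), ncol = 2L)
    for (s in seq_len(n_sites)) {
      for (try in 1:25) {
        nm <- sample(names(mirnas), 1L)
        ty <- sample(site_types, 1L)
        len <- nchar(site_patterns(mirnas[[nm]])[[ty]])
        k <- sample.int(plan$n_fragments, 1L)
        lo <- plan$intervals$start[k] + config$overlap
        hi <- plan$intervals$end[k] - config$overlap - len
        if (hi < lo) next
        pos <- sample_int_range(lo, hi)
        clash <- nrow(taken) > 0L &&
          any(pos <= taken[, 2L] + 10L & pos + len - 1L >= taken[, 1L] - 10L)
        if (clash) next
        planted <- rbind(planted, data.frame(
          mirna = nm, site_type = ty, position = pos,
          stringsAsFactors = FALSE))
        taken <- rbind(taken, c(pos, pos + len - 1L))
        break
      }
    }
    full <- generate_utr(L, planted, mirnas, gene = g, fragment_id = g)
    utrs[[g]] <- full$sequence
    plans[[g]] <- plan
    frs <- apply_plan(full$sequence, plan, gene = g)
    fragments <- c(fragments, frs)
    ps <- attr(full, "planted_sites")
    if (nrow(ps) > 0L) {
      # lift UTR coordinates onto the unique fragment containing each site
      for (r in seq_len(nrow(ps))) {
        k <- which(plan$intervals$start + config$overlap <= ps$start[r] &
                     plan$intervals$end - config$overlap >= ps$end[r])[1L]
        truth_sites[[length(truth_sites) + 1L]] <- data.frame(
          gene = g, fragment_id = sprintf("%s_f%d", g, k),
          mirna = ps$mirna[r], site_type = ps$site_type[r],
          start = ps$start[r] - plan$intervals$start[k] + 1L,
          end = ps$end[r] - plan$intervals$start[k] + 1L,
          utr_start = ps$start[r], utr_end = ps$end[r],
          target_seq = ps$target_seq[r], stringsAsFactors = FALSE)
      }
    }
  }
  truth_sites <- if (length(truth_sites) > 0L) {
    do.call(rbind, truth_sites)
  } else {
    cbind(empty_sites_df(), utr_start = integer(0), utr_end = integer(0))
  }

  # tested MTIs: fragments harbouring >= 1 site for a panel miRNA
  tested <- unique(truth_sites[, c("fragment_id", "mirna")])
  effects <- NULL
  if (nrow(tested) > 0L) {
    tested <- tested[order(tested$fragment_id, tested$mirna), , drop = FALSE]
    cls <- sample(c("repressed", "upregulated", "null"), nrow(tested),
                  replace = TRUE,
                  prob = c(config$prop_repressed, config$prop_upregulated,
                           1 - config$prop_repressed - config$prop_upregulated))
    mean_of <- function(cl) {
      switch(cl,
             repressed = runif(1, config$repressed_range[1L],
                               config$repressed_range[2L]),
             upregulated = config$upregulated_mean,
             null = 1.0)
    }
    effects <- data.frame(construct_id = tested$fragment_id,
                          mirna_id = tested$mirna,
                          class = cls,
                          true_mean = vapply(cls, mean_of, numeric(1)),
                          stringsAsFactors = FALSE)
    rownames(effects) <- NULL
  }

  plate <- if (!is.null(effects)) {
    generate_plate(effects, config$noise_sd, config$replicates,
                   config$duplicates, config$control_tag)
  } else {
    NULL
  }

  structures <- list()
  if (config$fold_structures && !is.null(effects)) {
    frag_ids <- vapply(fragments, function(f) f$fragment_id, character(1))
    for (cid in unique(effects$construct_id)) {
      f <- fragments[[match(cid, frag_ids)]]
      structures[[cid]] <- fold_baseline(f$sequence)
    }
  }

  structure(
    list(config = config, mirnas = mirnas, utrs = utrs, plans = plans,
         fragments = fragments, truth_sites = truth_sites,
         truth_effects = effects, plate = plate, structures = structures),
    class = "study_bundle"
  )
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf(
    "<study_bundle> seed %d: %d genes, %d fragments, %d planted sites, %d tested MTIs\n",
    x$config$rng_seed, length(x$utrs), length(x$fragments),
    nrow(x$truth_sites),
    if (is.null(x$truth_effects)) 0L else nrow(x$truth_effects)))
  invisible(x)
}

#' Write a study bundle to a directory
#'
#' Emits the file dialects the pipeline readers consume: fragment FASTA,
#' Vienna dot-bracket structures, plate TSV, truth tables, and a plain-text
#' config dump. Every table carries the seed in a `#` header line.
#'
#' @param bundle A [generate_study()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seed_line <- sprintf("# rng_seed: %d", bundle$config$rng_seed)
  write_tsv_hdr <- function(tab, path) {
    con <- file(path, "w")
    writeLines(seed_line, con)
    write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  write_fragments_fasta(bundle$fragments, file.path(dir, "fragments.fasta"))
  mseq <- setNames(
    vapply(bundle$mirnas, function(m) m$sequence, character(1)),
    names(bundle$mirnas))
  Biostrings::writeXStringSet(Biostrings::BStringSet(mseq),
                              file.path(dir, "mirnas.fasta"))
  if (!is.null(bundle$plate)) {
    write_tsv_hdr(bundle$plate, file.path(dir, "plate.tsv"))
  }
  write_tsv_hdr(bundle$truth_sites, file.path(dir, "truth_sites.tsv"))
  if (!is.null(bundle$truth_effects)) {
    write_tsv_hdr(bundle$truth_effects, file.path(dir, "truth_effects.tsv"))
  }
  if (length(bundle$structures) > 0L) {
    write_vienna(bundle$structures, file.path(dir, "structures.dbn"))
  }
  cfg <- bundle$config
  scalars <- cfg[!vapply(cfg, is.list, logical(1))]
  writeLines(c(seed_line,
               paste0(names(scalars), ": ",
                      vapply(scalars, function(v)
                        paste(v, collapse = ","), character(1)))),
             file.path(dir, "config.txt"))
  invisible(dir)
}
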