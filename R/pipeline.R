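#' Pipeline parameters
#'
#' All screen-analysis thresholds in one place, with the conventional
#' defaults: validation cutoff 0.90 on the mean normalized RLU, nominal
#' alpha 0.05, 675/30 nt fragmentation, paired-fraction windows 0/5/50 nt,
#' the [default_radii()] sweep, and minimum-coverage site selection.
#'
#' @param alpha Significance level for validation.
#' @param rlu_cutoff Mean-RLU validation cutoff.
#' @param target_len,overlap Fragmentation geometry (nt).
#' @param windows Paired-fraction window sizes (nt).
#' @param radii Coverage-score radii (length units).
#' @param site_selection How to pick the site feeding the window metrics
#'   when a fragment has several: `"min_coverage"` (most accessible site at
#'   `site_selection_radius`) or `"five_prime_most"`.
#' @param site_selection_radius Radius used by `"min_coverage"` selection.
#' @param control_tag `mirna_id` of the empty-vector control.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(alpha = 0.05, rlu_cutoff = 0.90,
                            target_len = 675L, overlap = 30L,
                            windows = c(0L, 5L, 50L),
                            radii = default_radii(),
                            site_selection = c("min_coverage",
                                               "five_prime_most"),
                            site_selection_radius = 2,
                            control_tag = "empty") {
  stopifnot(alpha > 0, alpha < 1, rlu_cutoff > 0, all(windows >= 0),
            all(radii > 0), site_selection_radius > 0)
  list(alpha = alpha, rlu_cutoff = rlu_cutoff,
       target_len = as.integer(target_len), overlap = as.integer(overlap),
       windows = as.integer(windows), radii = radii,
       site_selection = match.arg(site_selection),
       site_selection_radius = site_selection_radius,
       control_tag = control_tag)
}

#' Run the full screen-analysis pipeline on a study bundle
#'
#' Executes the stages in order -- seed-site scan, reporter statistics,
#' structure accessibility, gene-level network summary, structure-RLU
#' correlation -- and returns every intermediate table. Stages that lack
#' their inputs (no plate, no structures) are skipped with a note in
#' `$log`; a stage failure aborts with a stage-labelled error.
#'
#' @param study A [generate_study()] bundle, or a list with the same
#'   fields (`fragments`, `mirnas`, and optionally `plate`, `structures`).
#' @param params A [pipeline_params()] list.
#' @return Object of class `pipeline_result`: list with `sites`,
#'   `records`, `gene_results`, `network`, `metrics`, `correlations`,
#'   `site_count_correlation`, `params` and `log`.
#' @export
run_pipeline <- function(study, params = pipeline_params()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  # --- scan ---------------------------------------------------------------
  sites <- stage("scan", {
    out <- lapply(study$fragments, function(f) {
      do.call(rbind, lapply(study$mirnas, function(m) find_seed_sites(f, m)))
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
  note("scan: %d sites on %d fragments x %d miRNAs", nrow(sites),
       length(study$fragments), length(study$mirnas))

  # --- stats --------------------------------------------------------------
  records <- NULL
  if (!is.null(study$plate)) {
    records <- stage("stats", {
      screen_statistics(study$plate, control_tag = params$control_tag,
                        rlu_cutoff = params$rlu_cutoff,
                        alpha = params$alpha)
    })
    counts <- table(paste(sites$fragment_id, sites$mirna, sep = "\r"))
    records$site_count <-
      as.integer(counts[paste(records$construct_id, records$mirna,
                              sep = "\r")])
    records$site_count[is.na(records$site_count)] <- 0L
    note("stats: %d MTIs, %d validated", nrow(records),
         sum(records$validated))
  } else {
    note("stats: skipped (no plate data)")
  }

  # --- structure ----------------------------------------------------------
  metrics <- NULL
  if (!is.null(records) && length(study$structures) > 0L) {
    metrics <- stage("structure", {
      rows <- list()
      for (k in seq_len(nrow(records))) {
        cid <- records$construct_id[k]
        st <- study$structures[[cid]]
        if (is.null(st)) next
        ss <- sites[sites$fragment_id == cid &
                      sites$mirna == records$mirna[k], , drop = FALSE]
        if (nrow(ss) == 0L) next
        lay <- layout_2d(st)
        sel <- if (params$site_selection == "min_coverage") {
          attr(min_coverage_over_sites(lay, ss,
                                       params$site_selection_radius),
               "site_index")
        } else {
          1L
        }
        site <- ss[sel, , drop = FALSE]
        for (w in params$windows) {
          rows[[length(rows) + 1L]] <- data.frame(
            construct_id = cid, mirna = records$mirna[k],
            metric = sprintf("paired_fraction_w%d", w), radius = NA_real_,
            value = paired_fraction(st, site, w),
            mean_rlu = records$mean_rlu[k], stringsAsFactors = FALSE)
        }
        for (r in params$radii) {
          rows[[length(rows) + 1L]] <- data.frame(
            construct_id = cid, mirna = records$mirna[k],
            metric = "coverage_score", radius = r,
            value = min_coverage_over_sites(lay, ss, r)$score,
            mean_rlu = records$mean_rlu[k], stringsAsFactors = FALSE)
        }
      }
      res <- do.call(rbind, rows)
      rownames(res) <- NULL
      res
    })
    note("structure: %d metric values", nrow(metrics))
  } else {
    note("structure: skipped (no structures or no records)")
  }

  # --- network ------------------------------------------------------------
  gene_results <- NULL
  network <- NULL
  if (!is.null(records)) {
    gene_results <- stage("network", aggregate_gene_level(records))
    network <- stage("network", build_network(gene_results))
    note("network: %d gene-level MTIs, %d edges", nrow(gene_results),
         network$summary$n_edges)
  }

  # --- correlate ----------------------------------------------------------
  correlations <- NULL
  site_count_corr <- NULL
  if (!is.null(metrics)) {
    correlations <- stage("correlate", structure_rlu_scan(metrics))
    note("correlate: %d correlation cells", nrow(correlations))
  }
  if (!is.null(records)) {
    site_count_corr <- stage("correlate",
                             site_count_rlu_correlation(records))
  }

  structure(
    list(sites = sites, records = records, gene_results = gene_results,
         network = network, metrics = metrics, correlations = correlations,
         site_count_correlation = site_count_corr, params = params,
         log = log),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' Volcano plot of per-MTI screen results
#'
#' Mean normalized RLU against -log10 p; the validation region (RLU below
#' the cutoff at p below alpha) sits in the upper left.
#'
#' @param records Per-MTI table from [screen_statistics()].
#' @param rlu_cutoff,alpha Thresholds to draw.
#' @return Invisibly, `records`.
#' @export
plot_volcano <- function(records, rlu_cutoff = 0.90, alpha = 0.05) {
  stopifnot(all(c("mean_rlu", "p_value", "validated") %in% names(records)))
  plot(records$mean_rlu, -log10(records$p_value),
       col = ifelse(records$validated, "firebrick", "grey40"),
       pch = 16, xlab = "mean normalized RLU", ylab = "-log10(p)",
       main = "reporter screen")
  abline(v = rlu_cutoff, lty = 2)
  abline(h = -log10(alpha), lty = 2)
  invisible(records)
}
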