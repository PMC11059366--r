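#' Read a reporter-assay plate table
#'
#' Long-format TSV with columns `construct_id`, `mirna_id`, `replicate`,
#' `duplicate`, `firefly`, `renilla`. The empty miRNA expression vector
#' control carries a reserved `mirna_id` tag (default `"empty"`). Comment
#' lines starting with `#` are ignored.
#'
#' @param path TSV file path.
#' @return `data.frame` with the schema above.
#' @export
read_plate_tsv <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("construct_id", "mirna_id", "replicate", "duplicate",
              "firefly", "renilla")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0L) {
    stop(sprintf("plate table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tab
}

# per-replicate firefly/renilla ratios, technical duplicates averaged
replicate_ratios <- function(plate, construct, mirna_id) {
  rows <- plate[plate$construct_id == construct &
                  plate$mirna_id == mirna_id, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop(sprintf("no measurements for construct '%s' x '%s'",
                 construct, mirna_id), call. = FALSE)
  }
  if (any(rows$renilla <= 0) || any(rows$firefly <= 0)) {
    stop("non-positive luminescence reading", call. = FALSE)
  }
  rows$ratio <- rows$firefly / rows$renilla
  agg <- aggregate(ratio ~ replicate, data = rows, FUN = mean)
  setNames(agg$ratio, agg$replicate)
}

#' Normalize reporter readings to the empty-vector control
#'
#' Within each biological replicate, the firefly/renilla ratio is averaged
#' over the technical duplicates (duplicates share a lysate and are not
#' independent); the test-condition ratio is then divided by the
#' control-condition ratio of the same replicate. The result is the
#' normalized RLU: 1.0 means no effect, values below 1 repression.
#'
#' @param plate Plate table (see [read_plate_tsv()]).
#' @param construct Construct identifier.
#' @param mirna_id miRNA condition to normalize.
#' @param control_tag `mirna_id` of the empty expression-vector control.
#' @return Named numeric vector of per-replicate normalized RLU fractions.
#' @export
normalize_rlu <- function(plate, construct, mirna_id, control_tag = "empty") {
  test <- replicate_ratios(plate, construct, mirna_id)
  ctrl <- replicate_ratios(plate, construct, control_tag)
  if (!setequal(names(test), names(ctrl))) {
    stop("test and control conditions cover different replicates",
         call. = FALSE)
  }
  reps <- sort(names(test))
  test[reps] / ctrl[reps]
}

#' Welch's two-sample t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom,
#' two-sided, as used for per-construct test-versus-control comparisons.
#'
#' @param a,b Numeric samples, each with at least 2 observations; at least
#'   one sample must have nonzero variance.
#' @return List with `t`, `df` and `p`.
#' @export
welch_t_test <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("both samples have zero variance; the test is undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Validation call and repression category for one MTI
#'
#' An MTI is validated when the mean normalized RLU drops below the cutoff
#' (default 0.90, i.e. < 90% of the empty-vector control) AND the Welch
#' p value is below `alpha` (default 0.05, nominal). Categories bin the
#' effect size: `strong` (< 0.70), `moderate` (0.70 to < 0.90), `none`
#' (0.90 to 1.10), `upregulated` (> 1.10 with p < `alpha`; symmetric to the
#' repression cutoff).
#'
#' @param mean_rlu Mean normalized RLU fraction(s).
#' @param p Welch p value(s), same length.
#' @param rlu_cutoff Validation cutoff on the mean RLU (default 0.90).
#' @param alpha Significance level (default 0.05).
#' @param up_cutoff Up-regulation cutoff (default 1.10).
#' @return `data.frame` with columns `validated` (logical) and `category`.
#' @examples
#' validate_mti(c(0.85, 0.95, 0.85), c(0.01, 0.001, 0.20))
#' @export
validate_mti <- function(mean_rlu, p, rlu_cutoff = 0.90, alpha = 0.05,
                         up_cutoff = 1.10) {
  stopifnot(length(mean_rlu) == length(p))
  validated <- mean_rlu < rlu_cutoff & p < alpha
  category <- ifelse(mean_rlu > up_cutoff & p < alpha, "upregulated",
              ifelse(mean_rlu < 0.70, "strong",
              ifelse(mean_rlu < rlu_cutoff, "moderate", "none")))
  data.frame(validated = validated, category = category,
             stringsAsFactors = FALSE)
}

#' Per-MTI screen statistics from a plate table
#'
#' For every (construct, miRNA) test condition: normalized RLU replicates,
#' their mean, the Welch p value of the test-versus-control replicate
#' ratios, the validation flag and category, and a Benjamini-Hochberg
#' adjusted p value as supplementary output (validation itself uses the
#' nominal p, per the screen's validation rule).
#'
#' @param plate Plate table (see [read_plate_tsv()]).
#' @param gene_map Optional `data.frame` with `construct_id` and `gene`
#'   columns; by default the gene is the construct id up to the last
#'   `"_f<k>"` suffix.
#' @param control_tag `mirna_id` of the empty-vector control.
#' @inheritParams validate_mti
#' @return `data.frame` with one row per MTI: `construct_id`, `gene`,
#'   `mirna`, `rlu_1` to `rlu_<n>`, `mean_rlu`, `p_value`, `p_adj`,
#'   `validated`, `category`.
#' @export
screen_statistics <- function(plate, gene_map = NULL, control_tag = "empty",
                              rlu_cutoff = 0.90, alpha = 0.05) {
  conds <- unique(plate[plate$mirna_id != control_tag,
                        c("construct_id", "mirna_id")])
  if (nrow(conds) == 0L) {
    stop("plate table has no test conditions", call. = FALSE)
  }
  conds <- conds[order(conds$construct_id, conds$mirna_id), , drop = FALSE]
  rows <- lapply(seq_len(nrow(conds)), function(k) {
    cid <- conds$construct_id[k]
    mid <- conds$mirna_id[k]
    norm <- normalize_rlu(plate, cid, mid, control_tag)
    wt <- welch_t_test(unname(replicate_ratios(plate, cid, mid)),
                       unname(replicate_ratios(plate, cid, control_tag)))
    out <- data.frame(construct_id = cid, mirna = mid,
                      t(setNames(unname(norm),
                                 paste0("rlu_", seq_along(norm)))),
                      mean_rlu = mean(norm), p_value = wt$p,
                      stringsAsFactors = FALSE)
    out
  })
  res <- do.call(rbind, rows)
  res$gene <- if (!is.null(gene_map)) {
    gene_map$gene[match(res$construct_id, gene_map$construct_id)]
  } else {
    sub("_f[0-9]+$", "", res$construct_id)
  }
  res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  res <- cbind(res, validate_mti(res$mean_rlu, res$p_value,
                                 rlu_cutoff = rlu_cutoff, alpha = alpha))
  rownames(res) <- NULL
  res
}

#' Aggregate fragment-level MTI results to the gene level
#'
#' A gene is represented by the maximal reduction (minimum mean RLU) and
#' the maximal significance (minimum p value) over all its fragments; it is
#' validated if any fragment is. The two minima are taken independently and
#' may come from different fragments.
#'
#' @param records Per-MTI table from [screen_statistics()] (columns `gene`,
#'   `mirna`, `mean_rlu`, `p_value`, `validated`).
#' @return `data.frame` with one row per (gene, miRNA): `gene`, `mirna`,
#'   `best_rlu`, `best_p`, `n_fragments`, `validated`.
#' @export
aggregate_gene_level <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L,
            all(c("gene", "mirna", "mean_rlu", "p_value", "validated")
                %in% names(records)))
  key <- interaction(records$gene, records$mirna, drop = TRUE, sep = "\r")
  parts <- split(records, key)
  rows <- lapply(parts, function(d) {
    data.frame(gene = d$gene[1L], mirna = d$mirna[1L],
               best_rlu = min(d$mean_rlu), best_p = min(d$p_value),
               n_fragments = nrow(d), validated = any(d$validated),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validation rate, in percent
#'
#' Either give validated and tested counts, or a records table with a
#' `validated` column (and optionally a `mirna` column to stratify by).
#'
#' @param x Count of validated MTIs, or a records `data.frame`.
#' @param tested Count of tested MTIs (when `x` is a count).
#' @param by Grouping column when `x` is a `data.frame` (default
#'   `"mirna"`; use `NULL` for one overall rate).
#' @return A percentage (one decimal), or a `data.frame` of per-group
#'   `tested`, `validated`, `rate`.
#' @examples
#' validation_rate(76, 95)   # 80.0
#' validation_rate(96, 190)  # 50.5
#' @export
validation_rate <- function(x, tested = NULL, by = "mirna") {
  if (is.data.frame(x)) {
    stopifnot("validated" %in% names(x), nrow(x) >= 1L)
    if (is.null(by)) {
      return(round(100 * sum(x$validated) / nrow(x), 1L))
    }
    parts <- split(x, x[[by]])
    out <- do.call(rbind, lapply(names(parts), function(g) {
      d <- parts[[g]]
      data.frame(group = g, tested = nrow(d), validated = sum(d$validated),
                 rate = round(100 * sum(d$validated) / nrow(d), 1L),
                 stringsAsFactors = FALSE)
    }))
    names(out)[1L] <- by
    return(out)
  }
  stopifnot(is.numeric(x), is.numeric(tested), tested >= 1L, x >= 0L)
  round(100 * x / tested, 1L)
}

#' Number of single transfections in a screen
#'
#' Plates times biological replicates times wells per plate; fractional
#' plate counts are allowed (a partially filled final plate).
#'
#' @param n_plates Number of 96-well plates (may be fractional).
#' @param n_replicates Biological replicates (default 4).
#' @param wells_per_plate Wells per plate (default 96).
#' @return Transfection count.
#' @examples
#' count_transfections(35.25)  # 13536
#' @export
count_transfections <- function(n_plates, n_replicates = 4L,
                                wells_per_plate = 96L) {
  stopifnot(n_plates > 0, n_replicates >= 1L, wells_per_plate >= 1L)
  n_plates * n_replicates * wells_per_plate
}
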