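#' Pearson correlation with a two-sided t-based p value
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, each with nonzero
#'   variance.
#' @return List with `r`, `p` and `n`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("at least 3 observations are required", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation is undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlate structural accessibility metrics with measured repression
#'
#' Runs a Pearson correlation between each accessibility metric and the
#' mean normalized RLU, separately per miRNA and (for the coverage score)
#' per radius. Cells with fewer than 3 MTIs or a constant metric are
#' flagged, not dropped silently.
#'
#' @param mti_table Long-format `data.frame` with columns `mirna`, `metric`
#'   (e.g. `"paired_fraction_w0"`, `"coverage_score"`), `radius` (`NA` for
#'   window metrics), `value` and `mean_rlu`.
#' @return `data.frame` with one row per (miRNA, metric, radius):
#'   `pearson_r`, `p_value`, `n`, `flag` (`"ok"`, `"insufficient_n"` or
#'   `"zero_variance"`).
#' @export
structure_rlu_scan <- function(mti_table) {
  stopifnot(is.data.frame(mti_table),
            all(c("mirna", "metric", "radius", "value", "mean_rlu")
                %in% names(mti_table)))
  key <- interaction(mti_table$mirna, mti_table$metric,
                     ifelse(is.na(mti_table$radius), "-", mti_table$radius),
                     drop = TRUE, sep = "\r")
  parts <- split(mti_table, key)
  rows <- lapply(parts, function(d) {
    out <- data.frame(mirna = d$mirna[1L], metric = d$metric[1L],
                      radius = d$radius[1L], pearson_r = NA_real_,
                      p_value = NA_real_, n = nrow(d), flag = "ok",
                      stringsAsFactors = FALSE)
    if (nrow(d) < 3L) {
      out$flag <- "insufficient_n"
    } else if (stats::var(d$value) == 0 || stats::var(d$mean_rlu) == 0) {
      out$flag <- "zero_variance"
    } else {
      pc <- pearson_correlation(d$value, d$mean_rlu)
      out$pearson_r <- pc$r
      out$p_value <- pc$p
    }
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna, out$metric, out$radius), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlation between binding-site count and repression
#'
#' Pearson correlation of the number of seed-match sites per construct
#' against the mean normalized RLU. A constant site count makes the
#' correlation undefined; the result is then flagged instead of erroring.
#'
#' @param mti_table `data.frame` with columns `site_count` and `mean_rlu`.
#' @return List with `r`, `p`, `n` and `flag`.
#' @export
site_count_rlu_correlation <- function(mti_table) {
  stopifnot(is.data.frame(mti_table),
            all(c("site_count", "mean_rlu") %in% names(mti_table)))
  n <- nrow(mti_table)
  if (n < 3L) {
    return(list(r = NA_real_, p = NA_real_, n = n, flag = "insufficient_n"))
  }
  if (stats::var(mti_table$site_count) == 0 ||
      stats::var(mti_table$mean_rlu) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, flag = "zero_variance"))
  }
  pc <- pearson_correlation(mti_table$site_count, mti_table$mean_rlu)
  c(pc, list(flag = "ok"))
}
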