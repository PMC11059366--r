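#' Bipartite miRNA-target interaction network
#'
#' Treats each gene-level MTI as an edge in the complete bipartite graph
#' between the gene universe and the screened miRNAs. Every edge carries
#' three evidence flags: `predicted` (computational evidence), `tested`
#' (measured in the screen) and `validated` (tested and passing the
#' validation rule). `validated` implies `tested`; `predicted` is
#' independent of both.
#'
#' @param gene_results Gene-level table from [aggregate_gene_level()]
#'   (columns `gene`, `mirna`, `validated`); every row counts as tested.
#' @param predictions Optional `data.frame` with `gene` and `mirna` columns
#'   listing computationally predicted MTIs. Default: the tested set.
#' @param genes,mirnas Optional explicit node universes; default: all
#'   identifiers seen in `gene_results` and `predictions`.
#' @return Object of class `mti_network`: list with `graph` (bipartite
#'   [igraph::graph]), `edges` (per-edge flag table) and `summary`.
#' @examples
#' gr <- data.frame(gene = c("g1", "g2"), mirna = "m1",
#'                  validated = c(TRUE, FALSE))
#' build_network(gr)$summary
#' @export
build_network <- function(gene_results, predictions = NULL,
                          genes = NULL, mirnas = NULL) {
  stopifnot(is.data.frame(gene_results),
            all(c("gene", "mirna", "validated") %in% names(gene_results)))
  if (is.null(predictions)) {
    predictions <- gene_results[, c("gene", "mirna")]
  }
  genes <- sort(unique(c(genes, gene_results$gene, predictions$gene)))
  mirnas <- sort(unique(c(mirnas, gene_results$mirna, predictions$mirna)))

  edges <- expand.grid(gene = genes, mirna = mirnas,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tkey <- paste(gene_results$gene, gene_results$mirna, sep = "\r")
  pkey <- paste(predictions$gene, predictions$mirna, sep = "\r")
  vkey <- tkey[gene_results$validated]
  ekey <- paste(edges$gene, edges$mirna, sep = "\r")
  edges$predicted <- ekey %in% pkey
  edges$tested <- ekey %in% tkey
  edges$validated <- ekey %in% vkey

  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(genes), name = genes, type = FALSE)
  g <- igraph::add_vertices(g, length(mirnas), name = mirnas, type = TRUE)
  g <- igraph::add_edges(g, rbind(match(edges$gene, genes),
                                  length(genes) + match(edges$mirna, mirnas)))
  igraph::E(g)$predicted <- edges$predicted
  igraph::E(g)$tested <- edges$tested
  igraph::E(g)$validated <- edges$validated

  n_pred <- sum(edges$predicted)
  n_val_pred <- sum(edges$validated & edges$predicted)
  val_per_gene <- tapply(edges$validated, edges$gene, sum)
  hist <- c(table(factor(val_per_gene, levels = 0:length(mirnas))))
  summary <- list(
    n_genes = length(genes),
    n_mirnas = length(mirnas),
    n_edges = nrow(edges),
    n_predicted = n_pred,
    n_tested = sum(edges$tested),
    n_validated = sum(edges$validated),
    n_validated_predicted = n_val_pred,
    pct_predicted = round(100 * n_pred / nrow(edges), 1L),
    confirmation_rate = if (n_pred > 0L)
      round(100 * n_val_pred / n_pred, 1L) else NA_real_,
    pct_validated_predicted = round(100 * n_val_pred / nrow(edges), 1L),
    genes_by_validated_mirnas = hist
  )
  structure(list(graph = g, edges = edges, summary = summary),
            class = "mti_network")
}

#' @export
print.mti_network <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<mti_network> %d genes x %d miRNAs = %d edges\n  predicted %d (%.1f%%), tested %d, validated&predicted %d (confirmation %.1f%%)\n",
    s$n_genes, s$n_mirnas, s$n_edges, s$n_predicted, s$pct_predicted,
    s$n_tested, s$n_validated_predicted, s$confirmation_rate))
  invisible(x)
}

#' Export an MTI network
#'
#' @param network An [build_network()] result.
#' @param path Output path.
#' @param format `"tsv"` (edge list with flags) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(network$edges, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    igraph::write_graph(network$graph, path, format = "graphml")
  }
  invisible(path)
}

#' Fold increase in validated MTIs over a prior database
#'
#' @param prior_count Previously deposited validated MTIs (>= 1).
#' @param new_total Validated MTIs after the screen.
#' @return Ratio `new_total / prior_count`, rounded to one decimal.
#' @examples
#' fold_increase(3, 55)  # 18.3
#' @export
fold_increase <- function(prior_count, new_total) {
  stopifnot(is.numeric(prior_count), is.numeric(new_total))
  if (any(prior_count < 1)) {
    stop("prior_count must be >= 1; the ratio is undefined otherwise",
         call. = FALSE)
  }
  round(new_total / prior_count, 1L)
}

#' Size of the miRNA-target interaction space
#'
#' The number of conceivable MTIs between a gene universe and a miRNA
#' complement: the plain product of the two counts.
#'
#' @param n_genes Number of (protein-coding) genes.
#' @param n_mirnas Number of miRNAs.
#' @return `n_genes * n_mirnas` as a double.
#' @examples
#' mti_space_size(19379, 2300)  # 44571700
#' @export
mti_space_size <- function(n_genes, n_mirnas) {
  stopifnot(n_genes >= 1, n_mirnas >= 1)
  as.numeric(n_genes) * as.numeric(n_mirnas)
}
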