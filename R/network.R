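#' Read an interaction edge table
#'
#' Three-column tab-delimited file: `geneA`, `geneB`, `score` with scores in
#' `[0, 1]` (e.g. an export of a functional-association database).
#' Malformed rows (missing genes, unparseable or out-of-range scores,
#' self-loops) are skipped; the number skipped is reported in a message.
#'
#' @param path edge file.
#' @return data frame with columns `geneA`, `geneB`, `score`.
#' @export
read_edge_table <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("edge table needs 3 columns (geneA, geneB, score)")
  out <- data.frame(geneA = toupper(as.character(raw[[1]])),
                    geneB = toupper(as.character(raw[[2]])),
                    score = suppressWarnings(as.numeric(raw[[3]])),
                    stringsAsFactors = FALSE)
  ok <- nzchar(out$geneA) & nzchar(out$geneB) & out$geneA != out$geneB &
    is.finite(out$score) & out$score >= 0 & out$score <= 1
  if (any(!ok)) message(sum(!ok), " malformed edge row(s) skipped")
  out[ok, , drop = FALSE]
}

#' Assemble the confidence-filtered functional network of interactor calls
#'
#' Builds an undirected graph whose nodes are the genes called at tier
#' `potential_interactor` or above; edges from the supplied table are kept
#' when their confidence score is at least `min_score` and both endpoints
#' are call genes.  Call genes without any retained edge remain as isolated
#' nodes.  Node attributes carry the enrichment level (`median_log2_hm`) and
#' whether the call was stress-induced (`aph_induced`), mirroring the usual
#' color/shape encoding of such networks.
#'
#' @param calls an `interactor_calls` data frame.
#' @param edges edge data frame as from [read_edge_table()].
#' @param min_score minimum confidence score, default 0.4.
#' @return an [igraph::igraph] object.
#' @export
build_network <- function(calls, edges, min_score = 0.4) {
  stopifnot(inherits(calls, "interactor_calls"),
            is.numeric(min_score), length(min_score) == 1L)
  sel <- calls$tier %in% c("potential_interactor", "aph_induced")
  nodes <- calls[sel, , drop = FALSE]
  nodes$gene <- toupper(nodes$gene_names)
  nodes <- nodes[!duplicated(nodes$gene) & nzchar(nodes$gene), , drop = FALSE]

  if (nrow(edges)) {
    keep <- edges$score >= min_score &
      toupper(edges$geneA) %in% nodes$gene &
      toupper(edges$geneB) %in% nodes$gene
    kept <- edges[keep, , drop = FALSE]
  } else {
    kept <- data.frame(geneA = character(0), geneB = character(0),
                       score = numeric(0))
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = toupper(kept$geneA), to = toupper(kept$geneB),
                   score = kept$score),
    directed = FALSE,
    vertices = data.frame(name = nodes$gene,
                          median_log2_hm = nodes$median_log2_hm,
                          aph_induced = nodes$tier == "aph_induced"))
  igraph::simplify(g, edge.attr.comb = "max")
}

#' Write a network as GraphML
#'
#' @param graph an [igraph::igraph] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
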