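#' Classify an edge's interaction from its fitted weight
#'
#' A `binding/association` annotation from the catalog is kept regardless of
#' the weight's sign (the weight only quantifies the strength of the
#' association); otherwise a negative weight is `inhibition` and a positive
#' weight `activation`.
#'
#' @param weight Nonzero numeric weight(s).
#' @param catalog_type Optional catalog interaction type(s) (`NA` or `NULL`
#'   when the pair is not in the catalog).
#' @return Character vector of interaction labels.
#' @export
classify_interaction <- function(weight, catalog_type = NULL) {
  if (any(weight == 0)) stop("cannot classify a zero weight")
  if (is.null(catalog_type)) catalog_type <- rep(NA_character_, length(weight))
  catalog_type <- rep_len(as.character(catalog_type), length(weight))
  ifelse(!is.na(catalog_type) & catalog_type == "binding/association",
         "binding/association",
         ifelse(weight < 0, "inhibition", "activation"))
}

#' Extract signed edges from a fitted CTRNN
#'
#' Keeps every off-diagonal weight whose magnitude reaches
#' `rel_threshold * max |W|` (the threshold is relative because the absolute
#' scale of fitted weights is arbitrary under per-gene rescaling).
#' Each kept edge j -> i is labeled with `database` provenance when the pair
#' is present in the catalog, else `computed`, and typed by
#' [classify_interaction()]. Self-loops are dropped.
#'
#' @param model A fitted [ctrnn_model()].
#' @param catalog Optional [interaction_catalog()].
#' @param rel_threshold Fraction of the maximum absolute off-diagonal weight.
#' @return A [network_edges()] table, sorted by decreasing `|weight|`. An
#'   all-zero weight matrix yields an empty table.
#' @export
extract_edges <- function(model, catalog = NULL, rel_threshold = 0.10) {
  stopifnot(inherits(model, "CTRNNModel"))
  stopifnot(rel_threshold >= 0, rel_threshold <= 1)
  W <- model$W
  diag(W) <- 0
  maxw <- max(abs(W))
  if (maxw == 0) return(network_edges())
  keep <- which(W != 0 & abs(W) >= rel_threshold * maxw, arr.ind = TRUE)
  src <- model$gene_ids[keep[, 2]]
  tgt <- model$gene_ids[keep[, 1]]
  w <- W[keep]
  ctype <- catalog_type(catalog, src, tgt)
  edges <- network_edges(source = src, target = tgt, weight = w,
                         interaction = classify_interaction(w, ctype),
                         provenance = ifelse(is.na(ctype), "computed",
                                             "database"))
  edges <- edges[order(-abs(edges$weight), edges$source, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  class(edges) <- c("NetworkEdges", "data.frame")
  edges
}

#' Rank genes by their summed outgoing edge weight
#'
#' The regulator score of a gene is the sum of `|weight|` over its outgoing
#' edges — its aggregate effect on downstream targets. Genes are ranked in
#' decreasing score order (ties broken by out-degree, then gene id, for row
#' order; genes tied on both share the smallest rank).
#'
#' @param edges A [network_edges()] table.
#' @return Data frame `gene_id`, `out_weight_sum`, `out_degree`, `rank`,
#'   covering every gene incident to an edge. Empty edges give an empty
#'   ranking.
#' @export
rank_regulators <- function(edges) {
  stopifnot(inherits(edges, "NetworkEdges"))
  genes <- sort(unique(c(edges$source, edges$target)))
  if (!length(genes))
    return(data.frame(gene_id = character(), out_weight_sum = numeric(),
                      out_degree = integer(), rank = integer(),
                      stringsAsFactors = FALSE))
  ws <- vapply(genes, function(g) sum(abs(edges$weight[edges$source == g])),
               numeric(1))
  deg <- vapply(genes, function(g) sum(edges$source == g), integer(1))
  ord <- order(-ws, -deg, genes)
  res <- data.frame(gene_id = genes[ord], out_weight_sum = unname(ws[ord]),
                    out_degree = unname(deg[ord]),
                    stringsAsFactors = FALSE)
  key <- paste(res$out_weight_sum, res$out_degree)
  res$rank <- match(key, key)  # min rank among exact ties, else row position
  rownames(res) <- NULL
  res
}

#' Decompose a network into weakly connected sub-networks
#'
#' @param edges A [network_edges()] table.
#' @return List of sub-networks ordered by node count (decreasing), each a
#'   list with `nodes` (sorted gene ids) and `edges` (the induced edge
#'   table).
#' @export
decompose_subnetworks <- function(edges) {
  stopifnot(inherits(edges, "NetworkEdges"))
  if (!nrow(edges)) return(list())
  g <- igraph::graph_from_data_frame(as.data.frame(edges)[, c("source", "target")],
                                     directed = TRUE)
  comp <- igraph::components(g, mode = "weak")
  membership <- comp$membership
  subs <- lapply(seq_len(comp$no), function(ci) {
    nodes <- sort(names(membership)[membership == ci])
    sel <- edges$source %in% nodes | edges$target %in% nodes
    e <- edges[sel, , drop = FALSE]
    rownames(e) <- NULL
    class(e) <- c("NetworkEdges", "data.frame")
    list(nodes = nodes, edges = e)
  })
  sizes <- vapply(subs, function(s) length(s$nodes), integer(1))
  first <- vapply(subs, function(s) s$nodes[1], "")
  subs[order(-sizes, first)]
}
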