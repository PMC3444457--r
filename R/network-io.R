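#' Construct a network edge table
#'
#' Signed, weighted, directed edges extracted from a fitted dynamic model.
#' Each edge carries an interaction label (`activation`, `inhibition`,
#' `binding/association`, `other`) and a provenance flag: `database` when the
#' pair was present in the prior interaction catalog, `computed` when it
#' emerged from the model fit alone.
#'
#' @param source,target Character vectors of gene ids.
#' @param weight Numeric, nonzero fitted weights.
#' @param interaction Character, from the closed interaction vocabulary.
#' @param provenance Character, `"database"` or `"computed"`.
#' @return An object of class `NetworkEdges` (a data frame).
#' @export
network_edges <- function(source = character(), target = character(),
                          weight = numeric(), interaction = character(),
                          provenance = character()) {
  n <- length(source)
  stopifnot(length(target) == n, length(weight) == n,
            length(interaction) == n, length(provenance) == n)
  if (any(weight == 0)) stop("edge weights must be nonzero")
  if (any(!interaction %in% INTERACTION_TYPES))
    stop("interaction labels must be one of: ",
         paste(INTERACTION_TYPES, collapse = ", "))
  if (any(!provenance %in% c("database", "computed")))
    stop("provenance must be 'database' or 'computed'")
  edges <- data.frame(source = as.character(source),
                      target = as.character(target),
                      weight = as.numeric(weight),
                      interaction = as.character(interaction),
                      provenance = as.character(provenance),
                      stringsAsFactors = FALSE)
  class(edges) <- c("NetworkEdges", "data.frame")
  edges
}

#' Write a network to disk
#'
#' Three formats: `"edge-table"` (TSV with columns source, target, weight,
#' interaction, provenance; round-trips with [read_network()]), `"sif"`
#' (simple interaction format, `source<TAB>type<TAB>target`) and
#' `"graphml"` (via igraph, with weight/interaction/provenance as edge
#' attributes).
#'
#' @param edges A `NetworkEdges` object.
#' @param path Output path.
#' @param format One of `"edge-table"`, `"sif"`, `"graphml"`.
#' @return Invisibly, `edges`.
#' @export
write_network <- function(edges, path, format = c("edge-table", "sif", "graphml")) {
  stopifnot(inherits(edges, "NetworkEdges"))
  format <- match.arg(format)
  if (format == "edge-table") {
    tab <- as.data.frame(edges)
    tab$weight <- sprintf("%.17g", tab$weight)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    writeLines(paste(edges$source, edges$interaction, edges$target, sep = "\t"),
               path)
  } else {
    g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = TRUE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(edges)
}

#' Read a network edge table or GraphML file
#'
#' @param path Input path.
#' @param format `"edge-table"` or `"graphml"` (SIF drops weights and
#'   provenance and has no reader).
#' @return A [network_edges()] object.
#' @export
read_network <- function(path, format = c("edge-table", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edge-table") {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    req <- c("source", "target", "weight", "interaction", "provenance")
    miss <- setdiff(req, names(tab))
    if (length(miss))
      stop("edge table missing column(s): ", paste(miss, collapse = ", "))
    network_edges(tab$source, tab$target, as.numeric(tab$weight),
                  tab$interaction, tab$provenance)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    network_edges(el$from, el$to, as.numeric(el$weight), el$interaction,
                  el$provenance)
  }
}
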