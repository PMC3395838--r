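## Graph export: SIF for quick Cytoscape import, GraphML with full node
## and edge attributes (including edge rendering hints), and a plain TSV
## edge list.

sifRelation <- function(category, sign) {
  ifelse(category == "ppi", "binds",
  ifelse(category == "kinase_substrate", "phosphorylates",
  ifelse(category == "mirna_target", "targets",
  ifelse(sign == "activation", "activates",
  ifelse(sign == "repression", "represses", "regulates")))))
}

edgeColor <- function(sign) {
  c(activation = "#00AA00", repression = "#CC0000",
    ambiguous = "#8A2BE2", none = "#888888")[sign]
}

edgeArrowhead <- function(sign) {
  c(activation = "arrow", repression = "tee",
    ambiguous = "dot", none = "none")[sign]
}

#' Export a mixed graph
#'
#' `sif` writes one gene-level line per interaction using the relation
#' tokens `activates` / `represses` / `regulates` / `binds` / `targets` /
#' `phosphorylates`. `graphml` writes the instance-level graph with node
#' attributes (`gene_id`, `compartment`, `x`, `y`, `has_regulatory_info`)
#' and edge attributes (`category`, `sign`, `provenance`, plus the
#' rendering hints `color` and `arrowhead`: activation green/arrow,
#' repression red/T, ambiguous violet/dot). `tsv` writes the instance
#' edge list.
#'
#' @param graph A [MixedGraph-class].
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @param file Optional output path; when `NULL` the document is only
#'   returned.
#' @return Character vector of output lines, invisibly when `file` is
#'   given.
#' @export
exportGraph <- function(graph, format = c("sif", "graphml", "tsv"),
                        file = NULL) {
  format <- match.arg(format)
  edges <- graphEdges(graph)
  lines <- switch(format,
    sif = {
      g <- unique(edges[c("source_id", "target_id", "category", "sign")])
      if (nrow(g) == 0L) character(0) else {
        sprintf("%s %s %s", g$source_id,
                sifRelation(g$category, g$sign), g$target_id)
      }
    },
    tsv = {
      cols <- c("from", "to", "source_id", "target_id", "category", "sign",
                "directed", "provenance")
      c(paste(cols, collapse = "\t"),
        if (nrow(edges) > 0L) {
          do.call(sprintf, c(list(paste(rep("%s", length(cols)), collapse = "\t")),
                             lapply(edges[cols], as.character)))
        })
    },
    graphml = {
      ig <- asIgraph(graph)
      tmp <- tempfile(fileext = ".graphml")
      igraph::write_graph(ig, tmp, format = "graphml")
      on.exit(unlink(tmp))
      readLines(tmp)
    }
  )
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Convert a mixed graph to an igraph object
#'
#' Instance-level directed igraph carrying all node and edge attributes
#' written by the GraphML export. Undirected physical edges are encoded
#' with the `directed` edge attribute set to `FALSE`.
#'
#' @param graph A [MixedGraph-class].
#' @return An [igraph::graph] object.
#' @export
asIgraph <- function(graph) {
  inst <- graphInstances(graph)
  edges <- graphEdges(graph)
  ig <- igraph::make_empty_graph(n = 0, directed = TRUE)
  ig <- igraph::add_vertices(ig, nrow(inst),
    name = inst$instance_id, gene_id = inst$gene_id,
    compartment = inst$compartment, x = inst$x, y = inst$y,
    has_regulatory_info = inst$has_regulatory_info)
  if (nrow(edges) > 0L) {
    idx <- rbind(match(edges$from, inst$instance_id),
                 match(edges$to, inst$instance_id))
    ig <- igraph::add_edges(ig, as.vector(idx),
      category = edges$category, sign = edges$sign,
      directed = edges$directed, provenance = edges$provenance,
      color = unname(edgeColor(edges$sign)),
      arrowhead = unname(edgeArrowhead(edges$sign)))
  }
  ig
}

#' Read a GraphML file
#'
#' Thin wrapper over [igraph::read_graph()] used to verify export round
#' trips.
#'
#' @param file Path to a GraphML document.
#' @return An [igraph::graph] object.
#' @export
readGraphml <- function(file) {
  igraph::read_graph(file, format = "graphml")
}
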