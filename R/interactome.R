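## Compartment assignment, mixed-graph construction, filters and
## neighborhood expansion.

#' Map genes onto compartments of the tree
#'
#' Each annotated cellular-component term is mapped to itself when it is a
#' tree node, otherwise walked up its stated ancestry (the `ontology`
#' parent table) to the nearest tree term; a precisely annotated product
#' lands in a leaf zone while a coarsely annotated one lands in a higher
#' zone. Genes with no usable annotation get the fallback compartment.
#'
#' @param geneIds Character vector of genes to place.
#' @param ccMap data.frame `gene_id`, `cc_term` (a gene may map to several
#'   terms), or `NULL`.
#' @param tree A [CompartmentTree-class].
#' @param ontology Optional data.frame `term_id`, `parent` giving the
#'   ancestry of terms outside the tree subset.
#' @param fallback Compartment for unannotated genes (default
#'   `"intracellular"`; must be a tree node, else the root is used).
#' @return Named list: gene id -> character vector of distinct tree terms.
#' @export
assignCompartments <- function(geneIds, ccMap = NULL,
                               tree = defaultCompartmentTree(),
                               ontology = NULL, fallback = "intracellular") {
  nodes <- treeNodes(tree)
  if (!fallback %in% nodes$term_id) fallback <- tree@root
  parentOf <- if (!is.null(ontology)) {
    setNames(ontology$parent, ontology$term_id)
  } else {
    character(0)
  }
  mapTerm <- function(term) {
    seen <- character(0)
    cur <- term
    while (!is.na(cur) && nzchar(cur)) {
      if (cur %in% nodes$term_id) return(cur)
      if (cur %in% seen) break
      seen <- c(seen, cur)
      cur <- if (cur %in% names(parentOf)) parentOf[[cur]] else NA_character_
    }
    message(sprintf("term '%s' has no ancestor in the compartment tree; using fallback",
                    term))
    fallback
  }
  out <- lapply(geneIds, function(g) {
    terms <- if (!is.null(ccMap)) ccMap$cc_term[ccMap$gene_id == g] else character(0)
    if (length(terms) == 0L) return(fallback)
    sort(unique(vapply(terms, mapTerm, character(1), USE.NAMES = FALSE)))
  })
  setNames(out, geneIds)
}

#' Build a compartment-annotated mixed graph for a gene list
#'
#' Creates one product instance per (gene, compartment) pair and
#' materializes an edge between every instance pair of the two genes of
#' each interaction record whose genes are both in the list. Genes without
#' any record become orphan instances. A gene is flagged
#' `has_regulatory_info` when it appears as the source of a directed
#' regulatory record in `records`.
#'
#' @param geneList Character vector of gene ids to display.
#' @param records Interaction data.frame (see [readInteractionTable()]);
#'   also serves as the regulatory-information compendium.
#' @param compartments Optional precomputed named list gene -> tree terms;
#'   when `NULL` it is derived via [assignCompartments()].
#' @param ccMap,ontology,fallback Passed to [assignCompartments()].
#' @param tree A [CompartmentTree-class].
#' @return A [MixedGraph-class] with instances positioned at their
#'   compartment anchors (run [layoutGraph()] to refine).
#' @export
buildMixedGraph <- function(geneList, records, compartments = NULL,
                            ccMap = NULL, tree = defaultCompartmentTree(),
                            ontology = NULL, fallback = "intracellular") {
  geneList <- unique(as.character(geneList))
  if (is.null(compartments)) {
    compartments <- assignCompartments(geneList, ccMap, tree, ontology, fallback)
  }
  zones <- computeZones(tree)
  regSources <- unique(records$source_id[records$directed &
                                         records$category %in% REGULATORY_CATEGORIES])
  inst <- do.call(rbind, c(lapply(geneList, function(g) {
    comps <- compartments[[g]]
    if (is.null(comps) || length(comps) == 0L) comps <- fallback
    data.frame(instance_id = paste(g, comps, sep = "@"), gene_id = g,
               compartment = comps, stringsAsFactors = FALSE)
  }), list(data.frame(instance_id = character(0), gene_id = character(0),
                      compartment = character(0), stringsAsFactors = FALSE))))
  zi <- match(inst$compartment, zones$term_id)
  inst$x <- zones$anchor_x[zi]
  inst$y <- zones$anchor_y[zi]
  inst$has_regulatory_info <- inst$gene_id %in% regSources
  rownames(inst) <- NULL
  keep <- records[records$source_id %in% geneList &
                  records$target_id %in% geneList, , drop = FALSE]
  keep <- unique(keep)
  edges <- do.call(rbind, c(lapply(seq_len(nrow(keep)), function(i) {
    r <- keep[i, ]
    fromI <- inst$instance_id[inst$gene_id == r$source_id]
    toI <- inst$instance_id[inst$gene_id == r$target_id]
    grid <- expand.grid(from = fromI, to = toI, stringsAsFactors = FALSE)
    cbind(grid, r[rep(1L, nrow(grid)), , drop = FALSE], row.names = NULL)
  }), list(emptyGraphEdges())))
  rownames(edges) <- NULL
  new("MixedGraph", instances = inst, edges = edges, zones = zones, tree = tree)
}

emptyGraphEdges <- function() {
  cbind(data.frame(from = character(0), to = character(0),
                   stringsAsFactors = FALSE),
        emptyInteractions())
}

## Nested rectangular zones: the root spans [0,100]^2; each node's children
## are tiled on a near-square grid strictly inside the parent (8% inset),
## so zone nesting mirrors tree parentage by construction.
computeZones <- function(tree) {
  nodes <- treeNodes(tree)
  zones <- data.frame(term_id = nodes$term_id, xmin = NA_real_, xmax = NA_real_,
                      ymin = NA_real_, ymax = NA_real_, stringsAsFactors = FALSE)
  setRect <- function(term, xmin, xmax, ymin, ymax) {
    i <- match(term, zones$term_id)
    zones$xmin[i] <<- xmin; zones$xmax[i] <<- xmax
    zones$ymin[i] <<- ymin; zones$ymax[i] <<- ymax
    kids <- nodes$term_id[!is.na(nodes$parent) & nodes$parent == term]
    if (length(kids) == 0L) return()
    padX <- 0.08 * (xmax - xmin)
    padY <- 0.08 * (ymax - ymin)
    ix0 <- xmin + padX; ix1 <- xmax - padX
    iy0 <- ymin + padY; iy1 <- ymax - padY
    ncol <- ceiling(sqrt(length(kids)))
    nrow <- ceiling(length(kids) / ncol)
    cw <- (ix1 - ix0) / ncol
    ch <- (iy1 - iy0) / nrow
    gap <- 0.06
    for (j in seq_along(kids)) {
      r <- (j - 1L) %/% ncol
      c <- (j - 1L) %% ncol
      setRect(kids[j],
              ix0 + c * cw + gap * cw, ix0 + (c + 1) * cw - gap * cw,
              iy0 + r * ch + gap * ch, iy0 + (r + 1) * ch - gap * ch)
    }
  }
  setRect(tree@root, 0, 100, 0, 100)
  zones$anchor_x <- (zones$xmin + zones$xmax) / 2
  zones$anchor_y <- (zones$ymin + zones$ymax) / 2
  zones
}

#' Compartment adjacency predicate
#'
#' Two compartments are adjacent when identical, in a parent/child
#' relation in the tree, or listed as an explicit extra pair. The default
#' extra pair is (extracellular region, plasma membrane).
#'
#' @param a,b Compartment term ids.
#' @param tree A [CompartmentTree-class].
#' @param extraPairs List of unordered character pairs.
#' @return Logical.
#' @export
compartmentsAdjacent <- function(a, b, tree,
                                 extraPairs = list(c("extracellular region",
                                                     "plasma membrane"))) {
  if (a == b) return(TRUE)
  nodes <- treeNodes(tree)
  pa <- nodes$parent[match(a, nodes$term_id)]
  pb <- nodes$parent[match(b, nodes$term_id)]
  if ((!is.na(pa) && pa == b) || (!is.na(pb) && pb == a)) return(TRUE)
  for (p in extraPairs) {
    if (setequal(c(a, b), p)) return(TRUE)
  }
  FALSE
}

#' Filter a mixed graph
#'
#' Three independent display filters: `hideIntercompartmental` removes
#' undirected physical edges whose endpoint compartments are not adjacent
#' (directed regulatory edges are never removed -- a nuclear factor
#' legitimately regulates a membrane gene's transcript); `hideOrphans`
#' removes degree-0 instances; `hideEmptyCompartments` drops zones holding
#' no instance. Each filter is idempotent.
#'
#' @param graph A [MixedGraph-class].
#' @param hideOrphans,hideEmptyCompartments,hideIntercompartmental Logical
#'   flags.
#' @param extraPairs Adjacency exceptions, see [compartmentsAdjacent()].
#' @return The filtered [MixedGraph-class].
#' @export
filterGraph <- function(graph, hideOrphans = FALSE,
                        hideEmptyCompartments = FALSE,
                        hideIntercompartmental = FALSE,
                        extraPairs = list(c("extracellular region",
                                            "plasma membrane"))) {
  inst <- graphInstances(graph)
  edges <- graphEdges(graph)
  zones <- graphZones(graph)
  if (hideIntercompartmental && nrow(edges) > 0L) {
    compOf <- setNames(inst$compartment, inst$instance_id)
    adj <- vapply(seq_len(nrow(edges)), function(i) {
      compartmentsAdjacent(compOf[[edges$from[i]]], compOf[[edges$to[i]]],
                           graph@tree, extraPairs)
    }, logical(1))
    edges <- edges[edges$directed | adj, , drop = FALSE]
  }
  if (hideOrphans) {
    used <- unique(c(edges$from, edges$to))
    inst <- inst[inst$instance_id %in% used, , drop = FALSE]
    edges <- edges[edges$from %in% inst$instance_id &
                   edges$to %in% inst$instance_id, , drop = FALSE]
  }
  if (hideEmptyCompartments) {
    zones <- zones[zones$term_id %in% inst$compartment |
                   zones$term_id == graph@tree@root, , drop = FALSE]
  }
  rownames(inst) <- NULL
  rownames(edges) <- NULL
  new("MixedGraph", instances = inst, edges = edges, zones = zones,
      tree = graph@tree)
}

#' Expand a graph with interactors from a compendium
#'
#' `all_interactors` adds every compendium partner of any selected gene;
#' `common_interactors` adds only genes interacting with every selected
#' gene (in either direction). New edges among all displayed genes are
#' materialized from the compendium together with the graph's existing
#' records. An empty selection returns the graph unchanged.
#'
#' @param graph A [MixedGraph-class].
#' @param selected Character vector of selected gene ids (subset of the
#'   graph's genes).
#' @param compendium Interaction data.frame to draw partners from.
#' @param mode `"all_interactors"` or `"common_interactors"`.
#' @param ccMap,ontology,fallback Compartment assignment for the newly
#'   added genes (existing genes keep their compartments).
#' @return The expanded [MixedGraph-class].
#' @export
expandNeighbors <- function(graph, selected, compendium,
                            mode = c("all_interactors", "common_interactors"),
                            ccMap = NULL, ontology = NULL,
                            fallback = "intracellular") {
  mode <- match.arg(mode)
  inst <- graphInstances(graph)
  genes <- unique(inst$gene_id)
  if (length(selected) == 0L) return(graph)
  stopifnot2(all(selected %in% genes), "selected genes must be in the graph")
  partnersOf <- function(g) {
    unique(c(compendium$target_id[compendium$source_id == g],
             compendium$source_id[compendium$target_id == g]))
  }
  perSel <- lapply(selected, partnersOf)
  add <- if (mode == "all_interactors") {
    Reduce(union, perSel, character(0))
  } else {
    Reduce(intersect, perSel)
  }
  add <- setdiff(add, genes)
  newGenes <- c(genes, add)
  oldComps <- lapply(split(inst$compartment, inst$gene_id), unique)
  newComps <- assignCompartments(add, ccMap, graph@tree, ontology, fallback)
  comps <- c(oldComps, newComps)[newGenes]
  oldRecs <- unique(graphEdges(graph)[names(emptyInteractions())])
  recs <- unique(rbind(oldRecs, compendium[names(emptyInteractions())]))
  buildMixedGraph(newGenes, recs, compartments = comps, tree = graph@tree)
}
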