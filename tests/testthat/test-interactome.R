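test_that("interaction tables type, default and validate records", {
  lines <- c("source\ttarget\tcategory\tsign\tprovenance",
             "Notch1\tHes1\ttf_target_curated\tactivation\tcurated-db",
             "Mir17\tMycn\tmirna_target\t\tprediction",
             "Lck\tZap70\tkinase_substrate\t\tkinase-db",
             "Cd3e\tCd3d\tppi\t\tppi-db")
  recs <- readInteractionTable(lines)
  expect_equal(nrow(recs), 4)
  n1 <- recs[recs$source_id == "Notch1", ]
  expect_true(n1$directed)
  expect_equal(n1$sign, "activation")
  mir <- recs[recs$source_id == "Mir17", ]
  expect_true(mir$directed)
  expect_equal(mir$sign, "repression")  # default for miRNA targeting
  ppi <- recs[recs$category == "ppi", ]
  expect_false(ppi$directed)
  expect_equal(ppi$sign, "none")
  expect_error(readInteractionTable(c("source\ttarget\tcategory",
                                      "a\tb\tfoo")), "line 2.*category 'foo'")
  expect_error(readInteractionTable(c("source\ttarget\tcategory\tsign",
                                      "a\tb\tppi\tactivation")),
               "line 2.*unsigned")
  expect_error(readInteractionTable(c("source\ttarget\tcategory",
                                      "a\tb\tppi\tx\ty\tz")), "line 2")
})

test_that("compartment assignment walks ancestry and falls back", {
  cc <- data.frame(gene_id = c("A", "A", "C"),
                   cc_term = c("nucleus", "cytosol", "nucleolus"))
  onto <- data.frame(term_id = "nucleolus", parent = "nucleus")
  comp <- assignCompartments(c("A", "B", "C"), cc, ontology = onto)
  expect_equal(comp$A, c("cytosol", "nucleus"))
  expect_equal(comp$B, "intracellular")  # unannotated gene
  expect_equal(comp$C, "nucleus")        # walked up to the tree subset
  expect_message(
    orphanTerm <- assignCompartments("D",
                                     data.frame(gene_id = "D",
                                                cc_term = "ribosome")),
    "fallback")
  expect_equal(orphanTerm$D, "intracellular")
})

test_that("graph construction fans out instances per compartment", {
  recs <- readInteractionTable(c("source\ttarget\tcategory",
                                 "A\tB\tppi"))
  cc1 <- data.frame(gene_id = c("A", "B"), cc_term = c("nucleus", "cytosol"))
  g <- buildMixedGraph(c("A", "B"), recs, ccMap = cc1)
  expect_equal(nrow(graphInstances(g)), 2)
  expect_equal(nrow(graphEdges(g)), 1)
  expect_false(graphEdges(g)$directed)
  cc2 <- rbind(cc1, data.frame(gene_id = "A", cc_term = "cytosol"))
  g2 <- buildMixedGraph(c("A", "B"), recs, ccMap = cc2)
  expect_equal(sum(graphInstances(g2)$gene_id == "A"), 2)
  expect_equal(nrow(graphEdges(g2)), 2)  # one edge per instance pair
  ## instance uniqueness invariant
  inst <- graphInstances(g2)
  expect_false(anyDuplicated(inst[c("gene_id", "compartment")]) > 0)
  g3 <- buildMixedGraph(c("A", "B"), recs[0, ], ccMap = cc1)
  expect_equal(nrow(graphEdges(g3)), 0)
  expect_equal(nrow(graphInstances(g3)), 2)
})

test_that("regulatory-information flags mark regulation sources", {
  recs <- readInteractionTable(c("source\ttarget\tcategory",
                                 "TF1\tX\ttf_target_chip",
                                 "X\tY\tppi"))
  g <- buildMixedGraph(c("TF1", "X", "Y"), recs)
  inst <- graphInstances(g)
  expect_true(all(inst$has_regulatory_info[inst$gene_id == "TF1"]))
  expect_false(any(inst$has_regulatory_info[inst$gene_id %in% c("X", "Y")]))
})

test_that("layout is deterministic, anchors singletons and respects zones", {
  recs <- readInteractionTable("source\ttarget\tcategory")
  g <- buildMixedGraph("solo", recs)
  gl <- layoutGraph(g, seed = 4)
  inst <- graphInstances(gl)
  z <- graphZones(gl)
  a <- z[z$term_id == inst$compartment, ]
  expect_equal(inst$x, a$anchor_x, tolerance = 1e-6)
  expect_equal(inst$y, a$anchor_y, tolerance = 1e-6)
  for (seed in 1:5) {
    it <- syntheticInteractionTable(30, seed = seed)
    cc <- data.frame(gene_id = paste0("gene", 1:30),
                     cc_term = rep(c("nucleus", "cytosol", "plasma membrane",
                                     "extracellular region",
                                     "mitochondrion"), 6))
    gg <- buildMixedGraph(paste0("gene", 1:30), it$records, ccMap = cc)
    l1 <- layoutGraph(gg, seed = seed)
    l2 <- layoutGraph(gg, seed = seed)
    expect_identical(graphInstances(l1), graphInstances(l2))
    ins <- graphInstances(l1)
    zz <- graphZones(l1)
    zi <- match(ins$compartment, zz$term_id)
    expect_true(all(ins$x >= zz$xmin[zi] & ins$x <= zz$xmax[zi] &
                    ins$y >= zz$ymin[zi] & ins$y <= zz$ymax[zi]))
  }
})

test_that("zones nest strictly inside their parents", {
  z <- graphZones(buildMixedGraph(character(0),
                                  readInteractionTable("source\ttarget\tcategory")))
  tree <- treeNodes(defaultCompartmentTree())
  for (i in seq_len(nrow(tree))) {
    p <- tree$parent[i]
    if (is.na(p)) next
    zi <- z[z$term_id == tree$term_id[i], ]
    zp <- z[z$term_id == p, ]
    expect_true(zi$xmin > zp$xmin && zi$xmax < zp$xmax &&
                zi$ymin > zp$ymin && zi$ymax < zp$ymax)
  }
})

test_that("filters follow their contracts and are idempotent", {
  recs <- readInteractionTable(c("source\ttarget\tcategory",
                                 "A\tB\tppi",
                                 "TF\tB\ttf_target_curated",
                                 "C\tD\tppi"))
  cc <- data.frame(gene_id = c("A", "B", "TF", "C", "D", "E"),
                   cc_term = c("nucleus", "extracellular region", "nucleus",
                               "cytosol", "cytosol", "nucleus"))
  g <- buildMixedGraph(c("A", "B", "TF", "C", "D", "E"), recs, ccMap = cc)
  ## intercompartmental: ppi nucleus<->extracellular removed, directed kept
  f1 <- filterGraph(g, hideIntercompartmental = TRUE)
  e1 <- graphEdges(f1)
  expect_false(any(e1$category == "ppi" & e1$source_id == "A"))
  expect_true(any(e1$category == "tf_target_curated"))  # directed exempt
  expect_true(any(e1$source_id == "C"))  # same-compartment ppi kept
  ## orphans: E has no edges
  f2 <- filterGraph(g, hideOrphans = TRUE)
  expect_false("E" %in% graphInstances(f2)$gene_id)
  ## empty compartments lose their zones
  f3 <- filterGraph(g, hideEmptyCompartments = TRUE)
  expect_false("mitochondrion" %in% graphZones(f3)$term_id)
  expect_true("nucleus" %in% graphZones(f3)$term_id)
  ## idempotence
  expect_equal(filterGraph(f1, hideIntercompartmental = TRUE)@edges, f1@edges)
  expect_equal(filterGraph(f2, hideOrphans = TRUE)@instances, f2@instances)
  expect_equal(filterGraph(f3, hideEmptyCompartments = TRUE)@zones, f3@zones)
})

test_that("adjacency joins parent/child and the membrane exception", {
  tree <- defaultCompartmentTree()
  expect_true(compartmentsAdjacent("nucleus", "nucleus", tree))
  expect_true(compartmentsAdjacent("nucleus", "intracellular", tree))
  expect_true(compartmentsAdjacent("extracellular region", "plasma membrane",
                                   tree))
  expect_false(compartmentsAdjacent("nucleus", "extracellular region", tree))
  expect_false(compartmentsAdjacent("nucleus", "cytosol", tree))
})

test_that("neighbor expansion adds all or common interactors", {
  comp <- readInteractionTable(c("source\ttarget\tcategory",
                                 "A\tB\tppi", "A\tD\tppi",
                                 "B\tC\tppi", "A\tC\tppi"))
  base <- readInteractionTable(c("source\ttarget\tcategory", "A\tB\tppi"))
  g <- buildMixedGraph(c("A", "B"), base)
  ex <- expandNeighbors(g, "A", comp, "all_interactors")
  expect_setequal(unique(graphInstances(ex)$gene_id), c("A", "B", "C", "D"))
  ## common interactors of A and B: C (interacts with both), not D
  ex2 <- expandNeighbors(g, c("A", "B"), comp, "common_interactors")
  got <- unique(graphInstances(ex2)$gene_id)
  expect_true("C" %in% got)
  expect_false("D" %in% got)
  ## monotonicity and no-partner stability
  expect_true(all(unique(graphInstances(g)$gene_id) %in%
                  unique(graphInstances(ex)$gene_id)))
  expect_true(all(got %in% unique(graphInstances(ex)$gene_id)))
  lonely <- buildMixedGraph("Z", base[0, ])
  expect_equal(graphInstances(expandNeighbors(lonely, "Z", comp,
                                              "all_interactors")),
               graphInstances(lonely))
  expect_identical(expandNeighbors(g, character(0), comp), g)
})

test_that("exports produce SIF relations and GraphML attribute round trips", {
  recs <- readInteractionTable(c("source\ttarget\tcategory\tsign",
                                 "Notch1\tHes1\ttf_target_curated\tactivation",
                                 "Mir17\tMycn\tmirna_target\t",
                                 "A\tB\tppi\t"))
  g <- layoutGraph(buildMixedGraph(c("Notch1", "Hes1", "Mir17", "Mycn",
                                     "A", "B"), recs), seed = 1)
  sif <- exportGraph(g, "sif")
  expect_true("Notch1 activates Hes1" %in% sif)
  expect_true("Mir17 targets Mycn" %in% sif)
  expect_true("A binds B" %in% sif)
  empty <- buildMixedGraph(character(0),
                           readInteractionTable("source\ttarget\tcategory"))
  expect_length(exportGraph(empty, "sif"), 0)
  expect_match(exportGraph(empty, "graphml")[2], "graphml")
  f <- withr::local_tempfile(fileext = ".graphml")
  exportGraph(g, "graphml", f)
  ig <- readGraphml(f)
  expect_equal(igraph::vcount(ig), nrow(graphInstances(g)))
  expect_equal(igraph::ecount(ig), nrow(graphEdges(g)))
  va <- igraph::vertex_attr(ig)
  expect_setequal(va$gene_id, graphInstances(g)$gene_id)
  expect_setequal(va$compartment, graphInstances(g)$compartment)
  expect_equal(sort(va$x), sort(graphInstances(g)$x), tolerance = 1e-9)
  ea <- igraph::edge_attr(ig)
  expect_setequal(ea$category, graphEdges(g)$category)
  expect_setequal(ea$sign, graphEdges(g)$sign)
  expect_true(all(c("color", "arrowhead") %in% names(ea)))
  expect_error(exportGraph(g, "dot"), "arg")
  ## tsv edge list carries a header plus one line per edge
  tsv <- exportGraph(g, "tsv")
  expect_length(tsv, nrow(graphEdges(g)) + 1)
})

test_that("compartment trees load from parent-child TSV and OBO subsets", {
  f <- withr::local_tempfile(lines = c("term_id\tparent\tlabel",
                                       "cell\t\tcell",
                                       "inner\tcell\tinner zone",
                                       "nucleus\tinner\tnucleus"))
  tr <- readCompartmentTree(f)
  expect_equal(tr@root, "cell")
  expect_equal(treeNodes(tr)$depth, c(0, 1, 2))
  obo <- withr::local_tempfile(lines = c(
    "format-version: 1.2", "", "[Term]", "id: GO:0005575",
    "name: cellular_component", "", "[Term]", "id: GO:0005634",
    "name: nucleus", "is_a: GO:0005575 ! cellular_component"))
  tr2 <- readCompartmentTree(obo)
  expect_equal(tr2@root, "GO:0005575")
  expect_equal(nrow(treeNodes(tr2)), 2)
  bad <- withr::local_tempfile(lines = c("term_id\tparent", "a\tb", "b\ta"))
  expect_error(readCompartmentTree(bad), "root")
})
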