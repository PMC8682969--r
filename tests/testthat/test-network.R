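# Disease-network construction and topology metrics.

test_that("gene intersection is exact and rejects degenerate inputs", {
  expect_identical(intersect_genes(c("A", "B", "C"), c("B", "C", "D")),
                   c("B", "C"))
  expect_identical(intersect_genes(c("b", "a"), c("a", "b", "c")),
                   c("a", "b"))
  expect_error(intersect_genes(c("A"), c("B")), "overlap")
  expect_error(intersect_genes(character(0), c("A")), "non-empty")
  # case sensitivity: Tgfb1 != TGFB1
  expect_error(intersect_genes("Tgfb1", "TGFB1"), "overlap")
})

test_that("build_network keeps connected genes and reports isolated ones", {
  genes <- sprintf("g%02d", 1:10)
  edges <- data.frame(node_a = genes[c(1, 2, 3, 4, 5, 6, 7)],
                      node_b = genes[c(2, 3, 4, 5, 6, 7, 8)],
                      score = 900)
  net <- build_network(genes, edges)
  expect_length(net$nodes, 8L)
  expect_identical(net$dropped_isolated, c("g09", "g10"))
  expect_setequal(c(net$nodes, net$dropped_isolated), genes)

  # edges pointing outside the intersection are ignored
  edges2 <- rbind(edges, data.frame(node_a = "g01", node_b = "elsewhere",
                                    score = 999))
  net2 <- build_network(genes, edges2)
  expect_equal(nrow(net2$edges), nrow(edges))

  expect_warning(net3 <- build_network(genes, edges[0, ]), "empty")
  expect_length(net3$nodes, 0L)
  expect_length(net3$dropped_isolated, 10L)
})

test_that("topology matches closed-form values on canonical graphs", {
  # path A-B-C: B sits on the single shortest path
  path <- build_network(c("A", "B", "C"),
                        data.frame(node_a = c("A", "B"),
                                   node_b = c("B", "C"), score = 900))
  tp <- network_topology(path)
  expect_equal(tp$degree[tp$gene_id == "B"], 2L)
  expect_equal(tp$betweenness[tp$gene_id == "B"], 1.0)
  expect_equal(tp$betweenness[tp$gene_id == "A"], 0)

  # complete graph K4: every pair adjacent, all betweenness 0
  k4 <- utils::combn(LETTERS[1:4], 2)
  net4 <- build_network(LETTERS[1:4],
                        data.frame(node_a = k4[1, ], node_b = k4[2, ],
                                   score = 900))
  expect_true(all(network_topology(net4)$betweenness == 0))
  expect_true(all(network_topology(net4)$degree == 3L))

  # star with 5 leaves: center carries every leaf pair
  star <- build_network(c("hub", paste0("l", 1:5)),
                        data.frame(node_a = "hub", node_b = paste0("l", 1:5),
                                   score = 900))
  ts <- network_topology(star)
  expect_equal(ts$degree[ts$gene_id == "hub"], 5L)
  expect_equal(ts$betweenness[ts$gene_id == "hub"], 1.0)
})

test_that("degree sum equals twice the edge count; order does not matter", {
  set.seed(33)
  for (i in 1:5) {
    e <- random_edges(9, p = 0.4)
    nodes <- sort(unique(c(e$node_a, e$node_b)))
    net <- build_network(nodes, e)
    tp <- network_topology(net)
    expect_equal(sum(tp$degree), 2L * nrow(net$edges))
    # permute node and edge input order
    perm <- e[sample(nrow(e)), c("node_b", "node_a", "score")]
    names(perm) <- c("node_a", "node_b", "score")
    net_p <- build_network(sample(nodes), perm)
    expect_equal(network_topology(net_p), tp)
  }
})

test_that("betweenness agrees exactly with brute-force path enumeration", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    e <- random_edges(n, p = 0.35)
    nodes <- sort(unique(c(e$node_a, e$node_b)))
    net <- build_network(nodes, e)
    tp <- network_topology(net)
    oracle <- brute_force_betweenness(nodes, e)
    expect_equal(setNames(tp$betweenness, tp$gene_id), oracle[tp$gene_id],
                 tolerance = 1e-12)
  }
})

test_that("networks export to GraphML and TSV", {
  st <- small_study(seed = 55L)
  inter <- intersect_genes(st$disease_genes, st$gene_ids)
  net <- build_network(inter, st$ppi_edges)
  dir <- withr::local_tempdir()
  export_network(net,
                 graphml_path = file.path(dir, "net.graphml"),
                 edges_path = file.path(dir, "edges.tsv"),
                 topology_path = file.path(dir, "topo.tsv"))
  expect_true(file.exists(file.path(dir, "net.graphml")))
  g2 <- igraph::read_graph(file.path(dir, "net.graphml"), format = "graphml")
  expect_equal(igraph::gorder(g2), length(net$nodes))
  expect_equal(igraph::gsize(g2), nrow(net$edges))
})
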