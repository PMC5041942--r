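# Maximal bicliques and k-clique percolation against brute-force
# enumeration.

test_that("maximal bicliques match hand-worked examples", {
  # complete bipartite 2x3: one module, the whole graph
  cb <- expand.grid(mirna_id = c("mA", "mB"),
                    pathway_id = c("p1", "p2", "p3"),
                    stringsAsFactors = FALSE)
  mods <- maximalBicliques(cb)
  expect_length(mods, 1L)
  expect_equal(mods[[1]]$mirnas, c("mA", "mB"))
  expect_equal(mods[[1]]$pathways, c("p1", "p2", "p3"))

  # the classic asymmetric case
  e <- data.frame(mirna_id = c("a", "b", "b"),
                  pathway_id = c("p1", "p1", "p2"))
  mods <- maximalBicliques(e)
  expect_length(mods, 2L)
  keys <- vapply(mods, function(m)
    paste(c(m$mirnas, "|", m$pathways), collapse = " "), character(1))
  expect_setequal(keys, c("a b | p1", "b | p1 p2"))
  expect_equal(vapply(mods, `[[`, character(1), "id"),
               c("BM001", "BM002"))

  expect_length(maximalBicliques(e[0, ]), 0L)
  expect_error(maximalBicliques(
    data.frame(mirna_id = c("a", "p1"), pathway_id = c("p1", "a"))),
    "bipartite")

  # size floors
  expect_length(maximalBicliques(e, minMirnas = 2), 1L)
})

test_that("maximal bicliques equal brute force on random graphs", {
  set.seed(61)
  for (i in 1:60) {
    nm <- sample(2:6, 1)
    np <- sample(2:6, 1)
    e <- randomBipartite(nm, np, runif(1, 0.2, 0.7))
    if (!nrow(e)) next
    got <- maximalBicliques(e)
    ref <- bicliqueOracle(e)
    expect_equal(lapply(got, function(m) m[c("mirnas", "pathways")]),
                 ref)
  }
})

test_that("clique percolation matches hand-worked examples", {
  tri2edge <- data.frame(a = c("A", "A", "B", "B", "C"),
                         b = c("B", "C", "C", "D", "D"))
  # two triangles ABC, BCD share edge BC: one community of 4
  comms <- cliquePercolation(tri2edge, k = 3)
  expect_length(comms, 1L)
  expect_equal(comms[[1]], c("A", "B", "C", "D"))

  # two triangles sharing only node C: two communities
  tri1node <- data.frame(a = c("A", "A", "B", "C", "C", "D"),
                         b = c("B", "C", "C", "D", "E", "E"))
  expect_length(cliquePercolation(tri1node, k = 3), 2L)

  # triangle-free graph: nothing percolates
  path <- data.frame(a = c("A", "B", "C"), b = c("B", "C", "D"))
  expect_length(cliquePercolation(path, k = 3), 0L)
  expect_error(cliquePercolation(path, k = 2), ">= 3")
})

test_that("clique percolation equals brute force for k in 3:4", {
  set.seed(71)
  for (i in 1:60) {
    g <- randomGraph(sample(5:12, 1), runif(1, 0.25, 0.6))
    if (!nrow(g$edges)) next
    gr <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                        vertices = g$vertices)
    for (k in 3:4) {
      expect_equal(cliquePercolation(gr, k = k),
                   percolationOracle(g$edges, g$vertices, k))
    }
  }
})

test_that("module enumeration is invariant under relabeling", {
  set.seed(81)
  e <- randomBipartite(5, 5, 0.4)
  got <- maximalBicliques(e)
  # relabel miRNAs in reverse order
  map <- setNames(sprintf("z%02d", 5:1), sprintf("m%02d", 1:5))
  e2 <- data.frame(mirna_id = map[e$mirna_id], pathway_id = e$pathway_id)
  got2 <- maximalBicliques(e2)
  norm <- function(mods, f = identity)
    sort(vapply(mods, function(m)
      paste(c(sort(f(m$mirnas)), "|", m$pathways), collapse = " "),
      character(1)))
  expect_equal(norm(got, function(x) unname(map[x])), norm(got2))
})

test_that("core-module extraction returns community plus neighbors", {
  edges <- data.frame(
    pathway_i = c("A", "A", "B", "B", "C", "D", "E"),
    pathway_j = c("B", "C", "C", "D", "D", "E", "F"),
    weight = 1, n_edges = 1, perm_p = 0.01, stringsAsFactors = FALSE)
  nodes <- data.frame(pathway_id = LETTERS[1:7], grade = "III",
                      direction = "up", stringsAsFactors = FALSE)
  net <- new("CrosstalkNetwork", pairs = edges, edges = edges,
             nodes = nodes, nPermutations = 10L)
  core <- extractCoreModule(net, "A")
  expect_equal(core$core, c("A", "B", "C", "D"))
  expect_equal(core$neighbors, "E")
  expect_equal(core$nodes, c("A", "B", "C", "D", "E"))
  # the induced edge table stays within the module
  expect_true(all(core$edges$pathway_i %in% core$nodes))

  # isolated anchor: degenerate module of itself (plus no neighbors)
  iso <- extractCoreModule(net, "G")
  expect_equal(iso$core, "G")
  expect_equal(iso$nodes, "G")
  expect_error(extractCoreModule(net, "Z"), "anchor")
})
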