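# Fisher's-method interaction strength, pathway-pair weight, permutation
# null and the crosstalk network.

test_that("interaction strength follows the closed form", {
  expect_equal(edgeStrength(1, 1, 1), 0)
  expect_equal(edgeStrength(exp(-1), exp(-1), exp(-1)), 6)
  expect_equal(edgeStrength(0.05, 0.05, 0.05), -6 * log(0.05),
               tolerance = 1e-12)
  expect_error(edgeStrength(0, 0.5, 0.5), "\\(0, 1\\]")
  expect_error(edgeStrength(0.5, 1.2, 0.5), "\\(0, 1\\]")
  # monotone: any smaller p gives a strictly larger strength
  w0 <- edgeStrength(0.2, 0.3, 0.4)
  expect_gt(edgeStrength(0.1, 0.3, 0.4), w0)
  expect_gt(edgeStrength(0.2, 0.3, 0.2), w0)
  # clip floor keeps the strength finite
  expect_true(is.finite(edgeStrength(1e-320, 1e-320, 1e-320)))
})

makeToyCrosstalk <- function(seed, nGenes = 20, nSamples = 12,
                             pEdge = 0.3) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(nGenes))
  expr <- matrix(rnorm(nGenes * nSamples), nGenes,
                 dimnames = list(genes, sprintf("S%02d",
                                                seq_len(nSamples))))
  pr <- t(combn(genes, 2))
  keep <- runif(nrow(pr)) < pEdge
  ppi <- PPINetwork(data.frame(gene_a = pr[keep, 1],
                               gene_b = pr[keep, 2]))
  diffP <- setNames(runif(nGenes, 1e-6, 1), genes)
  list(genes = genes, expr = expr, ppi = ppi, diffP = diffP,
       em = ExpressionMatrix(expr, "gene"))
}

test_that("pair weight equals the exhaustive double-loop oracle", {
  for (seed in 1:12) {
    toy <- makeToyCrosstalk(seed)
    gi <- sample(toy$genes, sample(4:8, 1))
    gj <- sample(toy$genes, sample(4:8, 1))
    diffG <- sample(toy$genes, 14)
    got <- pairWeight(gi, gj, diffG, toy$ppi, toy$em, toy$diffP)
    ref <- pairWeightOracle(gi, gj, diffG, ppiEdges(toy$ppi), toy$expr,
                            toy$diffP)
    expect_equal(got$weight, ref$weight, tolerance = 1e-10)
    expect_equal(got$n_edges, ref$n_edges)
  }
  # no qualifying edges
  toy <- makeToyCrosstalk(99, pEdge = 0)
  none <- pairWeight(toy$genes[1:4], toy$genes[5:8], toy$genes,
                     toy$ppi, toy$em, toy$diffP)
  expect_equal(none$weight, 0)
  expect_equal(none$n_edges, 0L)
})

test_that("pair weight is additive and counts shared edges once", {
  toy <- makeToyCrosstalk(7, pEdge = 0.5)
  gi <- toy$genes[1:6]
  gj <- toy$genes[7:12]
  whole <- pairWeight(gi, gj, toy$genes, toy$ppi, toy$em, toy$diffP)
  # split pathway j in two disjoint halves: weights add up
  p1 <- pairWeight(gi, gj[1:3], toy$genes, toy$ppi, toy$em, toy$diffP)
  p2 <- pairWeight(gi, gj[4:6], toy$genes, toy$ppi, toy$em, toy$diffP)
  expect_equal(whole$weight, p1$weight + p2$weight, tolerance = 1e-10)
  # both genes in both pathways: each unordered PPI edge counted once
  both <- pairWeight(toy$genes[1:5], toy$genes[1:5], toy$genes, toy$ppi,
                     toy$em, toy$diffP)
  e <- ppiEdges(toy$ppi)
  inSet <- e$gene_a %in% toy$genes[1:5] & e$gene_b %in% toy$genes[1:5]
  expect_equal(both$n_edges, sum(inSet))
})

test_that("permutation p-value honours the pseudo-count and determinism", {
  toy <- makeToyCrosstalk(3, pEdge = 0.4)
  pool <- toy$genes
  # observed weight of zero can never beat the null
  expect_equal(permutationP(0, c(4, 4), pool, toy$ppi, toy$em, toy$diffP,
                            B = 50, seed = 1), 1)
  # an unbeatable observed weight attains the pseudo-count floor
  expect_equal(permutationP(1e9, c(4, 4), pool, toy$ppi, toy$em,
                            toy$diffP, B = 99, seed = 1) * 100, 1,
               tolerance = 1e-12)
  p1 <- permutationP(5, c(4, 4), pool, toy$ppi, toy$em, toy$diffP,
                     B = 200, seed = 42)
  p2 <- permutationP(5, c(4, 4), pool, toy$ppi, toy$em, toy$diffP,
                     B = 200, seed = 42)
  expect_identical(p1, p2)
  expect_error(permutationP(5, c(30, 4), pool, toy$ppi, toy$em,
                            toy$diffP, B = 10), "pool smaller")
})

test_that("crosstalk network recovers planted pairs and is seed-stable", {
  d <- simulateCrosstalkData(smallConfig(seed = 29))
  diffG <- rbind(callDifferential(d$geneExpr, d$annotation, "III_vs_II"),
                 callDifferential(d$geneExpr, d$annotation, "IV_vs_II"))
  ct <- buildCrosstalkNetwork(d$geneSets, d$ppi, d$geneExpr, diffG,
                              B = 200, seed = 11)
  sp <- scoredPairs(ct)
  expect_equal(nrow(sp), choose(8, 2))
  key <- paste(sp$pathway_i, sp$pathway_j)
  want <- paste(d$truth$crosstalkPairs$pathway_i,
                d$truth$crosstalkPairs$pathway_j)
  expect_gte(mean(sp$perm_p[key %in% want] < 0.05), 2 / 3)
  expect_lte(mean(sp$perm_p[!key %in% want] < 0.05), 0.2)
  # zero-edge pairs get permutation p exactly 1
  expect_true(all(sp$perm_p[sp$n_edges == 0] == 1))

  ct2 <- buildCrosstalkNetwork(d$geneSets, d$ppi, d$geneExpr, diffG,
                               B = 200, seed = 11)
  expect_identical(scoredPairs(ct), scoredPairs(ct2))

  # threshold 1 keeps every pair whose permutation p is below 1
  ct3 <- buildCrosstalkNetwork(d$geneSets, d$ppi, d$geneExpr, diffG,
                               B = 50, seed = 2, threshold = 1)
  expect_equal(nrow(networkEdges(ct3)),
               sum(scoredPairs(ct3)$perm_p < 1))
  expect_true(all(networkEdges(ct3)$n_edges >= 1))
})
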