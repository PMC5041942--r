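# Signature-pair selection, hypergeometric enrichment, miRNA-pathway
# network and hub calling.

test_that("correlation matches cor.test and handles edge cases", {
  set.seed(5)
  for (i in 1:15) {
    x <- rnorm(sample(5:40, 1))
    y <- rnorm(length(x))
    ref <- cor.test(x, y)
    got <- correlatePearson(x, y)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  x <- rnorm(10)
  anti <- correlatePearson(x, -x)
  expect_equal(anti$r, -1)
  expect_lt(anti$p, 1e-6)
  expect_equal(correlatePearson(x, x)$r, 1)
  expect_warning(flat <- correlatePearson(x, rep(1, 10)), "constant")
  expect_equal(flat, list(r = 0, p = 1))
  expect_error(correlatePearson(1:3, 1:4), "unequal")
})

test_that("correlation p-values are uniform under independence", {
  set.seed(99)
  n <- 100
  reps <- 500
  x <- matrix(rnorm(reps * n), reps)
  y <- matrix(rnorm(reps * n), reps)
  r <- mirXtalk:::rowCor(x, y)
  p <- mirXtalk:::corPValue(r, n)
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  u <- sprintf("g%02d", 1:10)
  full <- hypergeomEnrich(u[1:5], u[1:5], u)
  expect_equal(full$p_value, 1 / 252, tolerance = 1e-12)
  expect_equal(full[c("N", "M", "n", "m")],
               list(N = 10L, M = 5L, n = 5L, m = 5L))
  # N = 4, M = 2, n = 2, m = 1: enumeration over the C(4,2) = 6 draws
  overlap <- hypergeomEnrich(u[1:2], u[2:3], u[1:4])
  expect_equal(overlap$m, 1L)
  expect_equal(overlap$p_value, 5 / 6, tolerance = 1e-12)
  expect_equal(hypergeomEnrich(character(0), u[1:5], u)$p_value, 1)
  expect_error(hypergeomEnrich(u[1:2], u[1:3], character(0)), "universe")

  # oracle equivalence on a compact grid; the acceptance suite extends
  # this to every configuration with N <= 12
  for (N in c(4L, 6L, 9L)) {
    uu <- sprintf("x%02d", seq_len(N))
    for (M in 0:N) for (n in 0:N) {
      targets <- if (n) sample(uu, n) else character(0)
      res <- hypergeomEnrich(targets, uu[seq_len(M)], uu)
      expect_equal(res$p_value,
                   hyperTailOracle(N, M, n, res$m), tolerance = 1e-12)
      expect_equal(hypergeomEnrich(targets, uu[seq_len(M)], uu,
                                   tail = "gt")$p_value,
                   hyperTailOracle(N, M, n, res$m, tail = "gt"),
                   tolerance = 1e-12)
    }
  }
})

test_that("signature filter applies the -0.4 cutoff with p < 0.05 exactly", {
  n <- 60
  v39 <- vectorsWithCor(n, -0.39, seed = 1)
  v41 <- vectorsWithCor(n, -0.41, seed = 2)
  M <- rbind(m1 = v39$x, m2 = v41$x)
  G <- rbind(g1 = v39$y, g2 = v41$y)
  colnames(M) <- colnames(G) <- sprintf("S%02d", 1:n)
  ann <- data.frame(sample_id = colnames(M),
                    grade = rep(c("II", "III"), each = n / 2))
  mkDiff <- function(ids, kind, direction)
    data.frame(feature_id = ids, kind = kind, contrast = "III_vs_II",
               t = 5, p = 1e-4, fdr = 1e-3, direction = direction,
               significant = TRUE, stringsAsFactors = FALSE)
  pairs <- selectSignaturePairs(
    mkDiff(c("m1", "m2"), "miRNA", "up"),
    mkDiff(c("g1", "g2"), "gene", "down"),
    data.frame(mirna_id = c("m1", "m2"), gene_id = c("g1", "g2")),
    ExpressionMatrix(M, "miRNA"), ExpressionMatrix(G, "gene"), ann)
  expect_equal(pairs$mirna_id, "m2")   # r = -0.41 in, r = -0.39 out
  expect_equal(pairs$r, -0.41, tolerance = 1e-10)
  expect_equal(pairs$direction_pattern, "miR_up_gene_down")

  # same-direction pairs are excluded even when anticorrelated
  none <- selectSignaturePairs(
    mkDiff(c("m1", "m2"), "miRNA", "up"),
    mkDiff(c("g1", "g2"), "gene", "up"),
    data.frame(mirna_id = c("m1", "m2"), gene_id = c("g1", "g2")),
    ExpressionMatrix(M, "miRNA"), ExpressionMatrix(G, "gene"), ann)
  expect_equal(nrow(none), 0L)
})

test_that("signature selection is invariant to sample-column permutation", {
  d <- simulateCrosstalkData(smallConfig(seed = 17))
  diffM <- callDifferential(d$mirnaExpr, d$annotation, "IV_vs_II")
  diffG <- callDifferential(d$geneExpr, d$annotation, "IV_vs_II")
  base <- selectSignaturePairs(diffM, diffG, d$targetPairs, d$mirnaExpr,
                               d$geneExpr, d$annotation)
  set.seed(1)
  perm <- sample(sampleIds(d$mirnaExpr))
  mShuf <- ExpressionMatrix(exprValues(d$mirnaExpr)[, perm], "miRNA")
  gShuf <- ExpressionMatrix(exprValues(d$geneExpr)[, perm], "gene")
  shuf <- selectSignaturePairs(diffM, diffG, d$targetPairs, mShuf, gShuf,
                               d$annotation)
  o <- function(x) x[order(x$mirna_id, x$gene_id), ]
  expect_equal(o(base)$r, o(shuf)$r, tolerance = 1e-12)
  expect_equal(o(base)$gene_id, o(shuf)$gene_id)

  expect_equal(nrow(selectSignaturePairs(diffM[0, ], diffG, d$targetPairs,
                                         d$mirnaExpr, d$geneExpr,
                                         d$annotation)), 0L)
})

test_that("miRNA-pathway network keeps enriched edges and planted structure", {
  # one miRNA whose targets fill a small pathway in a small universe
  uni <- sprintf("g%02d", 1:12)
  pairs <- data.frame(mirna_id = "m1", gene_id = uni[1:3],
                      contrast = "III_vs_II",
                      direction_pattern = "miR_up_gene_down",
                      r = -0.9, r_p = 1e-5, stringsAsFactors = FALSE)
  gs <- GeneSetCollection(list(P1 = uni[1:3], P2 = uni[4:12]))
  net <- buildMirnaPathwayNetwork(pairs, gs, uni)
  e <- networkEdges(net)
  expect_equal(e$pathway_id, "P1")
  expect_equal(e$p, hyperTailOracle(12, 3, 3, 3), tolerance = 1e-12)
  nodes <- networkNodes(net)
  expect_equal(nodes$grade[nodes$node_id == "P1"], "III")
  expect_equal(nodes$direction[nodes$node_id == "P1"], "down")
  expect_equal(nodes$direction[nodes$node_id == "m1"], "up")

  # threshold 0 empties the network; no pairs is an error
  expect_equal(nrow(networkEdges(
    buildMirnaPathwayNetwork(pairs, gs, uni, threshold = 0))), 0L)
  expect_error(buildMirnaPathwayNetwork(pairs[0, ], gs, uni),
               "no signature pairs")

  # planted enrichment is recovered on generated data
  d <- simulateCrosstalkData(smallConfig(
    seed = 23, nSamplesPerGrade = c(30L, 30L, 30L)))
  diffM <- rbind(callDifferential(d$mirnaExpr, d$annotation, "III_vs_II"),
                 callDifferential(d$mirnaExpr, d$annotation, "IV_vs_II"))
  diffG <- rbind(callDifferential(d$geneExpr, d$annotation, "III_vs_II"),
                 callDifferential(d$geneExpr, d$annotation, "IV_vs_II"))
  sig <- selectSignaturePairs(diffM, diffG, d$targetPairs, d$mirnaExpr,
                              d$geneExpr, d$annotation)
  uni2 <- intersect(featureIds(d$geneExpr),
                    unique(unlist(geneSets(d$geneSets))))
  net2 <- buildMirnaPathwayNetwork(sig, d$geneSets, uni2)
  got <- paste(networkEdges(net2)$mirna_id, networkEdges(net2)$pathway_id)
  want <- paste(d$truth$mirnaPathway$mirna_id,
                d$truth$mirnaPathway$pathway_id)
  expect_gte(mean(want %in% got), 0.9)
})

test_that("hub rule returns the inclusive top fraction by degree", {
  mkNet <- function(degrees) {
    edges <- do.call(rbind, lapply(seq_along(degrees), function(i)
      data.frame(mirna_id = sprintf("m%02d", i),
                 pathway_id = sprintf("p%03d", seq_len(degrees[i])),
                 contrast = "III_vs_II", p = 0.01,
                 stringsAsFactors = FALSE)))
    new("MirnaPathwayNetwork", edges = edges,
        mirnaDirection = setNames(rep("up", length(degrees)),
                                  sprintf("m%02d", seq_along(degrees))),
        pathwayGrade = character(0), pathwayDirection = character(0))
  }
  # 20 miRNAs with distinct degrees: ceiling(0.15 * 20) = 3 hubs
  expect_equal(findHubs(mkNet(1:20)), c("m20", "m19", "m18"))
  # all tied: the tie rule includes everyone
  expect_equal(length(findHubs(mkNet(rep(4, 10)))), 10L)
  # 60 untied miRNAs: 9 hubs
  expect_equal(length(findHubs(mkNet(sample(60)))), 9L)
  # ties at the boundary are included
  expect_equal(length(findHubs(mkNet(c(10, 9, 9, 9, rep(1, 16))))), 4L)
})
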