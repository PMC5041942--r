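# Survival stratification: clustering, Kaplan-Meier, log-rank, heatmap
# ordering.

test_that("two-group clustering finds obvious structure deterministically", {
  m <- matrix(c(0, 0, 10, 10), ncol = 1,
              dimnames = list(sprintf("S%d", 1:4), "f1"))
  cl <- twoGroupCluster(m, seed = 1)
  expect_equal(cl[["S1"]], cl[["S2"]])
  expect_equal(cl[["S3"]], cl[["S4"]])
  expect_false(cl[["S1"]] == cl[["S3"]])

  set.seed(2)
  clouds <- rbind(matrix(rnorm(40, -5), 8), matrix(rnorm(40, 5), 8))
  rownames(clouds) <- sprintf("S%02d", 1:16)
  cl2 <- twoGroupCluster(clouds, seed = 3)
  expect_equal(length(unique(cl2[1:8])), 1L)
  expect_equal(length(unique(cl2[9:16])), 1L)
  expect_identical(cl2, twoGroupCluster(clouds, seed = 3))

  flat <- matrix(1, 4, 3, dimnames = list(sprintf("S%d", 1:4), NULL))
  expect_error(twoGroupCluster(flat), "degenerate")
})

test_that("Kaplan-Meier estimator matches hand constructions", {
  one <- kmFit(3, 1)
  expect_equal(one$event_times, 3)
  expect_equal(one$survival, 0)
  expect_equal(one$median, 3)

  ten <- kmFit(1:10, rep(1, 10))
  expect_equal(ten$survival, seq(0.9, 0, by = -0.1))
  expect_equal(ten$survival[ten$event_times == 5], 0.5)
  expect_equal(ten$median, 5)
  # no censoring: the estimator is the empirical survival function
  set.seed(4)
  tt <- round(rexp(30, 0.1), 2)
  km <- kmFit(tt, rep(1, 30))
  expect_equal(km$survival,
               vapply(km$event_times, function(t) mean(tt > t),
                      numeric(1)))

  cens <- kmFit(c(2, 4, 6), c(0, 0, 0))
  expect_length(cens$event_times, 0L)
  expect_true(is.na(cens$median))
  expect_error(kmFit(numeric(0), numeric(0)), "empty")
})

test_that("log-rank test behaves at the boundaries and detects separation", {
  same <- logrankTest(1:10, rep(1, 10), 1:10, rep(1, 10))
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  set.seed(8)
  a <- rexp(100, 1)
  b <- rexp(100, 3)
  sep <- logrankTest(a, rep(1, 100), b, rep(1, 100))
  expect_lt(sep$p, 0.01)
  flipped <- logrankTest(b, rep(1, 100), a, rep(1, 100))
  expect_equal(sep$chisq, flipped$chisq, tolerance = 1e-12)

  expect_warning(none <- logrankTest(1:4, rep(0, 4), 2:5, rep(0, 4)),
                 "no events")
  expect_equal(none$p, 1)
})

test_that("stratification chain recovers planted risk groups", {
  d <- simulateCrosstalkData(smallConfig(seed = 37))
  st <- stratifyAndTest(d$mirnaExpr, d$geneExpr, d$annotation,
                        signatureGenes = d$truth$diffGenes$gene_id,
                        signatureMirnas = d$truth$diffMirnas$mirna_id,
                        seed = 37)
  expect_lt(st$p, 0.05)
  # the short-labeled group has the smaller KM median
  ms <- st$curves$short$median
  ml <- st$curves$long$median
  expect_true(is.na(ml) || ms <= ml)
  # groups align with the planted risk labels
  truthGrp <- d$truth$riskGroups$risk_group[
    match(st$table$sample_id, d$truth$riskGroups$sample_id)]
  agree <- mean((st$table$group == "short") == (truthGrp == 1))
  expect_gte(max(agree, 1 - agree), 0.9)

  # single-layer modes run on the same inputs
  for (mode in c("gene", "mirna")) {
    stm <- stratifyAndTest(d$mirnaExpr, d$geneExpr, d$annotation,
                           signatureGenes = d$truth$diffGenes$gene_id,
                           signatureMirnas = d$truth$diffMirnas$mirna_id,
                           mode = mode, seed = 37)
    expect_true(all(stm$table$group %in% c("short", "long")))
  }
  expect_error(stratifyAndTest(d$mirnaExpr, d$geneExpr, d$annotation,
                               character(0), character(0)),
               "empty signature")
})

test_that("heatmap ordering keeps grades contiguous and pairs adjacent", {
  vals <- cbind(S1 = c(0, 0), S2 = c(10, 10), S3 = c(0.2, 0.1),
                S4 = c(10.1, 9.9), S5 = c(5, 5), S6 = c(5.1, 5.2))
  rownames(vals) <- c("f1", "f2")
  ann <- data.frame(sample_id = colnames(vals),
                    grade = c(rep("II", 4), "III", "III"))
  em <- ExpressionMatrix(vals, "gene")
  ord <- heatmapOrder(em, ann)
  expect_setequal(ord$sampleOrder[1:4], c("S1", "S2", "S3", "S4"))
  expect_equal(ord$sampleOrder[5:6], c("S5", "S6"))
  # obvious pairs sit next to each other within the grade block
  pos <- match(c("S1", "S3", "S2", "S4"), ord$sampleOrder)
  expect_equal(abs(pos[1] - pos[2]), 1L)
  expect_equal(abs(pos[3] - pos[4]), 1L)
  expect_setequal(ord$featureOrder, c("f1", "f2"))
})
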