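# Pathway-pathway crosstalk: Fisher's-method interaction strength over PPI
# edges linking differential genes of two pathways, with a permutation
# null that resamples same-size gene sets from the differential gene pool.

#' Fisher's-method interaction strength of a PPI edge
#'
#' Combines the two genes' differential p-values and their expression
#' correlation p-value as \code{w = -2 * (ln pA + ln pB + ln pAB)}
#' (natural logarithm). Inputs must lie in (0, 1]; values below
#' \code{floor} (default 1e-300) are clipped there so the strength stays
#' finite. Vectorized.
#'
#' @param pA,pB differential-significance p-values of the two genes.
#' @param pAB correlation p-value between the two genes' expression.
#' @param floor clip floor for tiny p-values.
#' @return numeric vector of interaction strengths (>= 0; 0 only when all
#'   three p-values are 1).
#' @examples
#' edgeStrength(0.05, 0.05, 0.05)  # -6 * log(0.05) = 17.97...
#' @export
edgeStrength <- function(pA, pB, pAB, floor = 1e-300) {
  for (p in list(pA, pB, pAB))
    if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
      stop("p-values must lie in (0, 1]", call. = FALSE)
  -2 * (log(pmax(pA, floor)) + log(pmax(pB, floor)) +
          log(pmax(pAB, floor)))
}

# precompute the strength of every PPI edge whose two endpoints are both
# in `genes`: differential p from diffP, correlation p over `samples`
precomputeEdgeStrengths <- function(genes, ppi, geneExpr, diffP,
                                    samples = NULL, floor = 1e-300) {
  e <- ppiEdges(ppi)
  e <- e[e$gene_a %in% genes & e$gene_b %in% genes, , drop = FALSE]
  G <- exprValues(geneExpr)
  if (is.null(samples)) samples <- colnames(G)
  out <- data.frame(gene_a = e$gene_a, gene_b = e$gene_b,
                    stringsAsFactors = FALSE)
  if (!nrow(e)) {
    out$p_a <- out$p_b <- out$p_ab <- out$w <- numeric(0)
    return(out)
  }
  r <- rowCor(G[e$gene_a, samples, drop = FALSE],
              G[e$gene_b, samples, drop = FALSE])
  pab <- corPValue(r, length(samples))
  pab[is.na(r)] <- 1
  out$p_a <- unname(diffP[e$gene_a])
  out$p_b <- unname(diffP[e$gene_b])
  out$p_ab <- pab
  out$w <- edgeStrength(out$p_a, out$p_b, out$p_ab, floor)
  out
}

# sum of precomputed edge strengths qualifying for an unordered pathway
# pair: edge (a, b) qualifies when a is a differential gene of one pathway
# and b of the other; each unordered PPI edge counts once
sumQualifying <- function(edgeTab, inI, inJ) {
  ia <- inI[edgeTab$gene_a]
  ib <- inI[edgeTab$gene_b]
  ja <- inJ[edgeTab$gene_a]
  jb <- inJ[edgeTab$gene_b]
  sel <- (ia & jb) | (ib & ja)
  list(weight = sum(edgeTab$w[sel]), nEdges = sum(sel))
}

#' Crosstalk weight of a pathway pair
#'
#' Sums [edgeStrength()] over every PPI edge joining a differential gene
#' annotated in pathway i to a differential gene annotated in pathway j.
#' Each unordered PPI edge is counted once, even when both genes belong
#' to both pathways.
#'
#' @param pathwayIGenes,pathwayJGenes gene identifier vectors of the two
#'   pathways.
#' @param diffGenes character vector of differential gene identifiers.
#' @param ppi a [PPINetwork-class].
#' @param geneExpr gene [ExpressionMatrix-class] (for the correlation
#'   p-value).
#' @param diffP named numeric: per-gene differential p-value.
#' @param samples optional sample identifiers over which correlation is
#'   computed (default: all columns of \code{geneExpr}).
#' @param floor clip floor, see [edgeStrength()].
#' @return list with elements \code{weight}, \code{n_edges} and
#'   \code{edges} (the qualifying edge table with per-edge strengths).
#' @export
pairWeight <- function(pathwayIGenes, pathwayJGenes, diffGenes, ppi,
                       geneExpr, diffP, samples = NULL, floor = 1e-300) {
  ai <- intersect(pathwayIGenes, diffGenes)
  aj <- intersect(pathwayJGenes, diffGenes)
  tab <- precomputeEdgeStrengths(union(ai, aj), ppi, geneExpr, diffP,
                                 samples, floor)
  allGenes <- union(ai, aj)
  inI <- setNames(allGenes %in% ai, allGenes)
  inJ <- setNames(allGenes %in% aj, allGenes)
  q <- sumQualifying(tab, inI, inJ)
  sel <- (inI[tab$gene_a] & inJ[tab$gene_b]) |
    (inI[tab$gene_b] & inJ[tab$gene_a])
  list(weight = q$weight, n_edges = q$nEdges,
       edges = tab[sel, , drop = FALSE])
}

# core permutation loop over a precomputed pool-edge table with integer
# endpoint indices into the pool
permuteNullWeights <- function(edgeA, edgeB, w, poolSize, sizeI, sizeJ, B) {
  vapply(seq_len(B), function(b) {
    ai <- logical(poolSize)
    ai[sample.int(poolSize, sizeI)] <- TRUE
    aj <- logical(poolSize)
    aj[sample.int(poolSize, sizeJ)] <- TRUE
    sum(w[(ai[edgeA] & aj[edgeB]) | (ai[edgeB] & aj[edgeA])])
  }, numeric(1))
}

#' Permutation significance of an observed crosstalk weight
#'
#' Replaces both pathways' differential-gene sets by uniform
#' without-replacement draws of the same sizes from the differential gene
#' pool, recomputes the crosstalk weight each round, and returns the
#' pseudo-count p-value \code{(r + 1) / (B + 1)} where \code{r} counts
#' permuted weights \code{>=} the observed weight. Set
#' \code{mode = "single"} to resample only the first pathway's set.
#'
#' @param observedWeight the observed pair weight.
#' @param pathwaySizes integer pair: differential-gene counts of the two
#'   pathways.
#' @param pool character vector: the differential gene pool to resample
#'   from.
#' @param ppi,geneExpr,diffP,samples,floor as in [pairWeight()].
#' @param B number of permutation rounds (>= 1).
#' @param seed optional seed for reproducibility.
#' @param mode \code{"joint"} (default, both sets resampled) or
#'   \code{"single"}.
#' @param pathwayJGenes for \code{mode = "single"}: the fixed
#'   differential-gene set of the second pathway.
#' @return the permutation p-value in (0, 1].
#' @export
permutationP <- function(observedWeight, pathwaySizes, pool, ppi,
                         geneExpr, diffP, B = 1000, seed = NULL,
                         samples = NULL, floor = 1e-300,
                         mode = c("joint", "single"),
                         pathwayJGenes = NULL) {
  mode <- match.arg(mode)
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  pool <- unique(pool)
  if (any(pathwaySizes > length(pool)))
    stop("pool smaller than a pathway's differential gene count",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tab <- precomputeEdgeStrengths(pool, ppi, geneExpr, diffP, samples,
                                 floor)
  a <- match(tab$gene_a, pool)
  b <- match(tab$gene_b, pool)
  if (mode == "joint") {
    null <- permuteNullWeights(a, b, tab$w, length(pool),
                               pathwaySizes[1L], pathwaySizes[2L], B)
  } else {
    if (is.null(pathwayJGenes))
      stop("mode = \"single\" needs pathwayJGenes", call. = FALSE)
    fixed <- pool %in% pathwayJGenes
    null <- vapply(seq_len(B), function(i) {
      ai <- logical(length(pool))
      ai[sample.int(length(pool), pathwaySizes[1L])] <- TRUE
      sum(tab$w[(ai[a] & fixed[b]) | (ai[b] & fixed[a])])
    }, numeric(1))
  }
  (sum(null >= observedWeight) + 1) / (B + 1)
}

#' Build the pathway crosstalk network
#'
#' Scores every unordered pair of the supplied pathways with the
#' Fisher's-method crosstalk weight over PPI edges between their
#' differential genes, estimates each pair's significance by gene-set
#' resampling from the pooled significant differential genes, and retains
#' pairs with permutation p below \code{threshold}. The per-gene
#' differential p-value entering the weight is the smallest p across the
#' contrasts present in \code{diffGenes}; the gene-gene correlation
#' p-value is computed over \code{samples} (default: all samples). Pairs
#' with no qualifying PPI edge have weight 0 and permutation p exactly 1
#' (every resampled weight is >= 0), so no rounds are spent on them.
#'
#' @param collection a [GeneSetCollection-class] (or subset) of the
#'   pathways to score, e.g. the pathways of a
#'   [MirnaPathwayNetwork-class].
#' @param ppi a [PPINetwork-class].
#' @param geneExpr gene [ExpressionMatrix-class].
#' @param diffGenes data.frame from [callDifferential()] for genes,
#'   possibly covering several contrasts.
#' @param B permutation rounds per pair, default 1000.
#' @param threshold permutation-p threshold for network edges, default
#'   0.05.
#' @param seed optional seed; with a fixed seed the network is
#'   reproducible.
#' @param nodeGrade,nodeDirection optional named character vectors of
#'   pathway attributes (e.g. from [networkNodes()] of the miRNA-pathway
#'   network).
#' @param samples optional sample subset for the correlation p-value.
#' @param floor clip floor, see [edgeStrength()].
#' @param mode permutation mode, see [permutationP()].
#' @return A [CrosstalkNetwork-class].
#' @export
buildCrosstalkNetwork <- function(collection, ppi, geneExpr, diffGenes,
                                  B = 1000, threshold = 0.05,
                                  seed = NULL, nodeGrade = NULL,
                                  nodeDirection = NULL, samples = NULL,
                                  floor = 1e-300,
                                  mode = c("joint", "single")) {
  mode <- match.arg(mode)
  sets <- geneSets(collection)
  if (length(sets) < 2L)
    stop("need >= 2 pathways", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sig <- diffGenes[diffGenes$significant, , drop = FALSE]
  measured <- featureIds(geneExpr)
  pool <- intersect(unique(sig$feature_id), measured)
  diffP <- vapply(split(diffGenes$p[diffGenes$feature_id %in% pool],
                        diffGenes$feature_id[diffGenes$feature_id %in%
                                               pool]),
                  min, numeric(1))
  tab <- precomputeEdgeStrengths(pool, ppi, geneExpr, diffP, samples,
                                 floor)
  a <- match(tab$gene_a, pool)
  b <- match(tab$gene_b, pool)
  diffSets <- lapply(sets, intersect, pool)
  ids <- names(sets)
  cmb <- combn(length(ids), 2L)
  rows <- vector("list", ncol(cmb))
  for (k in seq_len(ncol(cmb))) {
    i <- cmb[1L, k]
    j <- cmb[2L, k]
    inI <- pool %in% diffSets[[i]]
    inJ <- pool %in% diffSets[[j]]
    sel <- (inI[a] & inJ[b]) | (inI[b] & inJ[a])
    wObs <- sum(tab$w[sel])
    nE <- sum(sel)
    if (nE == 0L) {
      pp <- 1
    } else if (mode == "joint") {
      null <- permuteNullWeights(a, b, tab$w, length(pool),
                                 length(diffSets[[i]]),
                                 length(diffSets[[j]]), B)
      pp <- (sum(null >= wObs) + 1) / (B + 1)
    } else {
      null <- vapply(seq_len(B), function(x) {
        ai <- logical(length(pool))
        ai[sample.int(length(pool), length(diffSets[[i]]))] <- TRUE
        sum(tab$w[(ai[a] & inJ[b]) | (ai[b] & inJ[a])])
      }, numeric(1))
      pp <- (sum(null >= wObs) + 1) / (B + 1)
    }
    rows[[k]] <- data.frame(pathway_i = ids[i], pathway_j = ids[j],
                            weight = wObs, n_edges = nE, perm_p = pp,
                            stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  edges <- pairs[pairs$perm_p < threshold, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(
    pathway_id = ids,
    grade = if (is.null(nodeGrade)) NA_character_
            else unname(nodeGrade[ids]),
    direction = if (is.null(nodeDirection)) NA_character_
                else unname(nodeDirection[ids]),
    stringsAsFactors = FALSE)
  new("CrosstalkNetwork", pairs = pairs, edges = edges, nodes = nodes,
      nPermutations = as.integer(B))
}
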