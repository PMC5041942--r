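# Independent brute-force oracles and small fixture builders shared by
# the test files. Oracles are written from the definitions, not from the
# implementation code paths they check.

# exhaustive hypergeometric tail: enumerate every size-n draw from a
# universe of N genes of which the first M are "in the pathway"
hyperTailOracle <- function(N, M, n, m, tail = "ge") {
  if (n == 0L) {
    counts <- 0L
  } else {
    draws <- combn(N, n)
    counts <- colSums(draws <= M)
  }
  if (tail == "ge") mean(counts >= m) else mean(counts > m)
}

# step-up BH from the definition: sorted adj[i] = min_{j >= i} min(1, p_j*m/j)
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(1, min(sorted[i:m] * m / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# maximal bicliques by bitmask closure: for every miRNA subset U, the
# largest common pathway set V = AND of neighborhoods, then extend U to
# every miRNA whose neighborhood covers V; distinct closures with both
# sides nonempty are exactly the maximal bicliques
bicliqueOracle <- function(edges) {
  mir <- sort(unique(edges[[1L]]))
  pw <- sort(unique(edges[[2L]]))
  mask <- setNames(integer(length(mir)), mir)
  for (i in seq_len(nrow(edges))) {
    m <- edges[[1L]][i]
    bit <- bitwShiftL(1L, match(edges[[2L]][i], pw) - 1L)
    mask[m] <- bitwOr(mask[m], bit)
  }
  seen <- character(0)
  out <- list()
  for (u in seq_len(2^length(mir) - 1L)) {
    inU <- which(bitwAnd(u, bitwShiftL(1L, seq_along(mir) - 1L)) != 0L)
    v <- Reduce(bitwAnd, mask[inU])
    if (v == 0L) next
    u2 <- mir[bitwAnd(mask, v) == v]
    key <- paste(c(u2, "|",
                   pw[bitwAnd(v, bitwShiftL(1L, seq_along(pw) - 1L)) != 0L]),
                 collapse = " ")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- list(
      mirnas = u2,
      pathways = pw[bitwAnd(v, bitwShiftL(1L, seq_along(pw) - 1L)) != 0L])
  }
  out[order(vapply(out, function(m)
    paste(c(m$mirnas, "|", m$pathways), collapse = " "), character(1)))]
}

# k-clique percolation from the definition: enumerate complete k-subsets,
# merge those sharing k-1 vertices, report node unions
percolationOracle <- function(edges, vertices, k) {
  ekey <- c(paste(edges[[1L]], edges[[2L]]), paste(edges[[2L]], edges[[1L]]))
  isClique <- function(vs) {
    pr <- combn(vs, 2L)
    all(paste(pr[1L, ], pr[2L, ]) %in% ekey)
  }
  if (length(vertices) < k) return(list())
  cand <- combn(sort(vertices), k)
  cl <- Filter(isClique, lapply(seq_len(ncol(cand)), function(i) cand[, i]))
  if (!length(cl)) return(list())
  comp <- seq_along(cl)
  repeat {
    changed <- FALSE
    for (i in seq_along(cl)) for (j in seq_along(cl)) {
      if (comp[i] != comp[j] &&
          length(intersect(cl[[i]], cl[[j]])) >= k - 1L) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- lapply(unique(comp), function(ci)
    sort(unique(unlist(cl[comp == ci]))))
  out[order(vapply(out, paste, character(1), collapse = " "))]
}

# brute-force pathway-pair crosstalk weight: loop over all gene pairs,
# look each up in the PPI edge set, recompute the three p-values
pairWeightOracle <- function(genesI, genesJ, diffGenes, ppiTab, exprMat,
                             diffP) {
  ekey <- c(paste(ppiTab$gene_a, ppiTab$gene_b),
            paste(ppiTab$gene_b, ppiTab$gene_a))
  ai <- intersect(genesI, diffGenes)
  aj <- intersect(genesJ, diffGenes)
  total <- 0
  nE <- 0L
  counted <- character(0)
  for (a in ai) for (b in aj) {
    if (a == b) next
    key <- paste(sort(c(a, b)), collapse = " ")
    if (key %in% counted) next
    if (!paste(a, b) %in% ekey) next
    counted <- c(counted, key)
    ct <- cor.test(exprMat[a, ], exprMat[b, ])
    pab <- max(ct$p.value, .Machine$double.xmin)
    total <- total - 2 * (log(diffP[[a]]) + log(diffP[[b]]) + log(pab))
    nE <- nE + 1L
  }
  list(weight = total, n_edges = nE)
}

# vectors with an exact Pearson correlation r (sample correlation)
vectorsWithCor <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  z <- rnorm(n)
  z <- residuals(stats::lm(z ~ x))
  x <- as.vector(scale(x))
  z <- as.vector(scale(z))
  list(x = x, y = r * x + sqrt(1 - r^2) * z)
}

# compact generator configuration for fast tests
smallConfig <- function(seed = 1, ...) {
  args <- list(nSamplesPerGrade = c(20L, 20L, 20L), nMirnas = 60L,
               nGenes = 400L, nDiffMirnas = 12L, nDiffGenes = 90L,
               nPathways = 8L, pathwaySize = 30L,
               nPlantedCrosstalkPairs = 3L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(syntheticConfig, args)
}

# random bipartite edge list over <= 12 vertices
randomBipartite <- function(nm, np, pEdge) {
  mir <- sprintf("m%02d", seq_len(nm))
  pw <- sprintf("p%02d", seq_len(np))
  combos <- expand.grid(mirna_id = mir, pathway_id = pw,
                        stringsAsFactors = FALSE)
  combos[runif(nrow(combos)) < pEdge, , drop = FALSE]
}

# random simple graph edge list
randomGraph <- function(nv, pEdge) {
  v <- sprintf("v%02d", seq_len(nv))
  pr <- t(combn(v, 2L))
  keep <- runif(nrow(pr)) < pEdge
  list(edges = data.frame(a = pr[keep, 1L], b = pr[keep, 2L],
                          stringsAsFactors = FALSE), vertices = v)
}
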