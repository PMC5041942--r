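# Signature miRNA-target pair selection, cumulative hypergeometric
# pathway enrichment, and the bipartite miRNA-pathway crosstalk network.

#' Pearson correlation with the asymptotic (Fisher) test
#'
#' Pearson r and the two-sided p-value from the t-distribution transform
#' \code{t = r * sqrt(n - 2) / sqrt(1 - r^2)} (the asymptotic test, as in
#' \code{cor.test}). A constant vector leaves r undefined; the pair is
#' reported as \code{r = 0, p = 1} with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with elements \code{r} and \code{p}.
#' @export
correlatePearson <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  if (length(x) < 3L) stop("need >= 3 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: correlation undefined, reporting r = 0, p = 1")
    return(list(r = 0, p = 1))
  }
  r <- cor(x, y)
  list(r = r, p = corPValue(r, length(x)))
}

# two-sided p of Pearson r at sample size n (t transform); |r| = 1 gives
# the smallest representable p rather than 0
corPValue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pmax(2 * pt(-t, n - 2), .Machine$double.xmin)
}

# rowwise Pearson correlation of paired rows of two matrices
rowCor <- function(x, y) {
  cx <- x - rowMeans(x)
  cy <- y - rowMeans(y)
  sx <- sqrt(rowSums(cx^2))
  sy <- sqrt(rowSums(cy^2))
  num <- rowSums(cx * cy)
  r <- num / (sx * sy)
  r[sx == 0 | sy == 0] <- NA_real_
  r
}

#' Select signature miRNA-target pairs by inverse correlation
#'
#' A predicted miRNA-target pair is a signature pair for a grade contrast
#' when (1) both the miRNA and the gene are significantly differential in
#' that contrast with opposite directions, and (2) their expression is
#' inversely correlated past the cutoff: Pearson \code{r <= cutoff}
#' (default -0.4) with asymptotic-test \code{p < pMax} (default 0.05).
#' Correlation is computed per contrast over the grade II controls plus
#' the contrast's case-grade samples (\code{sampleSet = "contrast"},
#' keeping each contrast self-contained) or over all annotated samples.
#'
#' @param diffMirnas,diffGenes data.frames from [callDifferential()]
#'   (rows for one or more contrasts).
#' @param targetPairs data.frame with columns \code{mirna_id},
#'   \code{gene_id}.
#' @param mirnaExpr,geneExpr [ExpressionMatrix-class] objects sharing
#'   sample columns.
#' @param annotation sample annotation data.frame.
#' @param cutoff correlation cutoff, default -0.4.
#' @param pMax correlation p-value bound, default 0.05.
#' @param sampleSet \code{"contrast"} (default) or \code{"all"}.
#' @return data.frame with columns \code{mirna_id}, \code{gene_id},
#'   \code{contrast}, \code{direction_pattern}
#'   (\code{miR_up_gene_down}/\code{miR_down_gene_up}), \code{r},
#'   \code{r_p}.
#' @export
selectSignaturePairs <- function(diffMirnas, diffGenes, targetPairs,
                                 mirnaExpr, geneExpr, annotation,
                                 cutoff = -0.4, pMax = 0.05,
                                 sampleSet = c("contrast", "all")) {
  sampleSet <- match.arg(sampleSet)
  M <- exprValues(mirnaExpr)
  G <- exprValues(geneExpr)
  shared <- intersect(colnames(M), colnames(G))
  if (!length(shared))
    stop("expression matrices share no samples", call. = FALSE)
  out <- list()
  for (ctr in sort(unique(c(diffMirnas$contrast, diffGenes$contrast)))) {
    sigM <- diffMirnas[diffMirnas$contrast == ctr &
                         diffMirnas$significant, , drop = FALSE]
    sigG <- diffGenes[diffGenes$contrast == ctr &
                        diffGenes$significant, , drop = FALSE]
    cand <- targetPairs[targetPairs$mirna_id %in% sigM$feature_id &
                          targetPairs$gene_id %in% sigG$feature_id,
                        c("mirna_id", "gene_id"), drop = FALSE]
    if (!nrow(cand)) next
    dirM <- setNames(sigM$direction, sigM$feature_id)
    dirG <- setNames(sigG$direction, sigG$feature_id)
    cand <- cand[dirM[cand$mirna_id] != dirG[cand$gene_id], , drop = FALSE]
    if (!nrow(cand)) next
    if (sampleSet == "contrast") {
      caseGrade <- sub("_vs_II", "", ctr)
      keep <- annotation$sample_id[annotation$grade %in%
                                     c("II", caseGrade)]
      cols <- intersect(shared, keep)
    } else cols <- shared
    r <- rowCor(M[cand$mirna_id, cols, drop = FALSE],
                G[cand$gene_id, cols, drop = FALSE])
    rp <- corPValue(r, length(cols))
    rp[is.na(r)] <- 1
    r[is.na(r)] <- 0
    sel <- r <= cutoff & rp < pMax
    if (!any(sel)) next
    out[[ctr]] <- data.frame(
      mirna_id = cand$mirna_id[sel], gene_id = cand$gene_id[sel],
      contrast = ctr,
      direction_pattern = ifelse(dirM[cand$mirna_id[sel]] == "up",
                                 "miR_up_gene_down", "miR_down_gene_up"),
      r = r[sel], r_p = rp[sel], stringsAsFactors = FALSE,
      row.names = NULL)
  }
  if (!length(out))
    return(data.frame(mirna_id = character(0), gene_id = character(0),
                      contrast = character(0),
                      direction_pattern = character(0), r = numeric(0),
                      r_p = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cumulative hypergeometric enrichment of a gene set in a pathway
#'
#' Tests whether \code{targetGenes} over-represents \code{pathwayGenes}
#' within \code{universe}: with \code{N} universe genes, \code{M} pathway
#' genes, \code{n} target genes and \code{m} targets inside the pathway,
#' the upper-tail probability \code{P(X >= m)} of the
#' hypergeometric(N, M, n) law (\code{tail = "ge"}, the standard
#' enrichment convention) or the strict tail \code{P(X > m)}
#' (\code{tail = "gt"}).
#'
#' @param targetGenes,pathwayGenes,universe character vectors of gene
#'   identifiers; target and pathway sets are intersected with the
#'   universe.
#' @param tail \code{"ge"} (default) or \code{"gt"}.
#' @return list with elements \code{N}, \code{M}, \code{n}, \code{m},
#'   \code{p_value}.
#' @examples
#' hypergeomEnrich(letters[1:5], letters[1:5], letters[1:10])
#' @export
hypergeomEnrich <- function(targetGenes, pathwayGenes, universe,
                            tail = c("ge", "gt")) {
  tail <- match.arg(tail)
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  targetGenes <- intersect(unique(targetGenes), universe)
  pathwayGenes <- intersect(unique(pathwayGenes), universe)
  N <- length(universe)
  M <- length(pathwayGenes)
  n <- length(targetGenes)
  m <- length(intersect(targetGenes, pathwayGenes))
  q <- if (tail == "ge") m - 1L else m
  p <- phyper(q, M, N - M, n, lower.tail = FALSE)
  list(N = N, M = M, n = n, m = m, p_value = p)
}

#' Build the bipartite miRNA-pathway crosstalk network
#'
#' For each miRNA and contrast, the miRNA's inversely correlated target
#' set (genes of its signature pairs) is tested for enrichment in every
#' pathway with [hypergeomEnrich()]; edges with raw \code{p} below
#' \code{threshold} (default 0.05) are retained. Raw p-values are
#' thresholded by default; \code{adjust = TRUE} applies
#' Benjamini-Hochberg per contrast first. Pathway grade association
#' (\code{III}/\code{IV}/\code{both}) records which contrasts contribute
#' edges; node directions summarize the regulation pattern of the
#' contributing pairs.
#'
#' @param pairs signature pairs from [selectSignaturePairs()].
#' @param collection a [GeneSetCollection-class].
#' @param universe character vector: the enrichment universe, typically
#'   the genes both measured and annotated to at least one pathway.
#' @param threshold edge p-value threshold, default 0.05.
#' @param tail tail convention, see [hypergeomEnrich()].
#' @param adjust apply BH per contrast before thresholding (default
#'   FALSE).
#' @return A [MirnaPathwayNetwork-class].
#' @export
buildMirnaPathwayNetwork <- function(pairs, collection, universe,
                                     threshold = 0.05,
                                     tail = c("ge", "gt"),
                                     adjust = FALSE) {
  tail <- match.arg(tail)
  if (!nrow(pairs))
    stop("no signature pairs supplied", call. = FALSE)
  universe <- unique(universe)
  sets <- lapply(geneSets(collection), intersect, universe)
  sets <- sets[lengths(sets) > 0L]
  rows <- list()
  groups <- unique(pairs[c("mirna_id", "contrast")])
  for (i in seq_len(nrow(groups))) {
    mir <- groups$mirna_id[i]
    ctr <- groups$contrast[i]
    targets <- unique(pairs$gene_id[pairs$mirna_id == mir &
                                      pairs$contrast == ctr])
    targets <- intersect(targets, universe)
    if (!length(targets)) next
    p <- vapply(sets, function(s)
      hypergeomEnrich(targets, s, universe, tail)$p_value, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      mirna_id = mir, pathway_id = names(sets), contrast = ctr, p = p,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  edges <- do.call(rbind, rows)
  if (is.null(edges))
    edges <- data.frame(mirna_id = character(0), pathway_id = character(0),
                        contrast = character(0), p = numeric(0))
  if (adjust && nrow(edges))
    edges$p <- stats::ave(edges$p, edges$contrast, FUN = bhAdjust)
  edges <- edges[edges$p < threshold, , drop = FALSE]
  edges <- edges[order(edges$mirna_id, edges$pathway_id, edges$contrast), ,
                 drop = FALSE]
  rownames(edges) <- NULL

  majority <- function(x) {
    if (all(x == "up")) "up" else if (all(x == "down")) "down"
    else if (sum(x == "up") > sum(x == "down")) "up"
    else if (sum(x == "down") > sum(x == "up")) "down" else "mixed"
  }
  mirnaDir <- vapply(split(
    ifelse(pairs$direction_pattern == "miR_up_gene_down", "up", "down"),
    pairs$mirna_id), majority, character(1))
  mirnaDir <- mirnaDir[intersect(names(mirnaDir), unique(edges$mirna_id))]

  pwGrade <- character(0)
  pwDir <- character(0)
  if (nrow(edges)) {
    caseOf <- function(ctr) sub("_vs_II", "", ctr)
    gradeBy <- lapply(split(caseOf(edges$contrast), edges$pathway_id),
                      unique)
    pwGrade <- vapply(gradeBy, function(g)
      if (length(g) > 1L) "both" else g, character(1))
    # direction of the gene sets enriching the pathway: opposite of the
    # contributing miRNAs' direction
    geneDirRows <- merge(edges[c("mirna_id", "pathway_id")],
                         data.frame(mirna_id = names(mirnaDir),
                                    mdir = unname(mirnaDir)),
                         by = "mirna_id")
    geneDirRows$gdir <- ifelse(geneDirRows$mdir == "up", "down",
                               ifelse(geneDirRows$mdir == "down", "up",
                                      "mixed"))
    pwDir <- vapply(split(geneDirRows$gdir, geneDirRows$pathway_id),
                    majority, character(1))
    pwDir <- pwDir[names(pwGrade)]
  }
  new("MirnaPathwayNetwork", edges = edges, mirnaDirection = mirnaDir,
      pathwayGrade = pwGrade, pathwayDirection = pwDir)
}

#' Hub miRNAs of the miRNA-pathway network
#'
#' Hubs are the top \code{fraction} (default 15%) of miRNAs by degree
#' (number of distinct pathways regulated): the
#' \code{ceiling(fraction * n)} highest-degree miRNAs, with every miRNA
#' tied with the last included one also included.
#'
#' @param network a [MirnaPathwayNetwork-class].
#' @param fraction top fraction by degree, default 0.15.
#' @return character vector of hub miRNA identifiers, ordered by
#'   decreasing degree then identifier.
#' @export
findHubs <- function(network, fraction = 0.15) {
  e <- unique(networkEdges(network)[c("mirna_id", "pathway_id")])
  if (!nrow(e)) stop("network has no miRNAs", call. = FALSE)
  deg <- sort(table(e$mirna_id), decreasing = TRUE)
  k <- ceiling(fraction * length(deg))
  cut <- as.integer(deg[k])
  hubs <- deg[as.integer(deg) >= cut]
  names(hubs)[order(-as.integer(hubs), names(hubs))]
}
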